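test_that("annotated regions are discovered; decorations yield none", {
  svg <- generate_ehld(fixture_spec(seed = 6, ehld_regions = 3))
  doc <- parse_ehld(svg)
  expect_length(doc$regions, 3L)
  expect_setequal(names(doc$regions), c("EH1", "EH2", "EH3"))
  for (rg in doc$regions) {
    expect_false(is.null(rg$region))
    expect_false(is.null(rg$label))
    expect_false(is.null(rg$overlay))
  }

  plain <- paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                  'viewBox="0 0 10 10"><rect x="1" y="1" width="5" ',
                  'height="5"/></svg>')
  expect_length(parse_ehld(plain)$regions, 0L)
})

test_that("malformed or unannotatable documents are rejected", {
  expect_error(parse_ehld("<svg"), "malformed SVG")
  expect_error(
    parse_ehld('<svg xmlns="http://www.w3.org/2000/svg"></svg>'),
    "no canvas")
  dup <- paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 10 10">',
    '<rect id="REGION-P1" x="0" y="0" width="4" height="4"/>',
    '<rect id="REGION-P1" x="5" y="5" width="4" height="4"/></svg>')
  expect_error(parse_ehld(dup), "duplicate region .* 'P1'")
})

test_that("a region lacking its label or overlay is partial, with a warning", {
  svg <- paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 10 10">',
    '<rect id="REGION-P1" x="0" y="0" width="4" height="4"/></svg>')
  expect_warning(doc <- parse_ehld(svg), "partial active region")
  expect_length(doc$regions, 1L)
  expect_null(doc$regions[["P1"]]$label)
})

test_that("hit_test finds the topmost region and ignores decorations", {
  svg <- generate_ehld(fixture_spec(seed = 6, ehld_regions = 4))
  doc <- parse_ehld(svg)
  # oracle: region rects read straight off the generated attributes
  x <- xml2::read_xml(svg)
  nodes <- xml2::xml_find_all(x, "//*[@id]")
  ids <- xml2::xml_attr(nodes, "id")
  sel <- grepl("^REGION-", ids)
  rr <- lapply(which(sel), function(i) {
    n <- nodes[[i]]
    list(pid = sub("^REGION-", "", ids[i]),
         x = as.numeric(xml2::xml_attr(n, "x")),
         y = as.numeric(xml2::xml_attr(n, "y")),
         w = as.numeric(xml2::xml_attr(n, "width")),
         h = as.numeric(xml2::xml_attr(n, "height")))
  })
  oracle <- function(px, py) {
    hit <- NULL
    for (r in rr) {
      if (px >= r$x && px <= r$x + r$w && py >= r$y && py <= r$y + r$h) {
        hit <- r$pid
      }
    }
    hit
  }
  # centre of each region must hit it
  for (r in rr) {
    expect_identical(hit_test(doc, r$x + r$w / 2, r$y + r$h / 2), r$pid)
  }
  set.seed(3)
  for (i in 1:200) {
    px <- runif(1, 0, doc$canvas$w)
    py <- runif(1, 0, doc$canvas$h)
    expect_identical(hit_test(doc, px, py), oracle(px, py))
  }
  expect_null(hit_test(doc, doc$canvas$w - 1, doc$canvas$h - 1))
  expect_error(hit_test(doc, -5, 0), "out of canvas")
})

test_that("region states round-trip exactly and are idempotent", {
  svg <- generate_ehld(fixture_spec(seed = 6, ehld_regions = 3))
  doc <- parse_ehld(svg)
  original <- export_svg(doc)

  set_region_state(doc, "EH2", "selected")
  selected_once <- export_svg(doc)
  expect_false(identical(canon_xml(selected_once), canon_xml(original)))
  set_region_state(doc, "EH2", "selected")
  expect_identical(canon_xml(export_svg(doc)), canon_xml(selected_once))

  set_region_state(doc, "EH2", "flagged")
  flagged <- export_svg(doc)
  expect_false(identical(canon_xml(flagged), canon_xml(selected_once)))

  set_region_state(doc, "EH2", "normal")
  expect_identical(canon_xml(export_svg(doc)), canon_xml(original))

  expect_error(set_region_state(doc, "NOPE", "selected"),
               "no such region")
})

test_that("decoration subtrees are never modified", {
  svg <- generate_ehld(fixture_spec(seed = 9, ehld_regions = 3))
  doc <- parse_ehld(svg)
  deco_before <- as.character(
    xml2::xml_find_first(doc$doc, "//*[@id='deco-membrane']"))
  set_region_state(doc, "EH1", "highlighted")
  fx <- generate_analysis_fixture(fixture_spec(seed = 9,
                                               n_pathway_sets = 3))
  suppressMessages(apply_overlay(doc, ora(fx$query, fx$sets)))
  deco_after <- as.character(
    xml2::xml_find_first(doc$doc, "//*[@id='deco-membrane']"))
  expect_identical(deco_after, deco_before)
})

test_that("export preserves ids and supports overlay stripping", {
  svg <- generate_ehld(fixture_spec(seed = 10, ehld_regions = 5))
  doc <- parse_ehld(svg)
  reparsed <- parse_ehld(export_svg(doc))
  expect_setequal(names(reparsed$regions), names(doc$regions))

  plain <- export_svg(doc)
  fx <- generate_analysis_fixture(fixture_spec(seed = 10,
                                               n_pathway_sets = 5))
  suppressMessages(apply_overlay(doc, ora(fx$query, fx$sets)))
  with_overlay <- export_svg(doc, include_overlay = TRUE)
  expect_true(grepl("analysis-result-overlay", with_overlay))
  stripped <- export_svg(doc, include_overlay = FALSE)
  expect_identical(canon_xml(stripped), canon_xml(plain))
})
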