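test_that("ora reproduces the exact combinatorial tail probabilities", {
  universe <- sprintf("U%02d", 1:20)
  es <- entity_sets(list(P1 = universe[1:5]), universe = universe)
  res <- ora(universe[1:5], es)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p_value, 6.4499e-5, tolerance = 1e-3)
  expect_identical(res$found, 5L)

  res0 <- ora(universe[6:10], es)  # zero overlap: P(X >= 0) = 1
  expect_identical(res0$found, 0L)
  expect_equal(res0$p_value, 1)
})

test_that("ora matches the summation oracle on 50 random configurations", {
  set.seed(19)
  for (i in 1:50) {
    N <- sample(20:60, 1)
    universe <- sprintf("U%03d", seq_len(N))
    sets <- lapply(seq_len(sample(2:6, 1)), function(k) {
      sample(universe, sample(3:(N %/% 2), 1))
    })
    names(sets) <- paste0("P", seq_along(sets))
    es <- entity_sets(sets, universe = universe)
    query <- sample(universe, sample(3:(N %/% 2), 1))
    res <- ora(query, es)
    for (j in seq_len(nrow(res))) {
      expect_equal(res$p_value[j],
                   hyper_tail_oracle(res$found[j], res$total[j], N,
                                     length(query)),
                   tolerance = 1e-12)
    }
    expect_equal(res$fdr, bh_oracle(res$p_value), tolerance = 1e-12)
  }
})

test_that("query identifiers outside the universe are dropped, not counted", {
  universe <- sprintf("U%02d", 1:20)
  es <- entity_sets(list(P1 = universe[1:5]), universe = universe)
  expect_message(res <- ora(c(universe[1:5], "ALIEN1", "ALIEN2"), es),
                 "2 query identifier")
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_error(suppressMessages(ora(c("ALIEN1", "ALIEN2"), es)),
               "query disjoint from universe")
})

test_that("bh_fdr equals the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(23)
  for (i in 1:30) {
    p <- runif(sample(1:10, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("p-value colouring is a gradient below threshold, grey at and above", {
  st <- overlay_style(color_profile("modern"))
  expect_identical(pvalue_to_color(0, st), st$gradient[1])
  expect_identical(pvalue_to_color(0.2, st), st$grey)
  expect_identical(pvalue_to_color(st$significance_threshold, st), st$grey)

  mid <- pvalue_to_color(0.025, st)
  a <- pathcanvas:::parse_color(st$gradient[1])
  b <- pathcanvas:::parse_color(st$gradient[2])
  expect_identical(mid, pathcanvas:::format_color((a + b) / 2))

  # continuity on [0, threshold): small p-steps give small colour steps
  ps <- seq(0, st$significance_threshold - 1e-9, length.out = 200)
  cols <- t(vapply(pvalue_to_color(ps, st), pathcanvas:::parse_color,
                   integer(4)))
  expect_true(all(abs(diff(cols[, 1])) <= 2))
  expect_true(all(abs(diff(cols[, 2])) <= 2))
  expect_true(all(abs(diff(cols[, 3])) <= 2))
})

test_that("hit bar width is exactly proportional to the hit fraction", {
  lb <- rect(100, 50, 200, 20)
  expect_equal(hit_bar_rect(0, 10, lb)$w, 0)
  expect_equal(hit_bar_rect(10, 10, lb)$w, lb$w)
  expect_equal(hit_bar_rect(6, 24, lb)$w, 50)
  b <- hit_bar_rect(3, 7, lb)
  expect_equal(b$x, lb$x)
  expect_equal(b$y, lb$y + lb$h)
  expect_error(hit_bar_rect(1, 0, lb), "total")
  expect_error(hit_bar_rect(5, 4, lb), "found")
})

test_that("overlay rendering counts: one rect and bar per hit, one legend", {
  svg <- generate_ehld(fixture_spec(seed = 14, ehld_regions = 3))
  doc <- parse_ehld(svg)
  res <- structure(
    data.frame(pathway_id = c("EH1", "EH2", "EH3"),
               found = c(3L, 5L, 2L), total = c(10L, 20L, 8L),
               p_value = c(0.001, 0.2, 0.04),
               fdr = c(0.003, 0.2, 0.06), stringsAsFactors = FALSE),
    class = c("ora_result", "data.frame"))
  apply_overlay(doc, res)
  x <- doc$doc
  expect_length(xml2::xml_find_all(x, "//*[@class='overlay-rect']"), 3L)
  expect_length(xml2::xml_find_all(x, "//*[@class='hit-bar']"), 3L)
  expect_length(xml2::xml_find_all(x, "//*[@class='overlay-legend']"), 1L)
  txt <- xml2::xml_text(xml2::xml_find_first(
    x, "//*[@id='overlay-text-EH1']"))
  expect_match(txt, "3/10 FDR = 3\\.00E-03")

  # idempotence: re-applying the same result leaves the document unchanged
  before <- export_svg(doc)
  apply_overlay(doc, res)
  expect_identical(canon_xml(export_svg(doc)), canon_xml(before))
})

test_that("an empty result leaves the document untouched (no legend)", {
  svg <- generate_ehld(fixture_spec(seed = 14, ehld_regions = 3))
  doc <- parse_ehld(svg)
  original <- export_svg(doc)
  empty <- structure(
    data.frame(pathway_id = character(0), found = integer(0),
               total = integer(0), p_value = numeric(0),
               fdr = numeric(0), stringsAsFactors = FALSE),
    class = c("ora_result", "data.frame"))
  apply_overlay(doc, empty)
  expect_identical(canon_xml(export_svg(doc)), canon_xml(original))
})

test_that("classic-diagram labels gain proportional analysis bars", {
  doc <- generate_diagram(fixture_spec(seed = 16, n_reactions = 8,
                                       n_subpathways = 3))
  boxes <- highlight_diagram(doc$diagram, doc$subpathways)
  # the fixture is roomy: at least one label must have been placed
  expect_gt(sum(vapply(boxes, function(b) !is.null(b$label_rect),
                       logical(1))), 0L)

  set.seed(2)
  for (i in 1:10) {
    found <- sample(0:20, length(boxes), replace = TRUE)
    total <- found + sample(1:20, length(boxes), replace = TRUE)
    res <- structure(
      data.frame(pathway_id = vapply(boxes, `[[`, character(1),
                                     "subpathway_id"),
                 found = found, total = total,
                 p_value = runif(length(boxes)),
                 fdr = runif(length(boxes)), stringsAsFactors = FALSE),
      class = c("ora_result", "data.frame"))
    dec <- overlay_lld_labels(boxes, res)
    for (k in seq_along(dec)) {
      if (is.null(dec[[k]]$label_rect)) next
      expect_equal(dec[[k]]$hit_bar$w * total[k],
                   found[k] * dec[[k]]$label_rect$w,
                   tolerance = 1e-12)
    }
  }

  no_res <- overlay_lld_labels(boxes, structure(
    data.frame(pathway_id = character(0), found = integer(0),
               total = integer(0), p_value = numeric(0), fdr = numeric(0),
               stringsAsFactors = FALSE),
    class = c("ora_result", "data.frame")))
  expect_identical(no_res, boxes)
})

test_that("GMT files round-trip with their universe", {
  fx <- generate_analysis_fixture(fixture_spec(seed = 25))
  f <- tempfile(fileext = ".gmt")
  write_gmt(fx$sets, f)
  back <- read_gmt(f)
  expect_setequal(back$universe, fx$sets$universe)
  expect_identical(lapply(back$sets, sort), lapply(fx$sets$sets, sort))
  writeLines("only-one-field", f)
  expect_error(read_gmt(f), "malformed GMT")
})
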