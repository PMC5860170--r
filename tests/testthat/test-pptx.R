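test_that("the shape graph follows the segment-counting rule", {
  d <- tiny_diagram()
  g <- build_shape_graph(d)
  # backbone (3 pts, middle on the reaction point) -> 2 connectors, plus
  # one per 2-point role connector: 5 in total, no anchors needed
  expect_length(g$connectors, 5L)
  expect_identical(graph_shape_count(g, "anchor"), 0L)
  expect_identical(graph_shape_count(g, "node"), 3L)
  expect_identical(graph_shape_count(g, "reaction_centre"), 1L)
  expect_identical(graph_shape_count(g, "decoration"), 1L)  # catalyst circle
  expect_length(g$groups, 1L)

  ends <- unlist(lapply(g$connectors, function(cn) c(cn$from, cn$to)))
  expect_true(all(ends %in% names(g$shapes)))
  # input and output connectors join their node to the reaction centre
  roles <- Filter(function(cn) grepl("::c", cn$id), g$connectors)
  expect_setequal(vapply(roles, `[[`, character(1), "from"),
                  c("A", "B", "C"))
  expect_true(all(vapply(roles, `[[`, character(1), "to") ==
                    "R1::centre"))
})

test_that("backbone bends become invisible anchors", {
  d <- tiny_diagram()
  d$edges[[1]]$segments <- rbind(c(80, 120), c(100, 60), c(200, 60),
                                 c(280, 120))
  expect_identical(validate_diagram(d), character(0))
  g <- build_shape_graph(d)
  expect_identical(graph_shape_count(g, "anchor"), 2L)
  backbone <- Filter(function(cn) grepl("::b", cn$id), g$connectors)
  expect_length(backbone, 3L)
  # chained: A -> anchor -> anchor -> B
  expect_identical(backbone[[1]]$from, "A")
  expect_identical(backbone[[3]]$to, "B")
  expect_identical(backbone[[1]]$to, backbone[[2]]$from)
  expect_identical(backbone[[2]]$to, backbone[[3]]$from)
})

test_that("generated fixtures obey the counting rules exactly", {
  for (seed in c(2, 28)) {
    doc <- generate_diagram(fixture_spec(seed = seed, n_reactions = 12,
                                         n_nodes = 16))
    g <- build_shape_graph(doc$diagram)
    expect_length(g$connectors, expected_connector_count(doc$diagram))
    expect_identical(graph_shape_count(g, "anchor"),
                     expected_anchor_count(doc$diagram))
  }
})

test_that("written packages contain one slide and reference-attached connectors", {
  d <- tiny_diagram()
  f <- tempfile(fileext = ".pptx")
  g <- build_shape_graph(d)
  write_pptx(g, f)

  listing <- utils::unzip(f, list = TRUE)$Name
  expect_length(grep("^ppt/slides/slide[0-9]+\\.xml$", listing), 1L)

  exdir <- pathcanvas:::zip_extract(f)
  on.exit(unlink(exdir, recursive = TRUE))
  ns <- pathcanvas:::PML_NS
  slide <- xml2::read_xml(file.path(exdir, "ppt/slides/slide1.xml"))
  sp_ids <- xml2::xml_attr(
    xml2::xml_find_all(slide, "//p:sp/p:nvSpPr/p:cNvPr", ns), "id")
  cxns <- xml2::xml_find_all(slide, "//p:cxnSp", ns)
  expect_length(cxns, length(g$connectors))
  for (cx in cxns) {
    st <- xml2::xml_find_first(cx, ".//a:stCxn", ns)
    en <- xml2::xml_find_first(cx, ".//a:endCxn", ns)
    expect_false(inherits(st, "xml_missing"))
    expect_false(inherits(en, "xml_missing"))
    expect_true(xml2::xml_attr(st, "id") %in% sp_ids)
    expect_true(xml2::xml_attr(en, "id") %in% sp_ids)
  }
})

test_that("anchor shapes are serialized with no line and no fill", {
  d <- tiny_diagram()
  d$edges[[1]]$segments <- rbind(c(80, 120), c(100, 60), c(200, 60),
                                 c(280, 120))
  f <- tempfile(fileext = ".pptx")
  write_pptx(build_shape_graph(d), f)
  exdir <- pathcanvas:::zip_extract(f)
  on.exit(unlink(exdir, recursive = TRUE))
  ns <- pathcanvas:::PML_NS
  slide <- xml2::read_xml(file.path(exdir, "ppt/slides/slide1.xml"))
  anchors <- xml2::xml_find_all(
    slide, "//p:sp[contains(p:nvSpPr/p:cNvPr/@name, '::a')]", ns)
  expect_length(anchors, 2L)
  for (a in anchors) {
    expect_length(xml2::xml_find_all(a, "./p:spPr/a:noFill", ns), 1L)
    expect_length(xml2::xml_find_all(a, "./p:spPr/a:ln/a:noFill", ns), 1L)
  }
})

test_that("verify_export gives an all-zero report for written files", {
  doc <- generate_diagram(fixture_spec(seed = 33, n_reactions = 10,
                                       n_nodes = 14))
  f <- tempfile(fileext = ".pptx")
  export_pptx(doc$diagram, f)
  rep <- verify_export(f)
  expect_true(rep$ok)
  expect_identical(rep$dangling_refs, 0L)
  expect_identical(rep$unattached_connectors, 0L)
  expect_identical(rep$out_of_bounds, 0L)
})

test_that("deleting a referenced shape is reported as a dangling reference", {
  d <- tiny_diagram()
  f <- tempfile(fileext = ".pptx")
  write_pptx(build_shape_graph(d), f)
  exdir <- pathcanvas:::zip_extract(f)
  ns <- pathcanvas:::PML_NS
  slide_path <- file.path(exdir, "ppt/slides/slide1.xml")
  slide <- xml2::read_xml(slide_path)
  victim <- xml2::xml_find_first(
    slide, "//p:sp[p:nvSpPr/p:cNvPr/@name='A']", ns)
  xml2::xml_remove(victim)
  xml2::write_xml(slide, slide_path)
  files <- list.files(exdir, recursive = TRUE, all.files = TRUE,
                      no.. = TRUE)
  entries <- lapply(file.path(exdir, files), function(p) {
    readBin(p, "raw", file.size(p))
  })
  names(entries) <- files
  broken <- tempfile(fileext = ".pptx")
  pathcanvas:::zip_write(broken, entries)
  unlink(exdir, recursive = TRUE)
  rep <- verify_export(broken)
  expect_false(rep$ok)
  expect_gte(rep$dangling_refs, 1L)
})

test_that("unreadable files are rejected", {
  junk <- tempfile(fileext = ".pptx")
  writeLines("this is not a zip archive", junk)
  expect_error(verify_export(junk), "unreadable export")
})
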