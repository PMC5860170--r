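test_that("diagram documents round-trip through JSON byte-stably", {
  doc <- generate_diagram(fixture_spec(seed = 3))
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_diagram(doc, f1)
  doc2 <- read_diagram(f1)
  write_diagram(doc2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(doc2$diagram, doc$diagram)
  expect_equal(doc2$subpathways$groups, doc$subpathways$groups)
})

test_that("a 1000-node document survives the round trip", {
  spec <- fixture_spec(seed = 5, n_nodes = 1000, n_reactions = 200,
                       n_subpathways = 8, canvas = rect(0, 0, 6000, 4200))
  doc <- generate_diagram(spec)
  f <- tempfile(fileext = ".json")
  write_diagram(doc, f)
  doc2 <- read_diagram(f)
  expect_length(doc2$diagram$nodes, 1000L)
  expect_equal(doc2$diagram, doc$diagram)
})

test_that("invalid and malformed diagram files are rejected with context", {
  doc <- generate_diagram(fixture_spec(seed = 2))
  doc$diagram$edges[[1]]$connectors[[1]]$node_id <- "MISSING"
  f <- tempfile(fileext = ".json")
  pathcanvas:::write_json_canonical(
    pathcanvas:::diagram_doc_to_json(doc), f)
  expect_error(read_diagram(f), "invalid diagram")

  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_diagram(bad), "malformed diagram file")

  expect_error(read_diagram(tempfile()), "no such file")
})

test_that("unknown top-level keys survive the round trip", {
  doc <- generate_diagram(fixture_spec(seed = 2))
  doc$extra <- list(curatorNote = "drawn by hand")
  f <- tempfile(fileext = ".json")
  write_diagram(doc, f)
  doc2 <- read_diagram(f)
  expect_identical(doc2$extra$curatorNote, "drawn by hand")
})

test_that("hierarchies round-trip and cyclic files are rejected", {
  root <- generate_hierarchy(fixture_spec(seed = 11), n_entries = 85)
  expect_length(pathcanvas:::hierarchy_ids(root), 85L)
  f <- tempfile(fileext = ".json")
  write_hierarchy(root, f)
  expect_equal(read_hierarchy(f), root)

  cyc <- tempfile(fileext = ".json")
  writeLines(paste0(
    '{"stableId":"H1","name":"r","kind":"higher_level","children":',
    '[{"stableId":"H1","name":"r","kind":"lower_level","children":[]}]}'),
    cyc)
  expect_error(read_hierarchy(cyc), "hierarchy cycle")
})

test_that("rendered SVG is well-formed, namespaced, and id-bijective", {
  d <- tiny_diagram()
  svg <- render_svg(d, zoom = 1)
  doc <- xml2::read_xml(svg)  # would throw on malformed XML
  expect_identical(xml2::xml_ns(doc)[[1]], "http://www.w3.org/2000/svg")
  ids <- xml2::xml_attr(xml2::xml_find_all(doc, "//*[@id]"), "id")
  expect_setequal(ids, c("A", "B", "C", "R1"))
})

test_that("entity text is omitted below the zoom threshold", {
  d <- tiny_diagram()
  at_zoom <- function(z) {
    doc <- xml2::read_xml(render_svg(d, zoom = z))
    length(xml2::xml_find_all(doc, "//*[local-name() = 'text']"))
  }
  expect_gt(at_zoom(1), 0L)
  expect_identical(at_zoom(0.3), 0L)
})

test_that("highlight boxes are drawn beneath nodes in document order", {
  doc <- generate_diagram(fixture_spec(seed = 4, n_subpathways = 2))
  boxes <- highlight_diagram(doc$diagram, doc$subpathways)
  svg <- render_svg(doc$diagram, highlights = boxes, zoom = 0.3)
  x <- xml2::read_xml(svg)
  all_els <- xml2::xml_find_all(x, "//*")
  classes <- xml2::xml_attr(all_els, "class")
  box_pos <- which(classes == "highlight-box")
  node_pos <- which(classes == "node")
  expect_length(box_pos, 2L)
  expect_true(max(box_pos) < min(node_pos))
})

test_that("thumbnails scale to the long edge, keep aspect, drop text", {
  d <- tiny_diagram()
  d$canvas <- rect(0, 0, 1000, 500)
  t1 <- xml2::read_xml(render_thumbnail(d, 100))
  expect_identical(xml2::xml_attr(t1, "width"), "100")
  expect_identical(xml2::xml_attr(t1, "height"), "50")
  expect_identical(xml2::xml_attr(t1, "viewBox"), "0 0 1000 500")
  expect_length(xml2::xml_find_all(t1, "//*[local-name() = 'text']"), 0L)

  set.seed(9)
  for (i in 1:20) {
    w <- runif(1, 50, 3000)
    h <- runif(1, 50, 3000)
    d$canvas <- rect(0, 0, w, h)
    tn <- xml2::read_xml(render_thumbnail(d, 120))
    tw <- as.numeric(xml2::xml_attr(tn, "width"))
    th <- as.numeric(xml2::xml_attr(tn, "height"))
    expect_equal(max(tw, th), 120, tolerance = 1e-6)
    expect_equal(tw / th, w / h, tolerance = 1e-6)
  }
  expect_error(render_thumbnail(d, 15), "thumbnail too small")
})
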