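test_that("rect_union returns the smallest containing rectangle", {
  r <- rect(0, 0, 10, 10)
  expect_true(pathcanvas:::rect_equal(rect_union(list(r)), r))
  u <- rect_union(list(rect(0, 0, 10, 10), rect(20, 20, 10, 10)))
  expect_equal(c(u$x, u$y, u$w, u$h), c(0, 0, 30, 30))
  expect_error(rect_union(list()), "empty union")
})

test_that("rect_union contains every input, is idempotent and order-invariant", {
  set.seed(41)
  for (rep in 1:10) {
    rs <- lapply(1:50, function(i) {
      rect(runif(1, -50, 50), runif(1, -50, 50), runif(1, 0.1, 30),
           runif(1, 0.1, 30))
    })
    u <- rect_union(rs)
    for (r in rs) {
      expect_true(pathcanvas:::rect_contains_rect(u, r))
    }
    expect_true(pathcanvas:::rect_equal(rect_union(list(u)), u))
    perm <- sample(length(rs))
    expect_true(pathcanvas:::rect_equal(rect_union(rs[perm]), u))
  }
})

test_that("rect rejects degenerate input", {
  expect_error(rect(0, 0, -1, 5), "negative")
  expect_error(rect(0, NA, 1, 1), "finite")
})

test_that("a well-formed diagram validates cleanly", {
  expect_identical(validate_diagram(tiny_diagram()), character(0))
})

test_that("violations name the offending element", {
  d <- tiny_diagram()
  d$edges[[1]]$connectors[[1]]$node_id <- "X"
  v <- validate_diagram(d)
  expect_length(grep("'X'", v), 1L)

  d2 <- tiny_diagram()
  d2$nodes[[1]]$bounds <- rect(390, 100, 60, 40)  # spills past canvas
  v2 <- validate_diagram(d2)
  expect_true(any(grepl("'A'.*outside canvas", v2)))
})

test_that("role/ending compatibility and connector termination are enforced", {
  d <- tiny_diagram()
  d$edges[[1]]$connectors[[1]]$ending <- "arrow"  # arrow on an input
  expect_true(any(grepl("ending 'arrow' not allowed for role 'input'",
                        validate_diagram(d))))

  d2 <- tiny_diagram()
  d2$edges[[1]]$connectors[[2]]$points <- rbind(c(280, 120), c(300, 50))
  expect_true(any(grepl("ends .* from backbone", validate_diagram(d2))))

  d3 <- tiny_diagram()
  d3$edges[[1]]$connectors <- d3$edges[[1]]$connectors[-1]
  expect_true(any(grepl("no input connector", validate_diagram(d3))))
})

test_that("every generated fixture diagram validates cleanly", {
  for (seed in c(1, 17, 99)) {
    doc <- generate_diagram(fixture_spec(seed = seed))
    expect_identical(validate_diagram(doc$diagram), character(0))
    expect_identical(
      pathcanvas:::validate_assignment(doc$subpathways, doc$diagram),
      character(0))
  }
})

test_that("subpathway assignments reject overlap and empty groups", {
  expect_error(
    subpathway_assignment("P", list(S1 = c("R1", "R2"), S2 = "R2")),
    "more than one subpathway")
  expect_error(subpathway_assignment("P", list(S1 = character(0))),
               "empty reaction set")
})

test_that("hierarchy invariants hold: cycles rejected, leaves enforced", {
  root <- pathway_entry(
    "H1", "root", "higher_level",
    list(pathway_entry("H2", "mid", "higher_level",
                       list(pathway_entry("L1", "leaf", "lower_level")))))
  expect_silent(pathcanvas:::validate_hierarchy(root))
  expect_setequal(pathcanvas:::hierarchy_ids(root), c("H1", "H2", "L1"))

  expect_error(pathway_entry("L1", "leaf", "lower_level",
                             list(pathway_entry("L2", "x", "lower_level"))),
               "cannot have children")

  dup <- pathway_entry("H1", "root", "higher_level",
                       list(pathway_entry("H1", "again", "lower_level")))
  expect_error(pathcanvas:::validate_hierarchy(dup), "cycle at 'H1'")
})
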