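test_that("fade_alpha matches the linear ramp and its bounds", {
  expect_identical(fade_alpha(0.5), 1)
  expect_identical(fade_alpha(1.2), 0)
  expect_equal(fade_alpha(0.8), 0.5)
  expect_error(fade_alpha(1, fade_start = 1, fade_end = 1), "fade_start")

  set.seed(13)
  z <- sort(runif(1000, 0, 3))
  a <- fade_alpha(z)
  expect_true(all(a >= 0 & a <= 1))
  expect_true(all(diff(a) <= 1e-12))  # nonincreasing in zoom
})

test_that("palette colours are assigned cyclically and deterministically", {
  p <- color_profile("modern")
  expect_identical(assign_colors(1, p), p$subpathway_palette[1])
  n <- length(p$subpathway_palette) + 1L
  cols <- assign_colors(n, p)
  expect_identical(cols[n], cols[1])
  expect_identical(assign_colors(7, p), assign_colors(7, p))
})

test_that("compute_boxes pads the geometric union of member reactions", {
  a <- node_glyph("A", "protein", "A", rect(10, 10, 40, 20))
  b <- node_glyph("B", "protein", "B", rect(70, 20, 40, 40))
  rp <- c(60, 30)
  e <- reaction_edge(
    "R1", rp, rbind(c(30, 20), rp, c(90, 40)),
    list(connector("input", "A", rbind(c(30, 20), rp)),
         connector("output", "B", rbind(c(90, 40), rp), ending = "arrow")))
  d <- pathway_diagram("P", rect(0, 0, 200, 100), list(a, b), list(e))
  expect_identical(validate_diagram(d), character(0))
  asg <- subpathway_assignment("P", list(S1 = "R1"))

  # union of node bounds + all line points is (10,10,100,50)
  bx0 <- compute_boxes(d, asg, padding = 0)[[1]]$box
  expect_equal(c(bx0$x, bx0$y, bx0$w, bx0$h), c(10, 10, 100, 50))
  bx8 <- compute_boxes(d, asg, padding = 8)[[1]]$box
  expect_equal(c(bx8$x, bx8$y, bx8$w, bx8$h), c(2, 2, 116, 66))

  asg_bad <- subpathway_assignment("P", list(S1 = "NOPE"))
  expect_error(compute_boxes(d, asg_bad), "unresolvable reaction")
})

test_that("every member reaction lies inside its subpathway box", {
  for (seed in c(8, 21)) {
    doc <- generate_diagram(fixture_spec(seed = seed, n_reactions = 10,
                                         n_subpathways = 4))
    boxes <- compute_boxes(doc$diagram, doc$subpathways)
    names(boxes) <- vapply(boxes, `[[`, character(1), "subpathway_id")
    for (sid in names(doc$subpathways$groups)) {
      box <- boxes[[sid]]$box
      for (rid in doc$subpathways$groups[[sid]]) {
        e <- pathcanvas:::find_edge(doc$diagram, rid)
        pts <- rbind(e$segments, matrix(e$reaction_point, ncol = 2),
                     do.call(rbind, lapply(e$connectors, `[[`, "points")))
        for (i in seq_len(nrow(pts))) {
          expect_true(pathcanvas:::rect_contains_point(box, pts[i, 1],
                                                       pts[i, 2]))
        }
      }
    }
  }
})

test_that("maximal_empty_rectangles handles the canonical cases", {
  cont <- rect(0, 0, 10, 10)
  expect_true(rect_set_equal(maximal_empty_rectangles(cont, list()),
                             list(cont)))
  got <- maximal_empty_rectangles(cont, list(rect(4, 4, 2, 2)))
  expect_true(rect_set_equal(got, list(rect(0, 0, 10, 4), rect(0, 6, 10, 4),
                                       rect(0, 0, 4, 10),
                                       rect(6, 0, 4, 10))))
})

test_that("empty rectangles never intersect an obstacle interior", {
  set.seed(77)
  for (i in 1:25) {
    cont <- rect(0, 0, sample(8:20, 1), sample(8:20, 1))
    obs <- lapply(seq_len(sample(1:6, 1)), function(k) {
      rect(sample(0:15, 1), sample(0:15, 1), sample(1:6, 1),
           sample(1:6, 1))
    })
    for (r in maximal_empty_rectangles(cont, obs)) {
      for (o in obs) {
        ov <- pathcanvas:::rect_intersect(r, o)
        expect_null(ov)
      }
    }
  }
})

test_that("label placement follows the largest-and-widest rule", {
  mk_box <- function(id, r) {
    structure(list(subpathway_id = id, box = r, fill = "#FF000055",
                   label_text = "AB", label_rect = NULL, font_size = NULL),
              class = "highlight_box")
  }
  # alone: the label gets the whole box interior minus the margin
  solo <- mk_box("S1", rect(0, 0, 200, 100))
  placed <- place_label(solo, list(solo))
  expect_equal(c(placed$label_rect$x, placed$label_rect$y,
                 placed$label_rect$w, placed$label_rect$h),
               c(4, 4, 192, 92))
  expect_identical(placed$font_size, 24L)

  # fully covered by another box: no label
  top <- mk_box("S1", rect(0, 0, 50, 50))
  cover <- mk_box("S2", rect(-5, -5, 60, 60))
  expect_null(place_label(top, list(top, cover))$label_rect)

  # the worked half-overlap instance: label lands in the free lower half
  tgt <- mk_box("S1", rect(0, 0, 100, 40))
  other <- mk_box("S2", rect(0, 0, 100, 20))
  got <- place_label(tgt, list(tgt, other))
  expect_false(is.null(got$label_rect))
  expect_true(pathcanvas:::rect_contains_rect(rect(0, 20, 100, 20),
                                              got$label_rect))
  expect_gte(got$font_size, 8)
})

test_that("place_label is invariant under permutation of the box list", {
  doc <- generate_diagram(fixture_spec(seed = 31, n_reactions = 9,
                                       n_subpathways = 4))
  boxes <- compute_boxes(doc$diagram, doc$subpathways)
  set.seed(5)
  for (b in boxes) {
    ref <- place_label(b, boxes)
    for (k in 1:3) {
      perm <- place_label(b, boxes[sample(length(boxes))])
      expect_identical(perm$label_rect, ref$label_rect)
      expect_identical(perm$font_size, ref$font_size)
    }
  }
})

test_that("the full highlight computation is byte-stable across runs", {
  run <- function() {
    doc <- generate_diagram(fixture_spec(seed = 12))
    pathcanvas:::serialize_highlights(
      highlight_diagram(doc$diagram, doc$subpathways))
  }
  expect_identical(as.character(run()), as.character(run()))
})

test_that("degenerate single-point subpathways still get a box", {
  a <- node_glyph("A", "protein", "A", rect(40, 40, 20, 20))
  b <- node_glyph("B", "protein", "B", rect(40, 40, 20, 20))
  rp <- c(50, 50)
  e <- reaction_edge("R1", rp, rbind(rp, rp),
                     list(connector("input", "A", matrix(rp, ncol = 2)),
                          connector("output", "B", matrix(rp, ncol = 2))))
  d <- pathway_diagram("P", rect(0, 0, 100, 100), list(a, b), list(e))
  asg <- subpathway_assignment("P", list(S1 = "R1"))
  bx <- compute_boxes(d, asg, padding = 6)[[1]]$box
  expect_gt(bx$w, 0)
  expect_gt(bx$h, 0)
})
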