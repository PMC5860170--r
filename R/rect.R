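# Axis-aligned rectangles in canvas units.
#
# Convention used throughout the package: origin at the top-left corner,
# y grows downward, 1 canvas unit renders as 1 CSS pixel at zoom 1.
# Rect edges are closed intervals [x, x + w] x [y, y + h] for hit-testing;
# "interior" always means the open rectangle.

#' Create an axis-aligned rectangle
#'
#' @param x,y Canvas coordinates of the top-left corner (y grows downward).
#' @param w,h Width and height in canvas units; must be finite and
#'   non-negative (model invariants additionally require strictly positive
#'   extents for glyph bounds and the canvas, enforced by
#'   [validate_diagram()]).
#' @return An object of class `canvas_rect` with fields `x`, `y`, `w`, `h`.
#' @export
#' @examples
#' rect(0, 0, 100, 50)
rect <- function(x, y, w, h) {
  vals <- c(x = x, y = y, w = w, h = h)
  if (length(vals) != 4L || !all(is.finite(vals))) {
    stop("rect: all of x, y, w, h must be single finite numbers", call. = FALSE)
  }
  if (w < 0 || h < 0) {
    stop("rect: negative extent (w = ", w, ", h = ", h, ")", call. = FALSE)
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h)),
            class = "canvas_rect")
}

is_rect <- function(r) inherits(r, "canvas_rect")

#' @export
print.canvas_rect <- function(x, ...) {
  cat(sprintf("<rect x=%g y=%g w=%g h=%g>\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

#' @export
format.canvas_rect <- function(x, ...) {
  sprintf("(%g, %g, %g, %g)", x$x, x$y, x$w, x$h)
}

rect_x2 <- function(r) r$x + r$w
rect_y2 <- function(r) r$y + r$h

rect_equal <- function(a, b, tol = 1e-9) {
  abs(a$x - b$x) <= tol && abs(a$y - b$y) <= tol &&
    abs(a$w - b$w) <= tol && abs(a$h - b$h) <= tol
}

#' Smallest rectangle containing all inputs
#'
#' @param rects Non-empty list of rectangles created with [rect()].
#' @return The bounding `canvas_rect` of all inputs.
#' @export
#' @examples
#' rect_union(list(rect(0, 0, 10, 10), rect(20, 20, 10, 10)))
rect_union <- function(rects) {
  if (!is.list(rects) || length(rects) == 0L) {
    stop("empty union", call. = FALSE)
  }
  stopifnot(all(vapply(rects, is_rect, logical(1))))
  x1 <- min(vapply(rects, function(r) r$x, numeric(1)))
  y1 <- min(vapply(rects, function(r) r$y, numeric(1)))
  x2 <- max(vapply(rects, rect_x2, numeric(1)))
  y2 <- max(vapply(rects, rect_y2, numeric(1)))
  rect(x1, y1, x2 - x1, y2 - y1)
}

# Intersection with positive area, or NULL when the interiors are disjoint.
rect_intersect <- function(a, b) {
  x1 <- max(a$x, b$x)
  y1 <- max(a$y, b$y)
  x2 <- min(rect_x2(a), rect_x2(b))
  y2 <- min(rect_y2(a), rect_y2(b))
  if (x2 - x1 <= 0 || y2 - y1 <= 0) return(NULL)
  rect(x1, y1, x2 - x1, y2 - y1)
}

# Closed-interval point containment (edges included).
rect_contains_point <- function(r, x, y) {
  x >= r$x && x <= rect_x2(r) && y >= r$y && y <= rect_y2(r)
}

# TRUE when inner lies entirely within outer (closed comparison).
rect_contains_rect <- function(outer, inner, tol = 1e-9) {
  inner$x >= outer$x - tol && inner$y >= outer$y - tol &&
    rect_x2(inner) <= rect_x2(outer) + tol &&
    rect_y2(inner) <= rect_y2(outer) + tol
}

# TRUE when inner is strictly inside outer (no shared edges).
rect_strictly_inside <- function(outer, inner) {
  inner$x > outer$x && inner$y > outer$y &&
    rect_x2(inner) < rect_x2(outer) && rect_y2(inner) < rect_y2(outer)
}

# Grow (or shrink, with negative pad) by the same margin on all four sides.
rect_pad <- function(r, pad) {
  w <- r$w + 2 * pad
  h <- r$h + 2 * pad
  if (w <= 0 || h <= 0) return(NULL)
  rect(r$x - pad, r$y - pad, w, h)
}

# Clip r to the clip rectangle; NULL when nothing with positive area remains.
rect_clip <- function(r, clip) rect_intersect(r, clip)

rect_area <- function(r) r$w * r$h

rect_centre <- function(r) c(r$x + r$w / 2, r$y + r$h / 2)

# Distance from point p = c(x, y) to the segment a--b.
point_segment_dist <- function(p, a, b) {
  d <- b - a
  len2 <- sum(d * d)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * d) / len2))
  sqrt(sum((p - (a + t * d))^2))
}

# Minimum distance from a point to a polyline given as a 2-column matrix.
point_polyline_dist <- function(p, pts) {
  if (nrow(pts) == 1L) return(sqrt(sum((p - pts[1, ])^2)))
  dmin <- Inf
  for (i in seq_len(nrow(pts) - 1L)) {
    dmin <- min(dmin, point_segment_dist(p, pts[i, ], pts[i + 1L, ]))
  }
  dmin
}
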