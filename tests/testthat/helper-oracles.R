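# Independent oracles used to cross-check the package implementations.
# Each one is deliberately brute force: correctness over speed.

# --- maximal empty rectangles: exhaustive grid enumeration ------------------
# Every maximal empty rectangle has its edges on the coordinate-compressed
# grid. Enumerate all grid rectangles, keep the empty ones, and keep those
# that cannot be extended by one grid step in any direction (equivalent to
# not being contained in a larger empty rectangle, since the one-step
# extension of a contained rectangle is itself inside the container).
mer_oracle <- function(container, obstacles) {
  cx1 <- container$x
  cy1 <- container$y
  cx2 <- container$x + container$w
  cy2 <- container$y + container$h
  ox1 <- numeric(0); oy1 <- numeric(0); ox2 <- numeric(0); oy2 <- numeric(0)
  for (o in obstacles) {
    x1 <- max(o$x, cx1); y1 <- max(o$y, cy1)
    x2 <- min(o$x + o$w, cx2); y2 <- min(o$y + o$h, cy2)
    if (x2 > x1 && y2 > y1) {
      ox1 <- c(ox1, x1); oy1 <- c(oy1, y1)
      ox2 <- c(ox2, x2); oy2 <- c(oy2, y2)
    }
  }
  xs <- sort(unique(c(cx1, cx2, ox1, ox2)))
  ys <- sort(unique(c(cy1, cy2, oy1, oy2)))
  empty <- function(x1, y1, x2, y2) {
    !any(ox1 < x2 & ox2 > x1 & oy1 < y2 & oy2 > y1)
  }
  out <- list()
  for (i in seq_len(length(xs) - 1L)) {
    for (j in seq(i + 1L, length(xs))) {
      for (k in seq_len(length(ys) - 1L)) {
        for (l in seq(k + 1L, length(ys))) {
          x1 <- xs[i]; x2 <- xs[j]; y1 <- ys[k]; y2 <- ys[l]
          if (!empty(x1, y1, x2, y2)) next
          extendable <-
            (i > 1L && empty(xs[i - 1L], y1, x2, y2)) ||
            (j < length(xs) && empty(x1, y1, xs[j + 1L], y2)) ||
            (k > 1L && empty(x1, ys[k - 1L], x2, y2)) ||
            (l < length(ys) && empty(x1, y1, x2, ys[l + 1L]))
          if (!extendable) {
            out[[length(out) + 1L]] <- rect(x1, y1, x2 - x1, y2 - y1)
          }
        }
      }
    }
  }
  out
}

rect_key <- function(r) sprintf("%.6f|%.6f|%.6f|%.6f", r$x, r$y, r$w, r$h)

rect_set_equal <- function(a, b) {
  setequal(vapply(a, rect_key, character(1)),
           vapply(b, rect_key, character(1)))
}

# --- hypergeometric upper tail by direct combinatorial summation ------------
hyper_tail_oracle <- function(found, total, universe, draws) {
  ks <- found:min(total, draws)
  ks <- ks[draws - ks <= universe - total & ks >= 0]
  if (length(ks) == 0L) return(0)
  sum(choose(total, ks) * choose(universe - total, draws - ks)) /
    choose(universe, draws)
}

# --- Benjamini-Hochberg step-up straight from the definition ----------------
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# --- XML canonicalization for document comparisons --------------------------
canon_xml <- function(txt) as.character(xml2::read_xml(txt))
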