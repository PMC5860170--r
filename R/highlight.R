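# Subpathway highlight boxes and label placement.
#
# Each subpathway of a classic diagram gets a coloured box: the padded
# bounding rectangle of all geometry of its member reactions. The label is
# placed inside the box in the largest (then widest) empty rectangle left
# after overlapping the box with all other subpathway boxes — a space
# partitioning search over maximal empty rectangles. Everything here is
# deterministic: boxes and labels are meant to be precomputed once per data
# release and reused unchanged for its whole lifetime.

#' Approximate font metric model for label fitting
#'
#' Deterministic, device-independent text metrics: every character advances
#' `char_width` x font size, a line occupies `line_height` x font size, and
#' text is wrapped greedily at word boundaries. Real font metrics vary per
#' renderer; a fixed approximation keeps label placement reproducible across
#' machines.
#'
#' @param char_width Advance width per character, as a fraction of font size
#'   (default 0.6).
#' @param line_height Line height as a fraction of font size (default 1.2).
#' @param margin Inner margin between the candidate rectangle and the text,
#'   in canvas units (default 4).
#' @param max_font Largest font size tried, in points (default 24).
#' @return A `font_model` object.
#' @export
font_model <- function(char_width = 0.6, line_height = 1.2, margin = 4,
                       max_font = 24) {
  stopifnot(char_width > 0, line_height > 0, margin >= 0, max_font > 0)
  structure(list(char_width = char_width, line_height = line_height,
                 margin = margin, max_font = max_font),
            class = "font_model")
}

# Greedy word wrap of text into a w x h box at the given font size.
# Returns TRUE when every line fits horizontally and all lines fit
# vertically; a single word wider than the box fails.
text_fits <- function(text, w, h, size, fm) {
  words <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(words) == 0L) return(TRUE)
  cw <- fm$char_width * size
  max_chars <- floor(w / cw)
  if (max_chars < 1L) return(FALSE)
  if (max(nchar(words)) > max_chars) return(FALSE)
  lines <- 1L
  cur <- nchar(words[1])
  for (wd in words[-1]) {
    if (cur + 1L + nchar(wd) <= max_chars) {
      cur <- cur + 1L + nchar(wd)
    } else {
      lines <- lines + 1L
      cur <- nchar(wd)
    }
  }
  lines * fm$line_height * size <= h
}

#' Highlight fade opacity as a function of zoom
#'
#' Highlight boxes are fully opaque in zoomed-out views and fade out
#' linearly as the user zooms in, vanishing at `fade_end`:
#' 1 for `zoom <= fade_start`, 0 for `zoom >= fade_end`, linear in between.
#'
#' @param zoom Zoom factor(s), > 0.
#' @param fade_start Zoom at which fading begins (default 0.6).
#' @param fade_end Zoom at which boxes are fully transparent (default 1.0).
#' @return Opacity value(s) in \[0, 1\], nonincreasing in `zoom`.
#' @export
#' @examples
#' fade_alpha(c(0.5, 0.8, 1.2))
fade_alpha <- function(zoom, fade_start = 0.6, fade_end = 1.0) {
  if (fade_start >= fade_end) {
    stop("fade_start must be < fade_end", call. = FALSE)
  }
  pmin(1, pmax(0, (fade_end - zoom) / (fade_end - fade_start)))
}

#' Assign palette colours to subpathways
#'
#' Colours are drawn cyclically from the profile's subpathway palette, so
#' the assignment for a given number of subpathways (taken in sorted id
#' order by the callers) is always the same — the precomputed look of a
#' diagram must not change between runs.
#'
#' @param n Number of colours needed (>= 1).
#' @param profile A [color_profile()].
#' @return Character vector of `n` colours.
#' @export
assign_colors <- function(n, profile = color_profile()) {
  stopifnot(n >= 1)
  pal <- profile$subpathway_palette
  pal[((seq_len(n) - 1L) %% length(pal)) + 1L]
}

# All geometry of one reaction: backbone points, reaction point, connector
# points, plus the bounds of every participating node.
reaction_geometry_rects <- function(diagram, edge) {
  rects <- list(point_rect(edge$reaction_point))
  pts <- edge$segments
  for (cn in edge$connectors) {
    pts <- rbind(pts, cn$points)
    nd <- find_node(diagram, cn$node_id)
    if (!is.null(nd)) rects <- c(rects, list(nd$bounds))
  }
  for (i in seq_len(nrow(pts))) {
    rects <- c(rects, list(point_rect(pts[i, ])))
  }
  rects
}

point_rect <- function(p) rect(p[1], p[2], 0, 0)

#' Compute subpathway highlight boxes (labels not yet placed)
#'
#' One box per subpathway: the bounding rectangle of all backbone points,
#' connector points and participating node bounds of the subpathway's member
#' reactions, grown by `padding` on all sides and clipped to the canvas.
#' Colours come from [assign_colors()] over subpathways in sorted id order,
#' so the result is fully deterministic.
#'
#' @param diagram A valid [pathway_diagram()].
#' @param assignment A [subpathway_assignment()] for this diagram.
#' @param padding Box padding in canvas units (default 8).
#' @param profile A [color_profile()].
#' @return List of `highlight_box` objects (fields `subpathway_id`, `box`,
#'   `fill`, `label_text`; `label_rect`/`font_size` absent until
#'   [place_label()]).
#' @export
compute_boxes <- function(diagram, assignment, padding = 8,
                          profile = color_profile()) {
  stopifnot(inherits(assignment, "subpathway_assignment"), padding >= 0)
  sids <- sort(names(assignment$groups))
  cols <- assign_colors(length(sids), profile)
  boxes <- vector("list", length(sids))
  for (i in seq_along(sids)) {
    sid <- sids[i]
    rids <- assignment$groups[[sid]]
    edges <- lapply(rids, find_edge, diagram = diagram)
    if (any(vapply(edges, is.null, logical(1)))) {
      stop("subpathway '", sid, "': unresolvable reaction id(s): ",
           paste(rids[vapply(edges, is.null, logical(1))], collapse = ", "),
           call. = FALSE)
    }
    rects <- unlist(lapply(edges, reaction_geometry_rects,
                           diagram = diagram), recursive = FALSE)
    box <- rect_union(rects)
    if (padding > 0) box <- rect_pad(box, padding)
    if (box$w <= 0 || box$h <= 0) {
      # all geometry at a single point and no padding: keep a unit square
      box <- rect(box$x - 0.5, box$y - 0.5, 1, 1)
    }
    box <- rect_clip(box, diagram$canvas) %||% box
    boxes[[i]] <- structure(
      list(subpathway_id = sid, box = box, fill = cols[i],
           label_text = unname(assignment$display_names[sid]),
           label_rect = NULL, font_size = NULL),
      class = "highlight_box")
  }
  boxes
}

#' @export
print.highlight_box <- function(x, ...) {
  cat(sprintf("<highlight_box '%s' %s fill=%s%s>\n", x$subpathway_id,
              format(x$box), x$fill,
              if (!is.null(x$font_size)) {
                sprintf(" label@%s %gpt", format(x$label_rect), x$font_size)
              } else " (no label placed)"))
  invisible(x)
}

#' All maximal empty rectangles among obstacles
#'
#' Finds the complete set of maximal axis-aligned rectangles inside
#' `container` whose interiors intersect no obstacle interior ("maximal"
#' meaning not contained in any larger empty rectangle). The search sweeps
#' every pair of horizontal cut lines drawn from obstacle and container
#' edges and takes the maximal free x-intervals of each band; candidates
#' contained in another candidate are discarded. A maximal empty rectangle
#' necessarily has each edge pinned against an obstacle or the container
#' boundary, so the cut-line sweep finds all of them.
#'
#' @param container The bounding [rect()] to search within.
#' @param obstacles List of [rect()] obstacles (clipped to the container
#'   internally; zero-area obstacles are ignored).
#' @return List of maximal empty `canvas_rect`s (the container itself when
#'   there are no obstacles).
#' @export
maximal_empty_rectangles <- function(container, obstacles = list()) {
  stopifnot(is_rect(container))
  obs <- list()
  for (o in obstacles) {
    oc <- rect_clip(o, container)
    if (!is.null(oc)) obs[[length(obs) + 1L]] <- oc
  }
  if (length(obs) == 0L) return(list(container))
  ys <- sort(unique(c(container$y, rect_y2(container),
                      vapply(obs, function(o) o$y, numeric(1)),
                      vapply(obs, rect_y2, numeric(1)))))
  ox1 <- vapply(obs, function(o) o$x, numeric(1))
  ox2 <- vapply(obs, rect_x2, numeric(1))
  oy1 <- vapply(obs, function(o) o$y, numeric(1))
  oy2 <- vapply(obs, rect_y2, numeric(1))
  cands <- list()
  for (i in seq_len(length(ys) - 1L)) {
    for (j in seq(i + 1L, length(ys))) {
      yt <- ys[i]; yb <- ys[j]
      # obstacles whose interiors overlap the open band (yt, yb)
      hit <- oy1 < yb & oy2 > yt
      for (iv in free_intervals(container$x, rect_x2(container),
                                ox1[hit], ox2[hit])) {
        cands[[length(cands) + 1L]] <- rect(iv[1], yt, iv[2] - iv[1],
                                            yb - yt)
      }
    }
  }
  # drop duplicates and candidates contained in another candidate
  keep <- rep(TRUE, length(cands))
  for (a in seq_along(cands)) {
    if (!keep[a]) next
    for (b in seq_along(cands)) {
      if (a == b || !keep[b]) next
      if (rect_contains_rect(cands[[b]], cands[[a]], tol = 0)) {
        if (rect_equal(cands[[a]], cands[[b]], tol = 0)) {
          if (a > b) { keep[a] <- FALSE; break }
        } else {
          keep[a] <- FALSE
          break
        }
      }
    }
  }
  cands[keep]
}

# Maximal free x-intervals of [x1, x2] after removing [bx1, bx2] blocks.
free_intervals <- function(x1, x2, bx1, bx2) {
  if (length(bx1) == 0L) {
    return(if (x2 > x1) list(c(x1, x2)) else list())
  }
  ord <- order(bx1)
  bx1 <- pmax(bx1[ord], x1)
  bx2 <- pmin(bx2[ord], x2)
  out <- list()
  cur <- x1
  for (k in seq_along(bx1)) {
    if (bx1[k] > cur) out[[length(out) + 1L]] <- c(cur, bx1[k])
    cur <- max(cur, bx2[k])
  }
  if (cur < x2) out[[length(out) + 1L]] <- c(cur, x2)
  out
}

#' Place a subpathway label inside its highlight box
#'
#' Implements the space-partitioning placement rule: the label goes into the
#' largest, then widest, empty rectangle of its own box after accounting for
#' the overlap with every other subpathway box. Ties beyond width are broken
#' topmost, then leftmost. The chosen rectangle is shrunk by the font
#' model's inner margin, and the label text is fitted at the largest font
#' size (whole points, descending from `font_model$max_font`) at which the
#' greedily word-wrapped text fits. If no size `>= min_font` fits, the label
#' is omitted (`label_rect`/`font_size` stay `NULL`).
#'
#' @param target The `highlight_box` to label (must be one of `all_boxes`).
#' @param all_boxes All highlight boxes of the diagram.
#' @param fm A [font_model()].
#' @param min_font Minimum legible font size in points (default 8).
#' @return `target` with `label_rect` and `font_size` filled in (or left
#'   `NULL` when the label cannot be placed legibly).
#' @export
place_label <- function(target, all_boxes, fm = font_model(), min_font = 8) {
  others <- Filter(function(b) !identical(b$subpathway_id,
                                          target$subpathway_id), all_boxes)
  obstacles <- list()
  for (b in others) {
    ov <- rect_intersect(b$box, target$box)
    if (!is.null(ov)) obstacles[[length(obstacles) + 1L]] <- ov
  }
  cands <- maximal_empty_rectangles(target$box, obstacles)
  if (length(cands) == 0L) return(target)
  # largest and widest: primary area, then width, then topmost, leftmost
  ord <- order(-vapply(cands, rect_area, numeric(1)),
               -vapply(cands, function(r) r$w, numeric(1)),
               vapply(cands, function(r) r$y, numeric(1)),
               vapply(cands, function(r) r$x, numeric(1)))
  best <- cands[[ord[1]]]
  inner <- rect_pad(best, -fm$margin)
  if (is.null(inner)) return(target)
  for (size in rev(seq.int(ceiling(min_font), floor(fm$max_font)))) {
    if (text_fits(target$label_text, inner$w, inner$h, size, fm)) {
      target$label_rect <- inner
      target$font_size <- size
      return(target)
    }
  }
  target
}

#' Compute highlight boxes and place all labels
#'
#' Convenience wrapper: [compute_boxes()] followed by [place_label()] for
#' every subpathway.
#'
#' @inheritParams compute_boxes
#' @inheritParams place_label
#' @return List of fully labelled `highlight_box` objects.
#' @export
highlight_diagram <- function(diagram, assignment, padding = 8,
                              profile = color_profile(), fm = font_model(),
                              min_font = 8) {
  boxes <- compute_boxes(diagram, assignment, padding, profile)
  lapply(boxes, place_label, all_boxes = boxes, fm = fm,
         min_font = min_font)
}

# Canonical serialization of highlight boxes (the precomputed release
# artefact); used by tests and the CLI to assert byte-stable determinism.
serialize_highlights <- function(boxes) {
  jsonlite::toJSON(lapply(boxes, function(b) {
    o <- list(subpathwayId = b$subpathway_id, box = rect_to_json(b$box),
              fill = b$fill, labelText = b$label_text)
    if (!is.null(b$label_rect)) {
      o$labelRect <- rect_to_json(b$label_rect)
      o$fontSize <- b$font_size
    }
    o
  }), auto_unbox = TRUE, digits = NA, pretty = 2)
}
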