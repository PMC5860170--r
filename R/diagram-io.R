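# Reading and writing of the exchange formats: the diagram JSON schema,
# pathway hierarchy JSON, and SVG output for classic diagrams + thumbnails.
#
# The JSON schema is documented in docs/format-diagram.md. Serialization is
# canonical (fixed key order, 2-space indent), which makes round trips
# byte-stable.

DIAGRAM_SCHEMA_VERSION <- 1L

#' Create a diagram document
#'
#' A document wraps a [pathway_diagram()] together with an optional
#' [subpathway_assignment()] and a schema version, mirroring one diagram
#' JSON file on disk.
#'
#' @param diagram A valid [pathway_diagram()].
#' @param subpathways Optional [subpathway_assignment()] for this diagram.
#' @param schema_version Integer schema version (currently 1).
#' @param extra Named list of unknown top-level keys preserved for
#'   round-tripping.
#' @return A `diagram_document`.
#' @export
diagram_document <- function(diagram, subpathways = NULL,
                             schema_version = DIAGRAM_SCHEMA_VERSION,
                             extra = list()) {
  structure(list(schema_version = as.integer(schema_version),
                 diagram = diagram, subpathways = subpathways,
                 extra = extra),
            class = "diagram_document")
}

#' @export
print.diagram_document <- function(x, ...) {
  cat(sprintf("<diagram_document v%d>\n", x$schema_version))
  print(x$diagram)
  if (!is.null(x$subpathways)) {
    cat(sprintf("  + %d subpathway group(s)\n", length(x$subpathways$groups)))
  }
  invisible(x)
}

rect_to_json <- function(r) list(x = r$x, y = r$y, w = r$w, h = r$h)
rect_from_json <- function(j) rect(j$x, j$y, j$w, j$h)

points_to_json <- function(pts) {
  lapply(seq_len(nrow(pts)), function(i) list(x = pts[i, 1], y = pts[i, 2]))
}

points_from_json <- function(j) {
  # read_json gives either a list of {x, y} or (simplified) a data.frame
  if (is.data.frame(j)) return(as_points(as.matrix(j[, c("x", "y")])))
  as_points(do.call(rbind, lapply(j, function(p) c(p$x, p$y))))
}

#' Read a diagram JSON file
#'
#' @param path Path to a diagram JSON file (UTF-8).
#' @return A `diagram_document` whose diagram passes [validate_diagram()].
#'   Unknown top-level keys are preserved and written back by
#'   [write_diagram()].
#' @export
read_diagram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop("malformed diagram file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  known <- c("schemaVersion", "pathwayId", "canvas", "nodes", "edges",
             "compartments", "subpathways")
  if (is.null(raw$schemaVersion) ||
      raw$schemaVersion > DIAGRAM_SCHEMA_VERSION) {
    stop("unsupported diagram schema version: ",
         raw$schemaVersion %||% "<missing>", call. = FALSE)
  }
  nodes <- lapply(raw$nodes, function(n) {
    node_glyph(n$id, n$schemaClass, n$displayName, rect_from_json(n$bounds),
               compartment_id = n$compartmentId)
  })
  edges <- lapply(raw$edges, function(e) {
    reaction_edge(
      e$id, c(e$reactionPoint$x, e$reactionPoint$y),
      points_from_json(e$segments),
      lapply(e$connectors, function(cn) {
        connector(cn$role, cn$nodeId, points_from_json(cn$points),
                  ending = cn$ending %||% "none")
      }))
  })
  compartments <- lapply(raw$compartments, function(cp) {
    compartment(cp$id, cp$name, rect_from_json(cp$outer),
                inner = if (!is.null(cp$inner)) rect_from_json(cp$inner))
  })
  diagram <- pathway_diagram(raw$pathwayId, rect_from_json(raw$canvas),
                             nodes, edges, compartments)
  subpathways <- NULL
  if (!is.null(raw$subpathways)) {
    sp <- raw$subpathways
    subpathways <- subpathway_assignment(
      sp$parentPathwayId %||% raw$pathwayId,
      lapply(sp$groups, function(g) unlist(g)),
      display_names = unlist(sp$displayNames))
  }
  violations <- validate_diagram(diagram)
  if (!is.null(subpathways)) {
    violations <- c(violations, validate_assignment(subpathways, diagram))
  }
  if (length(violations)) {
    stop("invalid diagram '", path, "':\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  diagram_document(diagram, subpathways,
                   schema_version = raw$schemaVersion,
                   extra = raw[setdiff(names(raw), known)])
}

diagram_doc_to_json <- function(doc) {
  d <- doc$diagram
  out <- list(
    schemaVersion = doc$schema_version,
    pathwayId = d$pathway_id,
    canvas = rect_to_json(d$canvas),
    nodes = lapply(d$nodes, function(n) {
      o <- list(id = n$id, schemaClass = n$schema_class,
                displayName = n$display_name,
                bounds = rect_to_json(n$bounds))
      if (!is.null(n$compartment_id)) o$compartmentId <- n$compartment_id
      o
    }),
    edges = lapply(d$edges, function(e) {
      list(id = e$id,
           reactionPoint = list(x = e$reaction_point[1],
                                y = e$reaction_point[2]),
           segments = points_to_json(e$segments),
           connectors = lapply(e$connectors, function(cn) {
             list(role = cn$role, nodeId = cn$node_id,
                  points = points_to_json(cn$points), ending = cn$ending)
           }))
    }),
    compartments = lapply(d$compartments, function(cp) {
      o <- list(id = cp$id, name = cp$name, outer = rect_to_json(cp$outer))
      if (!is.null(cp$inner)) o$inner <- rect_to_json(cp$inner)
      o
    })
  )
  if (!is.null(doc$subpathways)) {
    sp <- doc$subpathways
    ord <- order(names(sp$groups))
    out$subpathways <- list(
      parentPathwayId = sp$parent_pathway_id,
      groups = lapply(sp$groups[ord], as.list),
      displayNames = as.list(sp$display_names[names(sp$groups)[ord]])
    )
  }
  if (length(doc$extra)) out <- c(out, doc$extra[order(names(doc$extra))])
  out
}

#' Write a diagram document as canonical JSON
#'
#' The inverse of [read_diagram()]: `read_diagram(write_diagram(doc, f))`
#' reproduces the model exactly, and writing the same document twice gives
#' byte-identical files.
#'
#' @param doc A `diagram_document`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(doc, path) {
  stopifnot(inherits(doc, "diagram_document"))
  violations <- validate_diagram(doc$diagram)
  if (length(violations)) {
    stop("refusing to write invalid diagram:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  write_json_canonical(diagram_doc_to_json(doc), path)
  invisible(path)
}

write_json_canonical <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = 2,
                          null = "null")
  writeLines(txt, path, useBytes = TRUE)
}

#' Read a pathway hierarchy JSON file
#'
#' The file holds one rooted tree of entries
#' `{stableId, name, kind, children}`; `kind` is `"higher_level"` or
#' `"lower_level"`, and lower-level entries are leaves. A child naming one
#' of its ancestors is rejected as a cycle.
#'
#' @param path Path to a hierarchy JSON file.
#' @return The root `pathway_entry`.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop("malformed hierarchy file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  build <- function(j, ancestors) {
    if (j$stableId %in% ancestors) {
      stop("hierarchy cycle at '", j$stableId, "'", call. = FALSE)
    }
    pathway_entry(j$stableId, j$name, j$kind,
                  children = lapply(j$children %||% list(), build,
                                    ancestors = c(ancestors, j$stableId)))
  }
  root <- build(raw, character(0))
  validate_hierarchy(root)
  root
}

#' Write a pathway hierarchy as canonical JSON
#'
#' @param root Root [pathway_entry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(root, path) {
  validate_hierarchy(root)
  to_json <- function(e) {
    o <- list(stableId = e$stable_id, name = e$name, kind = e$kind)
    o$children <- lapply(e$children, to_json)
    o
  }
  write_json_canonical(to_json(root), path)
  invisible(path)
}

svg_root <- function(viewbox, width, height) {
  root <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg", version = "1.1",
    viewBox = paste(viewbox, collapse = " "),
    width = fmt_num(width), height = fmt_num(height))
  root
}

fmt_num <- function(x) {
  vapply(x, function(v) trimws(formatC(v, format = "g", digits = 10)),
         character(1))
}

svg_points_attr <- function(pts) {
  paste(paste(fmt_num(pts[, 1]), fmt_num(pts[, 2]), sep = ","),
        collapse = " ")
}

add_rect_el <- function(parent, r, ..., id = NULL) {
  args <- list(.value = "rect", x = fmt_num(r$x), y = fmt_num(r$y),
               width = fmt_num(r$w), height = fmt_num(r$h), ...)
  if (!is.null(id)) args$id <- id
  do.call(xml2::xml_add_child, c(list(parent), args))
}

# glyph outline per schema class: proteins/rounded, chemicals/ellipse-like,
# process nodes/plain square — enough to echo SBGN conventions in fixtures
node_shape_attrs <- function(schema_class) {
  switch(schema_class,
         protein = list(rx = "6"),
         entity_set = list(rx = "10"),
         complex = list(rx = "2"),
         chemical = list(rx = "14"),
         list())
}

#' Render a classic diagram to SVG
#'
#' Produces one SVG element per compartment, reaction edge and node glyph,
#' each carrying its stable identifier as the element id. Z-order from back
#' to front: compartments, highlight boxes, edges, nodes, labels — highlight
#' boxes sit behind the molecular detail. When `zoom` is below
#' `label_zoom_threshold` (or `show_labels` is `FALSE`) entity text is
#' omitted, matching the zoomed-out rendering convention in which glyph text
#' disappears. Highlight boxes are drawn with opacity [fade_alpha()]`(zoom)`
#' so they fade away as the user zooms in.
#'
#' @param diagram A valid [pathway_diagram()].
#' @param profile A [color_profile()].
#' @param show_labels Draw entity/label text (subject to the zoom threshold).
#' @param highlights Optional list of highlight boxes from
#'   [highlight_diagram()].
#' @param zoom Zoom factor (> 0); scales the rendered width/height.
#' @param label_zoom_threshold Zoom below which entity text is omitted.
#' @param fade_start,fade_end Zoom interval over which highlight boxes fade
#'   out (passed to [fade_alpha()]).
#' @return SVG 1.1 document text.
#' @export
render_svg <- function(diagram, profile = color_profile(),
                       show_labels = TRUE, highlights = NULL, zoom = 1,
                       label_zoom_threshold = 0.5,
                       fade_start = 0.6, fade_end = 1.0) {
  stopifnot(zoom > 0)
  violations <- validate_diagram(diagram)
  if (length(violations)) {
    stop("cannot render invalid diagram:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  cv <- diagram$canvas
  root <- svg_root(c(cv$x, cv$y, cv$w, cv$h), cv$w * zoom, cv$h * zoom)
  draw_text <- show_labels && zoom >= label_zoom_threshold

  g_comp <- xml2::xml_add_child(root, "g", class = "compartments")
  for (cp in diagram$compartments) {
    g <- xml2::xml_add_child(g_comp, "g", id = cp$id, class = "compartment")
    add_rect_el(g, cp$outer, fill = "#F5F2D8", stroke = "#B0A46A",
                "stroke-width" = "2")
    if (!is.null(cp$inner)) {
      add_rect_el(g, cp$inner, fill = "none", stroke = "#B0A46A",
                  "stroke-width" = "1")
    }
    if (draw_text) {
      xml2::xml_add_child(g, "text", x = fmt_num(cp$outer$x + 6),
                          y = fmt_num(cp$outer$y + 16),
                          class = "compartment-label", cp$name)
    }
  }

  if (!is.null(highlights) && length(highlights)) {
    alpha <- fade_alpha(zoom, fade_start, fade_end)
    g_hl <- xml2::xml_add_child(root, "g", class = "subpathway-highlights")
    if (alpha > 0) {
      for (hb in highlights) add_highlight_el(g_hl, hb, alpha)
    }
  }

  g_edges <- xml2::xml_add_child(root, "g", class = "edges")
  for (e in diagram$edges) draw_edge(g_edges, e)

  g_nodes <- xml2::xml_add_child(root, "g", class = "nodes")
  for (n in diagram$nodes) {
    g <- xml2::xml_add_child(g_nodes, "g", id = n$id, class = "node")
    attrs <- c(list(g, n$bounds,
                    fill = unname(profile$node_fill[n$schema_class]),
                    stroke = unname(profile$node_stroke[n$schema_class]),
                    "stroke-width" = "1.5"),
               node_shape_attrs(n$schema_class))
    do.call(add_rect_el, attrs)
    if (draw_text) {
      ctr <- rect_centre(n$bounds)
      xml2::xml_add_child(g, "text", x = fmt_num(ctr[1]), y = fmt_num(ctr[2]),
                          "text-anchor" = "middle",
                          "dominant-baseline" = "middle",
                          class = "entity-label", n$display_name)
    }
  }
  as.character(root)
}

add_highlight_el <- function(parent, hb, alpha) {
  g <- xml2::xml_add_child(parent, "g",
                           id = paste0("highlight-", hb$subpathway_id),
                           class = "highlight-box")
  fill <- color_svg(hb$fill)
  add_rect_el(g, hb$box, fill = fill$hex,
              "fill-opacity" = fmt_num(fill$opacity * alpha),
              stroke = fill$hex,
              "stroke-opacity" = fmt_num(min(1, fill$opacity * 2) * alpha),
              rx = "6")
  if (!is.null(hb$label_rect) && !is.null(hb$font_size)) {
    if (!is.null(hb$overlay_colour)) {
      oc <- color_svg(hb$overlay_colour)
      add_rect_el(g, hb$label_rect, fill = oc$hex,
                  "fill-opacity" = fmt_num(0.85 * alpha),
                  class = "analysis-overlay-rect")
    }
    xml2::xml_add_child(
      g, "text", x = fmt_num(hb$label_rect$x),
      y = fmt_num(hb$label_rect$y + hb$font_size),
      "font-size" = fmt_num(hb$font_size),
      "fill-opacity" = fmt_num(alpha),
      class = "highlight-label", hb$label_text)
    if (!is.null(hb$hit_bar) && hb$hit_bar$w > 0) {
      bc <- color_svg(hb$bar_colour %||% "#FFDD00")
      add_rect_el(g, hb$hit_bar, fill = bc$hex,
                  "fill-opacity" = fmt_num(alpha),
                  class = "analysis-hit-bar")
    }
    if (!is.null(hb$annotation)) {
      xml2::xml_add_child(
        g, "text",
        x = fmt_num(hb$label_rect$x),
        y = fmt_num(rect_y2(hb$label_rect) + hb$font_size * 0.9),
        "font-size" = fmt_num(max(6, hb$font_size * 0.6)),
        "fill-opacity" = fmt_num(alpha),
        class = "analysis-annotation", hb$annotation)
    }
  }
}

draw_edge <- function(parent, e) {
  g <- xml2::xml_add_child(parent, "g", id = e$id, class = "reaction")
  xml2::xml_add_child(g, "polyline", points = svg_points_attr(e$segments),
                      fill = "none", stroke = "#000000",
                      "stroke-width" = "1", class = "backbone")
  for (cn in e$connectors) {
    xml2::xml_add_child(g, "polyline", points = svg_points_attr(cn$points),
                        fill = "none", stroke = "#000000",
                        "stroke-width" = "1",
                        class = paste0("connector-", cn$role))
    tip <- cn$points[nrow(cn$points), ]
    if (cn$ending == "circle") {
      xml2::xml_add_child(g, "circle", cx = fmt_num(tip[1]),
                          cy = fmt_num(tip[2]), r = "4", fill = "#FFFFFF",
                          stroke = "#000000", class = "ending-circle")
    } else if (cn$ending == "bar") {
      xml2::xml_add_child(g, "line", x1 = fmt_num(tip[1] - 4),
                          y1 = fmt_num(tip[2] - 4), x2 = fmt_num(tip[1] + 4),
                          y2 = fmt_num(tip[2] + 4), stroke = "#000000",
                          "stroke-width" = "2", class = "ending-bar")
    } else if (cn$ending == "arrow") {
      xml2::xml_add_child(g, "polygon",
                          points = arrow_head_points(cn$points),
                          fill = "#000000", class = "ending-arrow")
    }
  }
  rp <- e$reaction_point
  add_rect_el(g, rect(rp[1] - 3, rp[2] - 3, 6, 6), fill = "#FFFFFF",
              stroke = "#000000", class = "reaction-node")
}

arrow_head_points <- function(pts) {
  tip <- pts[nrow(pts), ]
  prev <- if (nrow(pts) >= 2L) pts[nrow(pts) - 1L, ] else tip + c(-1, 0)
  d <- tip - prev
  len <- sqrt(sum(d * d))
  u <- if (len > 0) d / len else c(1, 0)
  n <- c(-u[2], u[1])
  base <- tip - 8 * u
  p1 <- base + 3.5 * n
  p2 <- base - 3.5 * n
  svg_points_attr(rbind(tip, p1, p2))
}

#' Render a diagram thumbnail
#'
#' A miniature of the diagram used for in-viewer navigation: same viewBox as
#' the canvas, the longer rendered edge scaled to `max_edge` pixels, aspect
#' ratio preserved, and no text elements at all.
#'
#' @param diagram A valid [pathway_diagram()].
#' @param max_edge Length of the longer edge in pixels (>= 16).
#' @return SVG text.
#' @export
render_thumbnail <- function(diagram, max_edge = 120) {
  if (max_edge < 16) stop("thumbnail too small (max_edge < 16)", call. = FALSE)
  cv <- diagram$canvas
  scale <- max_edge / max(cv$w, cv$h)
  root <- svg_root(c(cv$x, cv$y, cv$w, cv$h), cv$w * scale, cv$h * scale)
  g <- xml2::xml_add_child(root, "g", class = "thumbnail")
  for (cp in diagram$compartments) {
    add_rect_el(g, cp$outer, fill = "#F5F2D8", stroke = "#B0A46A")
  }
  for (e in diagram$edges) {
    xml2::xml_add_child(g, "polyline", points = svg_points_attr(e$segments),
                        fill = "none", stroke = "#808080")
  }
  for (n in diagram$nodes) {
    add_rect_el(g, n$bounds, fill = "#8DC7BB", stroke = "none")
  }
  as.character(root)
}
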