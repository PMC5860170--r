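# Enhanced high-level diagrams: textbook-style SVG illustrations made
# interactive through three kinds of technical annotations carried in
# element ids — the clickable region of a subpathway, the text element
# holding its name, and the element to be covered by analysis results.
# Every element without such an annotation is a decoration and is never
# touched by any operation here.

#' EHLD annotation conventions
#'
#' The three annotation types are recognised by element-id prefixes:
#' `REGION-<stableId>` marks the clickable region of a subpathway,
#' `TEXT-<stableId>` its label and `OVERLAY-<stableId>` the element to be
#' covered by analysis results. The prefixes are configurable to accommodate
#' other annotation dialects.
#'
#' @param region_prefix,label_prefix,overlay_prefix Id prefixes for the
#'   three annotation types.
#' @return An `ehld_config` object.
#' @export
ehld_config <- function(region_prefix = "REGION-", label_prefix = "TEXT-",
                        overlay_prefix = "OVERLAY-") {
  structure(list(region_prefix = region_prefix,
                 label_prefix = label_prefix,
                 overlay_prefix = overlay_prefix),
            class = "ehld_config")
}

STATE_PREFIX <- "STATE-"
OVERLAY_GROUP_ID <- "analysis-result-overlay"
REGION_STATES <- c("normal", "highlighted", "selected", "flagged")

#' Parse an EHLD SVG document
#'
#' Reads an SVG 1.1 document and discovers its active regions from the
#' technical annotations (see [ehld_config()]). A pathway with a region
#' element but a missing label or overlay element yields a warning and a
#' partial active region; elements with no annotation are decorations and
#' are left untouched by all operations.
#'
#' @param svg SVG text, or a path to an SVG file.
#' @param config An [ehld_config()].
#' @return An `ehld_document` with fields `doc` (the xml2 tree), `regions`
#'   (list keyed by pathway stable id, each with `pathway_id`, `region`,
#'   `label`, `overlay` node references), `canvas` (from the viewBox) and
#'   `config`.
#' @export
parse_ehld <- function(svg, config = ehld_config()) {
  doc <- tryCatch(xml2::read_xml(svg),
                  error = function(e) {
                    stop("malformed SVG: ", conditionMessage(e),
                         call. = FALSE)
                  })
  vb <- xml2::xml_attr(doc, "viewBox")
  if (is.na(vb)) stop("no canvas: SVG root has no viewBox", call. = FALSE)
  nums <- as.numeric(strsplit(trimws(vb), "[ ,]+")[[1]])
  if (length(nums) != 4L || any(!is.finite(nums))) {
    stop("no canvas: malformed viewBox '", vb, "'", call. = FALSE)
  }
  canvas <- rect(nums[1], nums[2], nums[3], nums[4])
  with_id <- xml2::xml_find_all(doc, "//*[@id]")
  ids <- xml2::xml_attr(with_id, "id")
  pick <- function(prefix) {
    sel <- startsWith(ids, prefix)
    stats::setNames(as.list(with_id[sel]),
                    substring(ids[sel], nchar(prefix) + 1L))
  }
  regions_el <- pick(config$region_prefix)
  labels_el <- pick(config$label_prefix)
  overlays_el <- pick(config$overlay_prefix)
  if (anyDuplicated(names(regions_el))) {
    stop("duplicate region annotation for pathway '",
         names(regions_el)[duplicated(names(regions_el))][1], "'",
         call. = FALSE)
  }
  regions <- list()
  for (pid in names(regions_el)) {
    if (is.null(labels_el[[pid]]) || is.null(overlays_el[[pid]])) {
      warning("pathway '", pid, "': region annotation without ",
              if (is.null(labels_el[[pid]])) "label " else "",
              if (is.null(overlays_el[[pid]])) "overlay " else "",
              "element; partial active region", call. = FALSE)
    }
    regions[[pid]] <- list(pathway_id = pid, region = regions_el[[pid]],
                           label = labels_el[[pid]],
                           overlay = overlays_el[[pid]])
  }
  structure(list(doc = doc, regions = regions, canvas = canvas,
                 config = config),
            class = "ehld_document")
}

#' @export
print.ehld_document <- function(x, ...) {
  cat(sprintf("<ehld_document: %d active region(s), canvas %s>\n",
              length(x$regions), format(x$canvas)))
  if (length(x$regions)) {
    cat("  pathways:", paste(names(x$regions), collapse = ", "), "\n")
  }
  invisible(x)
}

# --- geometry of SVG shape elements -----------------------------------------

svg_num <- function(node, attr, default = NA_real_) {
  v <- suppressWarnings(as.numeric(xml2::xml_attr(node, attr)))
  if (is.na(v)) default else v
}

# exact containment for the basic shapes; paths fall back to the bounding
# box of their coordinate data (full Bezier containment is out of scope)
svg_shape_contains <- function(node, x, y) {
  tag <- xml2::xml_name(node)
  switch(
    tag,
    rect = {
      r <- rect(svg_num(node, "x", 0), svg_num(node, "y", 0),
                svg_num(node, "width", 0), svg_num(node, "height", 0))
      rect_contains_point(r, x, y)
    },
    circle = {
      cx <- svg_num(node, "cx", 0); cy <- svg_num(node, "cy", 0)
      r <- svg_num(node, "r", 0)
      (x - cx)^2 + (y - cy)^2 <= r^2
    },
    ellipse = {
      cx <- svg_num(node, "cx", 0); cy <- svg_num(node, "cy", 0)
      rx <- svg_num(node, "rx", 0); ry <- svg_num(node, "ry", 0)
      rx > 0 && ry > 0 && ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
    },
    polygon = {
      pts <- parse_points_attr(xml2::xml_attr(node, "points"))
      point_in_polygon(x, y, pts)
    },
    g = {
      kids <- xml2::xml_children(node)
      any(vapply(kids, svg_shape_contains, logical(1), x = x, y = y))
    },
    {
      bb <- svg_node_bbox(node)
      !is.null(bb) && rect_contains_point(bb, x, y)
    })
}

parse_points_attr <- function(s) {
  nums <- as.numeric(strsplit(trimws(s), "[ ,]+")[[1]])
  matrix(nums, ncol = 2L, byrow = TRUE)
}

point_in_polygon <- function(x, y, pts) {
  n <- nrow(pts)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- pts[i, 1]; yi <- pts[i, 2]
    xj <- pts[j, 1]; yj <- pts[j, 2]
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Bounding box of an SVG element (rect/circle/ellipse/polygon/text exactly
# where attributes allow; paths via their coordinate stream, assuming
# absolute commands; groups as the union of their children).
svg_node_bbox <- function(node) {
  tag <- xml2::xml_name(node)
  switch(
    tag,
    rect = rect(svg_num(node, "x", 0), svg_num(node, "y", 0),
                svg_num(node, "width", 0), svg_num(node, "height", 0)),
    circle = {
      cx <- svg_num(node, "cx", 0); cy <- svg_num(node, "cy", 0)
      r <- svg_num(node, "r", 0)
      rect(cx - r, cy - r, 2 * r, 2 * r)
    },
    ellipse = {
      cx <- svg_num(node, "cx", 0); cy <- svg_num(node, "cy", 0)
      rx <- svg_num(node, "rx", 0); ry <- svg_num(node, "ry", 0)
      rect(cx - rx, cy - ry, 2 * rx, 2 * ry)
    },
    polygon = ,
    polyline = {
      pts <- parse_points_attr(xml2::xml_attr(node, "points"))
      rect(min(pts[, 1]), min(pts[, 2]), diff(range(pts[, 1])),
           diff(range(pts[, 2])))
    },
    text = {
      # no renderer metrics available: approximate from position, length
      # and font size (same fixed-metric model as label placement)
      x <- svg_num(node, "x", 0); y <- svg_num(node, "y", 0)
      size <- svg_num(node, "font-size", 16)
      n <- nchar(xml2::xml_text(node))
      rect(x, y - size, max(1, 0.6 * size * n), 1.2 * size)
    },
    path = {
      d <- xml2::xml_attr(node, "d")
      nums <- suppressWarnings(as.numeric(
        regmatches(d, gregexpr("-?[0-9.]+(e-?[0-9]+)?", d))[[1]]))
      nums <- nums[is.finite(nums)]
      if (length(nums) < 4L) return(NULL)
      xs <- nums[seq(1, length(nums) - 1, by = 2)]
      ys <- nums[seq(2, length(nums), by = 2)]
      rect(min(xs), min(ys), diff(range(xs)), diff(range(ys)))
    },
    g = {
      kids <- xml2::xml_children(node)
      bbs <- Filter(Negate(is.null), lapply(kids, svg_node_bbox))
      if (length(bbs) == 0L) NULL else rect_union(bbs)
    },
    NULL)
}

#' Hit-test a point against the active regions
#'
#' Returns the pathway id of the topmost active region (last in document
#' order) whose geometry contains the point, or `NULL` when only
#' decorations lie under it — this is the click-to-navigate interaction of
#' the viewer.
#'
#' @param ehld An `ehld_document`.
#' @param x,y Canvas coordinates of the query point.
#' @return A pathway stable id, or `NULL`.
#' @export
hit_test <- function(ehld, x, y) {
  stopifnot(inherits(ehld, "ehld_document"))
  if (!rect_contains_point(ehld$canvas, x, y)) {
    stop("out of canvas: (", x, ", ", y, ")", call. = FALSE)
  }
  hit <- NULL
  # regions list preserves document order; later elements sit on top
  for (rg in ehld$regions) {
    if (!is.null(rg$region) && svg_shape_contains(rg$region, x, y)) {
      hit <- rg$pathway_id
    }
  }
  hit
}

#' Set the interaction state of a region
#'
#' Renders hover/selection/flagging feedback by adding an explicit state
#' element (`STATE-<pathwayId>`) on top of the region: a stroked outline for
#' `"highlighted"` and `"selected"`, a dashed outline plus corner marker for
#' `"flagged"`. `"normal"` removes the state element, restoring the document
#' exactly. Styling is written as explicit attributes, not CSS classes, so
#' exported files render identically in any SVG viewer. Setting the same
#' state twice is idempotent; the underlying artwork is never modified.
#'
#' @param ehld An `ehld_document` (modified in place, xml2 semantics).
#' @param pathway_id Stable id of an active region.
#' @param state One of `"normal"`, `"highlighted"`, `"selected"`,
#'   `"flagged"`.
#' @return The modified `ehld_document`, invisibly.
#' @export
set_region_state <- function(ehld, pathway_id,
                             state = c("normal", "highlighted", "selected",
                                       "flagged")) {
  state <- match.arg(state)
  rg <- ehld$regions[[pathway_id]]
  if (is.null(rg)) stop("no such region: '", pathway_id, "'", call. = FALSE)
  state_id <- paste0(STATE_PREFIX, pathway_id)
  old <- xml2::xml_find_all(ehld$doc,
                            sprintf("//*[@id='%s']", state_id))
  for (el in old) xml2::xml_remove(el)
  if (state == "normal") return(invisible(ehld))
  bb <- svg_node_bbox(rg$region)
  if (is.null(bb)) stop("region '", pathway_id, "' has no geometry",
                        call. = FALSE)
  stroke <- switch(state, highlighted = "#2A7FFF", selected = "#004FB0",
                   flagged = "#C335C7")
  g <- xml2::xml_add_child(xml2::xml_root(ehld$doc), "g", id = state_id,
                           class = paste0("region-state state-", state))
  args <- list(g, bb, fill = "none", stroke = stroke, "stroke-width" = "3")
  if (state == "flagged") args[["stroke-dasharray"]] <- "6,3"
  do.call(add_rect_el, args)
  if (state == "flagged") {
    xml2::xml_add_child(g, "circle", cx = fmt_num(rect_x2(bb)),
                        cy = fmt_num(bb$y), r = "5", fill = stroke)
  }
  invisible(ehld)
}

#' Serialize an EHLD document to SVG text
#'
#' With `include_overlay = TRUE`, any analysis-result overlay currently
#' applied (see [apply_overlay()]) is kept in the output — the downloaded
#' file shows exactly what the viewer shows. With `FALSE`, the overlay
#' group is stripped. The output re-parses into an equivalent document.
#'
#' @param ehld An `ehld_document`.
#' @param include_overlay Keep the analysis overlay group (default `TRUE`).
#' @return SVG text.
#' @export
export_svg <- function(ehld, include_overlay = TRUE) {
  stopifnot(inherits(ehld, "ehld_document"))
  out <- xml2::read_xml(as.character(ehld$doc))  # deep copy
  if (!include_overlay) {
    grp <- xml2::xml_find_all(out, sprintf("//*[@id='%s']",
                                           OVERLAY_GROUP_ID))
    for (el in grp) xml2::xml_remove(el)
  }
  as.character(out)
}
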