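# Over-representation analysis and its visual overlay.
#
# The statistic is the classical hypergeometric upper tail: given a universe
# of annotated entities, a pathway's entity set, and a query list, the
# p-value is P(X >= found) for X ~ Hypergeometric(|universe|, total, |query|).
# P-values are adjusted across pathways with the Benjamini-Hochberg step-up.
# The overlay renders, for each subpathway label: a rectangle coloured along
# a p-value gradient (grey when not significant), a bar under the label
# whose width is the hit fraction found/total of the label width, the
# "found/total" count with the FDR, and a shared legend bar.

#' Define pathway entity sets over a universe
#'
#' @param sets Named list: pathway stable id -> character vector of entity
#'   identifiers (each non-empty).
#' @param universe Character vector of all entity identifiers under
#'   consideration; defaults to the union of all sets. Every set must be a
#'   subset of the universe.
#' @return A `pathway_entity_sets` object.
#' @export
entity_sets <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) {
    stop("every pathway set must be non-empty", call. = FALSE)
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- unique(as.character(universe))
    bad <- names(sets)[!vapply(sets, function(s) all(s %in% universe),
                               logical(1))]
    if (length(bad)) {
      stop("set(s) not contained in universe: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  structure(list(universe = universe, sets = sets),
            class = "pathway_entity_sets")
}

#' @export
print.pathway_entity_sets <- function(x, ...) {
  cat(sprintf("<pathway_entity_sets: %d sets over a universe of %d entities>\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Over-representation analysis
#'
#' For each pathway set, computes `found` (size of the query/set overlap),
#' `total` (set size), the hypergeometric upper-tail p-value
#' `P(X >= found)` with population size `|universe|`, `total` successes and
#' `|query % in % universe|` draws, and the Benjamini-Hochberg FDR across
#' all pathways. Query identifiers outside the universe are dropped (their
#' count is reported via a message).
#'
#' @param query Character vector of query entity identifiers.
#' @param sets A [entity_sets()] object.
#' @return An `ora_result`: a data.frame with columns `pathway_id`, `found`,
#'   `total`, `p_value`, `fdr`, one row per pathway set.
#' @export
#' @examples
#' es <- entity_sets(list(P1 = letters[1:5]), universe = letters[1:20])
#' ora(letters[1:5], es)
ora <- function(query, sets) {
  stopifnot(inherits(sets, "pathway_entity_sets"))
  query <- unique(as.character(query))
  eff <- intersect(query, sets$universe)
  dropped <- length(query) - length(eff)
  if (dropped > 0L) {
    message(dropped, " query identifier(s) outside the universe dropped")
  }
  if (length(eff) == 0L) {
    stop("query disjoint from universe", call. = FALSE)
  }
  N <- length(sets$universe)
  n_draws <- length(eff)
  pid <- names(sets$sets)
  found <- vapply(sets$sets, function(s) length(intersect(eff, s)),
                  integer(1))
  total <- lengths(sets$sets)
  # upper tail P(X >= found): exact and numerically stable in stats
  p <- stats::phyper(found - 1L, total, N - total, n_draws,
                     lower.tail = FALSE)
  res <- data.frame(pathway_id = pid, found = unname(found),
                    total = unname(total), p_value = unname(p),
                    fdr = bh_fdr(unname(p)), stringsAsFactors = FALSE,
                    row.names = NULL)
  class(res) <- c("ora_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values (monotone after sorting, capped at 1).
#' @export
bh_fdr <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Overlay style parameters
#'
#' @param profile A [color_profile()]; supplies the p-value gradient, the
#'   not-significant grey and the hit-bar colour.
#' @param significance_threshold P-value below which a pathway is a hit and
#'   coloured along the gradient; at or above it the grey is used
#'   (default 0.05).
#' @param bar_height Height of the hit-fraction bar in canvas units.
#' @param legend_width Width of the legend bar in canvas units.
#' @return An `overlay_style` object.
#' @export
overlay_style <- function(profile = color_profile(),
                          significance_threshold = 0.05, bar_height = 5,
                          legend_width = 18) {
  if (!(significance_threshold > 0 && significance_threshold < 1)) {
    stop("significance threshold must lie strictly between 0 and 1",
         call. = FALSE)
  }
  structure(list(significance_threshold = significance_threshold,
                 gradient = profile$overlay_gradient,
                 grey = profile$not_significant_colour,
                 bar_colour = profile$hit_bar_colour,
                 bar_height = bar_height, legend_width = legend_width),
            class = "overlay_style")
}

#' Map a p-value to an overlay colour
#'
#' Significant p-values (`p < threshold`) are interpolated linearly in RGB
#' between the gradient endpoints, parameterized by `p / threshold`;
#' non-significant ones get the profile's grey. The mapping is continuous
#' on `[0, threshold)` and constant grey from the threshold on.
#'
#' @param p P-value(s) in \[0, 1\].
#' @param style An [overlay_style()].
#' @return Character vector of colours.
#' @export
pvalue_to_color <- function(p, style = overlay_style()) {
  stopifnot(all(p >= 0 & p <= 1))
  vapply(p, function(pi) {
    if (pi >= style$significance_threshold) return(style$grey)
    lerp_color(style$gradient[1], style$gradient[2],
               pi / style$significance_threshold)
  }, character(1))
}

#' Hit-fraction bar geometry
#'
#' The bar under a pathway label whose width shows the proportion of the
#' pathway's entities present in the analysed dataset: anchored at the
#' label's bottom-left, width exactly `(found / total) * label_box$w`.
#'
#' @param found,total Hit count and set size (`0 <= found <= total`,
#'   `total > 0`).
#' @param label_box Bounding [rect()] of the label.
#' @param bar_height Bar height in canvas units.
#' @return A `canvas_rect` (zero width when `found == 0`).
#' @export
hit_bar_rect <- function(found, total, label_box, bar_height = 5) {
  if (total <= 0) stop("total must be > 0", call. = FALSE)
  if (found < 0 || found > total) {
    stop("found must lie in [0, total]", call. = FALSE)
  }
  rect(label_box$x, rect_y2(label_box), (found / total) * label_box$w,
       bar_height)
}

format_fdr <- function(fdr) sprintf("FDR = %.2E", fdr)

#' Apply an analysis overlay to an EHLD
#'
#' For every active region with a result entry, covers the region's overlay
#' target with a rectangle coloured by [pvalue_to_color()], adds the
#' hit-fraction bar ([hit_bar_rect()]) under the label, and writes the
#' "found/total" count with the FDR next to the label. A vertical legend
#' (the p-value gradient over a grey block, with a tick per displayed
#' p-value) is added at the right edge whenever at least one result is
#' displayed. All added elements live in a single group
#' (`analysis-result-overlay`), so re-applying a result replaces the
#' previous overlay (idempotent) and nothing outside the group is touched.
#' Result entries whose pathway id has no region are skipped (count
#' reported via a message).
#'
#' @param ehld An `ehld_document` (modified in place).
#' @param result An `ora_result` from [ora()].
#' @param style An [overlay_style()].
#' @return The modified `ehld_document`, invisibly.
#' @export
apply_overlay <- function(ehld, result, style = overlay_style()) {
  stopifnot(inherits(ehld, "ehld_document"),
            inherits(result, "ora_result"))
  old <- xml2::xml_find_all(ehld$doc, sprintf("//*[@id='%s']",
                                              OVERLAY_GROUP_ID))
  for (el in old) xml2::xml_remove(el)
  matched <- intersect(result$pathway_id, names(ehld$regions))
  skipped <- setdiff(result$pathway_id, names(ehld$regions))
  if (length(skipped)) {
    message(length(skipped),
            " result pathway(s) without an active region skipped")
  }
  if (length(matched) == 0L) return(invisible(ehld))
  g <- xml2::xml_add_child(xml2::xml_root(ehld$doc), "g",
                           id = OVERLAY_GROUP_ID,
                           class = "analysis-result-overlay")
  shown_p <- numeric(0)
  for (rg in ehld$regions) {          # document order, deterministic
    pid <- rg$pathway_id
    if (!pid %in% matched) next
    row <- result[match(pid, result$pathway_id), ]
    col <- pvalue_to_color(row$p_value, style)
    if (!is.null(rg$overlay)) {
      bb <- svg_node_bbox(rg$overlay)
      if (!is.null(bb)) {
        add_rect_el(g, bb, fill = col, "fill-opacity" = "0.9",
                    class = "overlay-rect",
                    id = paste0("overlay-rect-", pid))
      }
    }
    if (!is.null(rg$label)) {
      lb <- svg_node_bbox(rg$label)
      if (!is.null(lb)) {
        bar <- hit_bar_rect(row$found, row$total, lb, style$bar_height)
        if (bar$w > 0) {
          add_rect_el(g, bar, fill = style$bar_colour, class = "hit-bar",
                      id = paste0("hit-bar-", pid))
        }
        xml2::xml_add_child(
          g, "text", x = fmt_num(rect_x2(lb) + 4),
          y = fmt_num(rect_y2(lb) - 2), "font-size" = "11",
          class = "overlay-annotation",
          id = paste0("overlay-text-", pid),
          sprintf("%d/%d %s", row$found, row$total, format_fdr(row$fdr)))
      }
    }
    shown_p <- c(shown_p, row$p_value)
  }
  add_legend(g, ehld$canvas, style, shown_p)
  invisible(ehld)
}

# Vertical legend at the right edge: gradient (p = 0 at the top down to the
# significance threshold) over a grey not-significant block, plus one tick
# per displayed p-value.
add_legend <- function(parent, canvas, style, shown_p) {
  lw <- style$legend_width
  lh <- canvas$h * 0.6
  x0 <- rect_x2(canvas) - lw - 6
  y0 <- canvas$y + canvas$h * 0.1
  g <- xml2::xml_add_child(parent, "g", class = "overlay-legend")
  steps <- 24L
  grad_h <- lh * 0.8
  for (i in seq_len(steps)) {
    t <- (i - 1) / (steps - 1)
    add_rect_el(g, rect(x0, y0 + (i - 1) * grad_h / steps, lw,
                        grad_h / steps + 0.5),
                fill = lerp_color(style$gradient[1], style$gradient[2], t),
                stroke = "none")
  }
  add_rect_el(g, rect(x0, y0 + grad_h, lw, lh - grad_h),
              fill = style$grey, stroke = "none",
              class = "legend-not-significant")
  add_rect_el(g, rect(x0, y0, lw, lh), fill = "none", stroke = "#333333")
  for (p in sort(unique(shown_p))) {
    ty <- if (p < style$significance_threshold) {
      y0 + (p / style$significance_threshold) * grad_h
    } else {
      y0 + grad_h + (lh - grad_h) / 2
    }
    xml2::xml_add_child(g, "line", x1 = fmt_num(x0 - 4), y1 = fmt_num(ty),
                        x2 = fmt_num(x0 + lw), y2 = fmt_num(ty),
                        stroke = "#000000", "stroke-width" = "1",
                        class = "legend-tick")
  }
}

#' Decorate classic-diagram highlight labels with analysis results
#'
#' The classic-diagram counterpart of [apply_overlay()]: each labelled
#' highlight box whose subpathway has a result entry gains the overlay
#' colour for its label rectangle, a hit-fraction bar and a "found/total
#' FDR" annotation. [render_svg()] draws these decorations. Boxes without a
#' result (or without a placed label) are returned unchanged.
#'
#' @param boxes List of `highlight_box` objects (labels placed).
#' @param result An `ora_result`.
#' @param style An [overlay_style()].
#' @return The decorated list of boxes.
#' @export
overlay_lld_labels <- function(boxes, result, style = overlay_style()) {
  stopifnot(inherits(result, "ora_result"))
  lapply(boxes, function(b) {
    i <- match(b$subpathway_id, result$pathway_id)
    if (is.na(i) || is.null(b$label_rect)) return(b)
    row <- result[i, ]
    b$overlay_colour <- pvalue_to_color(row$p_value, style)
    b$hit_bar <- hit_bar_rect(row$found, row$total, b$label_rect,
                              style$bar_height)
    b$bar_colour <- style$bar_colour
    b$annotation <- sprintf("%d/%d %s", row$found, row$total,
                            format_fdr(row$fdr))
    b
  })
}

#' Read GMT-style pathway sets
#'
#' Tab-separated, one set per line: set name, description, then member
#' identifiers. A set named `UNIVERSE` is treated as the analysis universe
#' rather than a pathway; without one, the universe defaults to the union
#' of all sets.
#'
#' @param path Path to a `.gmt` file.
#' @return A [entity_sets()] object.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1], " (need name, description, members)",
         call. = FALSE)
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  members <- lapply(parts, function(p) p[-(1:2)])
  names(members) <- nm
  universe <- NULL
  if ("UNIVERSE" %in% nm) {
    universe <- members[["UNIVERSE"]]
    members <- members[nm != "UNIVERSE"]
  }
  entity_sets(members, universe = universe)
}

#' Write GMT-style pathway sets
#'
#' @param sets A [entity_sets()] object.
#' @param path Output path. The universe is written as a first set named
#'   `UNIVERSE` so that [read_gmt()] restores it exactly.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "pathway_entity_sets"))
  lines <- c(paste(c("UNIVERSE", "analysis universe", sets$universe),
                   collapse = "\t"),
             vapply(names(sets$sets), function(nm) {
               paste(c(nm, "pathway entity set", sets$sets[[nm]]),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
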