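# Colour handling and named colour profiles.
#
# Colours are "#RRGGBB" or "#RRGGBBAA" hex strings (8-bit channels), the form
# that goes straight into SVG attributes and OOXML srgbClr values.

parse_color <- function(col) {
  if (!is.character(col) || length(col) != 1L ||
      !grepl("^#[0-9A-Fa-f]{6}([0-9A-Fa-f]{2})?$", col)) {
    stop("invalid colour: ", deparse(col), call. = FALSE)
  }
  hex <- substring(col, 2L)
  n <- nchar(hex) / 2L
  ch <- vapply(seq_len(n), function(i) {
    strtoi(substr(hex, 2L * i - 1L, 2L * i), 16L)
  }, integer(1))
  if (n == 3L) ch <- c(ch, 255L)
  names(ch) <- c("r", "g", "b", "a")
  ch
}

format_color <- function(ch) {
  ch <- as.integer(round(pmin(pmax(ch, 0), 255)))
  if (length(ch) == 3L || ch[4] == 255L) {
    sprintf("#%02X%02X%02X", ch[1], ch[2], ch[3])
  } else {
    sprintf("#%02X%02X%02X%02X", ch[1], ch[2], ch[3], ch[4])
  }
}

# Componentwise linear interpolation between two colours; t in [0, 1].
lerp_color <- function(from, to, t) {
  a <- parse_color(from)
  b <- parse_color(to)
  format_color(a + t * (b - a))
}

# Split a possibly-translucent colour into an opaque hex + numeric opacity,
# the representation SVG wants (fill + fill-opacity).
color_svg <- function(col) {
  ch <- parse_color(col)
  list(hex = sprintf("#%02X%02X%02X", ch[1], ch[2], ch[3]),
       opacity = ch[4] / 255)
}

SCHEMA_CLASSES <- c("protein", "chemical", "complex", "entity_set",
                    "gene", "rna", "process_node")

#' Build or retrieve a colour profile
#'
#' A colour profile bundles every colour decision the renderer and exporters
#' make: glyph fill/stroke per schema class, the ordered semi-transparent
#' palette cycled over subpathway highlight boxes, the p-value gradient and
#' grey used by analysis overlays, and the hit-fraction bar colour. Two
#' presets ship with the package: `"modern"` and `"standard"`.
#'
#' @param name Preset name (`"modern"` or `"standard"`), or a path to a JSON
#'   profile file with the same fields.
#' @return An object of class `color_profile`.
#' @export
#' @examples
#' p <- color_profile("modern")
#' p$subpathway_palette
color_profile <- function(name = "modern") {
  if (file.exists(name)) {
    return(read_color_profile(name))
  }
  preset <- switch(
    name,
    modern = list(
      node_fill = c(protein = "#8DC7BB", chemical = "#A5D791",
                    complex = "#ABD1E3", entity_set = "#A0BBCD",
                    gene = "#F7E29C", rna = "#F1C3B8",
                    process_node = "#A5D791"),
      node_stroke = c(protein = "#356D64", chemical = "#356D36",
                      complex = "#3E546B", entity_set = "#3E546B",
                      gene = "#8A7A2F", rna = "#8A4A3A",
                      process_node = "#356D36"),
      subpathway_palette = c("#E6194B55", "#3CB44B55", "#4363D855",
                             "#F5823155", "#911EB455", "#46F0F055",
                             "#F032E655", "#BCF60C55", "#00808055",
                             "#9A632455"),
      overlay_gradient = c("#FFFF4D", "#FF7700"),
      not_significant_colour = "#C8C8C8",
      hit_bar_colour = "#FFDD00"
    ),
    standard = list(
      node_fill = c(protein = "#CCFFCC", chemical = "#A2D699",
                    complex = "#CCFFFF", entity_set = "#CCCCFF",
                    gene = "#FFFFCC", rna = "#FFE4C4",
                    process_node = "#CCFFCC"),
      node_stroke = c(protein = "#008000", chemical = "#008000",
                      complex = "#000080", entity_set = "#000080",
                      gene = "#808000", rna = "#804000",
                      process_node = "#008000"),
      subpathway_palette = c("#FF634755", "#4682B455", "#32CD3255",
                             "#FFA50055", "#8A2BE255", "#20B2AA55",
                             "#FF69B455", "#9ACD3255"),
      overlay_gradient = c("#FFFFE0", "#FF4500"),
      not_significant_colour = "#BEBEBE",
      hit_bar_colour = "#FFD700"
    ),
    stop("unknown colour profile: ", name, call. = FALSE)
  )
  new_color_profile(name, preset)
}

new_color_profile <- function(name, fields) {
  p <- c(list(name = name), fields)
  validate_color_profile(p)
  structure(p, class = "color_profile")
}

validate_color_profile <- function(p) {
  stopifnot(
    all(SCHEMA_CLASSES %in% names(p$node_fill)),
    all(SCHEMA_CLASSES %in% names(p$node_stroke)),
    length(p$subpathway_palette) >= 8L,
    length(p$overlay_gradient) == 2L
  )
  for (col in c(p$node_fill, p$node_stroke, p$subpathway_palette,
                p$overlay_gradient, p$not_significant_colour,
                p$hit_bar_colour)) {
    parse_color(col)
  }
  if (anyDuplicated(p$subpathway_palette)) {
    stop("colour profile: subpathway palette entries must be distinct",
         call. = FALSE)
  }
  invisible(p)
}

#' Read a colour profile from a JSON file
#'
#' @param path Path to a JSON file with fields `name`, `node_fill`,
#'   `node_stroke`, `subpathway_palette`, `overlay_gradient`,
#'   `not_significant_colour`, `hit_bar_colour`.
#' @return A `color_profile`.
#' @export
read_color_profile <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_color_profile(raw$name %||% basename(path), list(
    node_fill = unlist(raw$node_fill),
    node_stroke = unlist(raw$node_stroke),
    subpathway_palette = unlist(raw$subpathway_palette),
    overlay_gradient = unlist(raw$overlay_gradient),
    not_significant_colour = raw$not_significant_colour,
    hit_bar_colour = raw$hit_bar_colour
  ))
}

#' @export
print.color_profile <- function(x, ...) {
  cat(sprintf("<color_profile '%s': %d palette colours, gradient %s -> %s>\n",
              x$name, length(x$subpathway_palette),
              x$overlay_gradient[1], x$overlay_gradient[2]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
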