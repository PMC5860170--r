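# Small hand-built fixtures shared across test files.

# Three glyphs and one catalysed reaction: A --R1--> B with catalyst C.
# The backbone runs through the reaction point; connectors end exactly on
# it, so the geometry is valid by construction.
tiny_diagram <- function() {
  a <- node_glyph("A", "protein", "Kinase A", rect(50, 100, 60, 40))
  b <- node_glyph("B", "protein", "Substrate B", rect(250, 100, 60, 40))
  cc <- node_glyph("C", "chemical", "Cofactor C", rect(150, 20, 60, 40))
  rp <- c(180, 120)
  e <- reaction_edge(
    "R1", rp, rbind(c(80, 120), c(180, 120), c(280, 120)),
    list(connector("input", "A", rbind(c(80, 120), rp)),
         connector("output", "B", rbind(c(280, 120), rp),
                   ending = "arrow"),
         connector("catalyst", "C", rbind(c(180, 40), rp),
                   ending = "circle")))
  pathway_diagram("PW-TINY", rect(0, 0, 400, 300), list(a, b, cc), list(e))
}

# expected connector count under the segment-counting rule: one connector
# per polyline segment, over the backbone and every role connector
expected_connector_count <- function(diagram) {
  sum(vapply(diagram$edges, function(e) {
    (nrow(e$segments) - 1L) +
      sum(vapply(e$connectors, function(cn) nrow(cn$points) - 1L,
                 integer(1)))
  }, integer(1)))
}

# expected anchor count: interior polyline points that do not coincide with
# the reaction point (fixture polyline endpoints always resolve to glyph or
# centre shapes)
expected_anchor_count <- function(diagram, eps = 0.5) {
  total <- 0L
  for (e in diagram$edges) {
    polylines <- c(list(e$segments),
                   lapply(e$connectors, `[[`, "points"))
    for (pts in polylines) {
      m <- nrow(pts)
      if (m > 2L) {
        for (i in 2:(m - 1L)) {
          if (sqrt(sum((pts[i, ] - e$reaction_point)^2)) > eps) {
            total <- total + 1L
          }
        }
      }
    }
  }
  total
}

graph_shape_count <- function(graph, kind) {
  sum(vapply(graph$shapes, function(s) s$kind == kind, logical(1)))
}
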