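# In-memory model of a classic lower-level pathway diagram: glyph nodes,
# segmented reaction edges with role-typed connectors, and compartments.
# The model mirrors SBGN process-description semantics at the level needed
# to render, highlight and export published layouts; it never computes
# layout itself (positions always come from input files).

CONNECTOR_ROLES <- c("input", "output", "catalyst", "activator", "inhibitor")
CONNECTOR_ENDINGS <- c("none", "arrow", "circle", "bar")

# ending legality per role: arrow marks outputs, open circle catalysis and
# activation, bar inhibition (classic SBGN-style line endings)
ROLE_ENDINGS <- list(
  input = "none", output = c("none", "arrow"),
  catalyst = c("none", "circle"), activator = c("none", "circle"),
  inhibitor = c("none", "bar")
)

#' Create a node glyph
#'
#' @param id Stable identifier, unique within the diagram.
#' @param schema_class One of `r paste0('"', SCHEMA_CLASSES, '"', collapse = ", ")`.
#' @param display_name Text shown inside the glyph.
#' @param bounds Glyph bounding box ([rect()]).
#' @param compartment_id Optional id of the containing compartment.
#' @return A `node_glyph` object.
#' @export
node_glyph <- function(id, schema_class, display_name, bounds,
                       compartment_id = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id), is_rect(bounds))
  schema_class <- match.arg(schema_class, SCHEMA_CLASSES)
  structure(list(id = id, schema_class = schema_class,
                 display_name = as.character(display_name), bounds = bounds,
                 compartment_id = compartment_id),
            class = "node_glyph")
}

#' Create a reaction connector
#'
#' A connector is the polyline joining a participating node to the reaction:
#' its points run from the node toward the reaction centre.
#'
#' @param role One of `"input"`, `"output"`, `"catalyst"`, `"activator"`,
#'   `"inhibitor"`.
#' @param node_id Id of the participating node glyph.
#' @param points Numeric matrix with columns x, y (at least one row).
#' @param ending Line ending drawn at the reaction-side tip: `"none"`,
#'   `"arrow"` (outputs), `"circle"` (catalysis/activation), `"bar"`
#'   (inhibition).
#' @return A `connector` object.
#' @export
connector <- function(role, node_id, points, ending = "none") {
  role <- match.arg(role, CONNECTOR_ROLES)
  ending <- match.arg(ending, CONNECTOR_ENDINGS)
  points <- as_points(points)
  structure(list(role = role, node_id = node_id, points = points,
                 ending = ending),
            class = "connector")
}

#' Create a reaction edge
#'
#' @param id Stable identifier, unique within the diagram.
#' @param reaction_point Length-2 numeric: position of the reaction node
#'   square.
#' @param segments Numeric matrix (columns x, y, >= 2 rows): the backbone
#'   polyline of the reaction.
#' @param connectors List of [connector()] objects; a valid reaction has at
#'   least one input and one output connector.
#' @return A `reaction_edge` object.
#' @export
reaction_edge <- function(id, reaction_point, segments, connectors) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            length(reaction_point) == 2L, all(is.finite(reaction_point)))
  segments <- as_points(segments)
  stopifnot(nrow(segments) >= 2L, is.list(connectors))
  structure(list(id = id, reaction_point = as.numeric(reaction_point),
                 segments = segments, connectors = connectors),
            class = "reaction_edge")
}

#' Create a compartment
#'
#' @param id Stable identifier.
#' @param name Display name.
#' @param outer Outer boundary rectangle.
#' @param inner Optional inner rectangle (membrane ring), strictly inside
#'   `outer`.
#' @return A `compartment` object.
#' @export
compartment <- function(id, name, outer, inner = NULL) {
  stopifnot(is.character(id), length(id) == 1L, is_rect(outer))
  structure(list(id = id, name = as.character(name), outer = outer,
                 inner = inner),
            class = "compartment")
}

#' Assemble a pathway diagram
#'
#' @param pathway_id Stable identifier of the pathway the diagram depicts.
#' @param canvas Canvas bounds ([rect()]); every node and edge point must lie
#'   within it.
#' @param nodes List of [node_glyph()] objects.
#' @param edges List of [reaction_edge()] objects.
#' @param compartments List of [compartment()] objects.
#' @return A `pathway_diagram` object. Use [validate_diagram()] to check the
#'   model invariants.
#' @export
pathway_diagram <- function(pathway_id, canvas, nodes = list(),
                            edges = list(), compartments = list()) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L,
            is_rect(canvas))
  structure(list(pathway_id = pathway_id, canvas = canvas, nodes = nodes,
                 edges = edges, compartments = compartments),
            class = "pathway_diagram")
}

#' @export
print.pathway_diagram <- function(x, ...) {
  cat(sprintf(
    "<pathway_diagram '%s': %d nodes, %d reactions, %d compartments, canvas %s>\n",
    x$pathway_id, length(x$nodes), length(x$edges), length(x$compartments),
    format(x$canvas)))
  invisible(x)
}

as_points <- function(points) {
  if (is.numeric(points) && is.null(dim(points)) && length(points) == 2L) {
    points <- matrix(points, ncol = 2L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 1L || !all(is.finite(points))) {
    stop("points must be a finite n x 2 matrix", call. = FALSE)
  }
  dimnames(points) <- list(NULL, c("x", "y"))
  storage.mode(points) <- "double"
  points
}

node_ids <- function(diagram) vapply(diagram$nodes, `[[`, character(1), "id")
edge_ids <- function(diagram) vapply(diagram$edges, `[[`, character(1), "id")

find_node <- function(diagram, id) {
  idx <- match(id, node_ids(diagram))
  if (is.na(idx)) NULL else diagram$nodes[[idx]]
}

find_edge <- function(diagram, id) {
  idx <- match(id, edge_ids(diagram))
  if (is.na(idx)) NULL else diagram$edges[[idx]]
}

#' Check all diagram model invariants
#'
#' Violations are data, not exceptions: each entry is a human-readable string
#' naming the offending element and the broken invariant. An empty character
#' vector means the diagram is valid.
#'
#' Checked invariants: unique node/edge/compartment ids; positive, finite
#' glyph bounds contained in the canvas; every connector's `node_id`
#' resolving to a node; line endings legal for the connector role; at least
#' one input and one output connector per reaction; every connector polyline
#' terminating within `eps` of the reaction backbone or reaction point;
#' all edge points inside the canvas; compartment inner rectangles strictly
#' inside their outer rectangle.
#'
#' @param diagram A [pathway_diagram()].
#' @param eps Connector endpoint tolerance in canvas units (default 0.5).
#' @return Character vector of violation descriptions (empty when valid).
#' @export
validate_diagram <- function(diagram, eps = 0.5) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))
  if (!inherits(diagram, "pathway_diagram")) {
    return("not a pathway_diagram object")
  }
  nids <- node_ids(diagram)
  if (anyDuplicated(nids)) {
    for (id in unique(nids[duplicated(nids)])) {
      say("node '%s': duplicate id", id)
    }
  }
  canvas <- diagram$canvas
  for (n in diagram$nodes) {
    if (n$bounds$w <= 0 || n$bounds$h <= 0) {
      say("node '%s': bounds must have positive extent", n$id)
    }
    if (!rect_contains_rect(canvas, n$bounds)) {
      say("node '%s': bounds outside canvas", n$id)
    }
    if (!is.null(n$compartment_id)) {
      cids <- vapply(diagram$compartments, `[[`, character(1), "id")
      if (!n$compartment_id %in% cids) {
        say("node '%s': unknown compartment '%s'", n$id, n$compartment_id)
      }
    }
  }
  eids <- edge_ids(diagram)
  if (anyDuplicated(eids)) {
    for (id in unique(eids[duplicated(eids)])) {
      say("edge '%s': duplicate id", id)
    }
  }
  if (anyDuplicated(c(unique(nids), unique(eids)))) {
    say("diagram '%s': node and edge id namespaces overlap",
        diagram$pathway_id)
  }
  for (e in diagram$edges) {
    pts <- rbind(e$segments, matrix(e$reaction_point, ncol = 2L))
    for (i in seq_len(nrow(pts))) {
      if (!rect_contains_point(canvas, pts[i, 1], pts[i, 2])) {
        say("edge '%s': point (%g, %g) outside canvas", e$id,
            pts[i, 1], pts[i, 2])
        break
      }
    }
    roles <- vapply(e$connectors, `[[`, character(1), "role")
    if (!"input" %in% roles) say("edge '%s': no input connector", e$id)
    if (!"output" %in% roles) say("edge '%s': no output connector", e$id)
    for (cn in e$connectors) {
      if (!cn$node_id %in% nids) {
        say("edge '%s': connector references absent node '%s'", e$id,
            cn$node_id)
      }
      if (!cn$ending %in% ROLE_ENDINGS[[cn$role]]) {
        say("edge '%s': ending '%s' not allowed for role '%s'", e$id,
            cn$ending, cn$role)
      }
      tip <- cn$points[nrow(cn$points), ]
      d <- min(point_polyline_dist(tip, e$segments),
               sqrt(sum((tip - e$reaction_point)^2)))
      if (d > eps) {
        say("edge '%s': %s connector for '%s' ends %.3g units from backbone (tolerance %g)",
            e$id, cn$role, cn$node_id, d, eps)
      }
      if (any(!rect_contains_point_vec(canvas, cn$points))) {
        say("edge '%s': connector for '%s' leaves canvas", e$id, cn$node_id)
      }
    }
  }
  cids <- vapply(diagram$compartments, `[[`, character(1), "id")
  if (anyDuplicated(cids)) {
    for (id in unique(cids[duplicated(cids)])) {
      say("compartment '%s': duplicate id", id)
    }
  }
  for (cp in diagram$compartments) {
    if (!is.null(cp$inner) && !rect_strictly_inside(cp$outer, cp$inner)) {
      say("compartment '%s': inner rect not strictly inside outer", cp$id)
    }
  }
  v
}

rect_contains_point_vec <- function(r, pts) {
  pts[, 1] >= r$x & pts[, 1] <= rect_x2(r) &
    pts[, 2] >= r$y & pts[, 2] <= rect_y2(r)
}

#' Create a subpathway-to-reaction assignment
#'
#' Records which reactions of a parent diagram belong to each subpathway;
#' highlight boxes are computed from these groups. A reaction may belong to
#' at most one subpathway.
#'
#' @param parent_pathway_id Id of the diagram the assignment refers to.
#' @param groups Named list: subpathway stable id -> character vector of
#'   reaction ids (each non-empty).
#' @param display_names Named character vector: subpathway id -> label text.
#' @return A `subpathway_assignment` object.
#' @export
subpathway_assignment <- function(parent_pathway_id, groups,
                                  display_names = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)), all(nzchar(names(groups))))
  if (anyDuplicated(names(groups))) {
    stop("duplicate subpathway id in assignment", call. = FALSE)
  }
  for (sid in names(groups)) {
    if (length(groups[[sid]]) == 0L) {
      stop("subpathway '", sid, "' has an empty reaction set", call. = FALSE)
    }
  }
  all_rids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_rids)) {
    dup <- unique(all_rids[duplicated(all_rids)])
    stop("reaction(s) assigned to more than one subpathway: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(display_names)) {
    display_names <- stats::setNames(names(groups), names(groups))
  }
  structure(list(parent_pathway_id = parent_pathway_id,
                 groups = lapply(groups, as.character),
                 display_names = display_names),
            class = "subpathway_assignment")
}

# Assignment-vs-diagram cross checks, reported like validate_diagram().
validate_assignment <- function(assignment, diagram) {
  v <- character(0)
  eids <- edge_ids(diagram)
  for (sid in names(assignment$groups)) {
    missing <- setdiff(assignment$groups[[sid]], eids)
    if (length(missing)) {
      v <- c(v, sprintf("subpathway '%s': unknown reaction(s) %s", sid,
                        paste(missing, collapse = ", ")))
    }
  }
  v
}

#' Create a pathway hierarchy entry
#'
#' @param stable_id Stable identifier of the pathway.
#' @param name Display name.
#' @param kind `"higher_level"` (aggregating pathway, may have children) or
#'   `"lower_level"` (detailed reaction-level pathway; always a leaf).
#' @param children List of child `pathway_entry` objects.
#' @return A `pathway_entry`; a hierarchy is a single rooted tree of entries.
#' @export
pathway_entry <- function(stable_id, name, kind = c("higher_level",
                                                    "lower_level"),
                          children = list()) {
  kind <- match.arg(kind)
  if (kind == "lower_level" && length(children) > 0L) {
    stop("lower_level entry '", stable_id, "' cannot have children",
         call. = FALSE)
  }
  structure(list(stable_id = stable_id, name = as.character(name),
                 kind = kind, children = children),
            class = "pathway_entry")
}

hierarchy_ids <- function(entry) {
  c(entry$stable_id, unlist(lapply(entry$children, hierarchy_ids)))
}

# Enforces tree invariants: no id may repeat along or across branches (a
# repeat along a branch is reported as a cycle, which is what a nested file
# that names an ancestor as a child encodes).
validate_hierarchy <- function(entry, ancestors = character(0)) {
  if (entry$stable_id %in% ancestors) {
    stop("hierarchy cycle at '", entry$stable_id, "'", call. = FALSE)
  }
  for (ch in entry$children) {
    validate_hierarchy(ch, c(ancestors, entry$stable_id))
  }
  ids <- hierarchy_ids(entry)
  if (length(ancestors) == 0L && anyDuplicated(ids)) {
    stop("duplicate stable_id in hierarchy: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  invisible(entry)
}
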