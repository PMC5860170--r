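# Deterministic synthetic fixture generators: every input the toolkit
# consumes (diagram JSON, pathway hierarchy, annotated EHLD SVG, GMT
# pathway sets, query list) can be produced from a seeded specification,
# so the whole pipeline runs with no external data. Generated topology is
# deliberately schematic, not biologically realistic: nodes on a jittered
# grid, reactions between nearby nodes, subpathways as contiguous spatial
# clusters.

#' Specification for synthetic fixtures
#'
#' @param seed Integer seed; all generators are pure functions of the spec.
#' @param n_nodes,n_reactions,n_subpathways,n_compartments Diagram
#'   dimensions.
#' @param canvas Canvas bounds.
#' @param ehld_regions Number of annotated active regions in the generated
#'   EHLD.
#' @param universe_size,n_pathway_sets,set_size,query_size Analysis fixture
#'   dimensions.
#' @param hit_fraction Fraction of the query drawn from the planted
#'   enriched pathway's set (the remainder is background drawn uniformly
#'   from the rest of the universe).
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L, n_nodes = 12L, n_reactions = 6L,
                         n_subpathways = 3L, n_compartments = 1L,
                         canvas = rect(0, 0, 1000, 700),
                         ehld_regions = 4L, universe_size = 200L,
                         n_pathway_sets = 10L, set_size = 20L,
                         query_size = 20L, hit_fraction = 0.8) {
  stopifnot(n_nodes >= 0, n_reactions >= 0, n_subpathways >= 0,
            n_compartments >= 0, ehld_regions >= 0,
            hit_fraction >= 0, hit_fraction <= 1, is_rect(canvas))
  structure(list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
                 n_reactions = as.integer(n_reactions),
                 n_subpathways = as.integer(n_subpathways),
                 n_compartments = as.integer(n_compartments),
                 canvas = canvas, ehld_regions = as.integer(ehld_regions),
                 universe_size = as.integer(universe_size),
                 n_pathway_sets = as.integer(n_pathway_sets),
                 set_size = as.integer(set_size),
                 query_size = as.integer(query_size),
                 hit_fraction = hit_fraction),
            class = "fixture_spec")
}

# run code under a private seeded RNG stream, restoring the caller's state
with_fixture_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  force(code)
}

NODE_W <- 110
NODE_H <- 46

#' Generate a synthetic diagram document
#'
#' Nodes are placed on a jittered grid (no overlaps), reactions connect a
#' node to its nearest neighbour with a 0-2 bend backbone running through
#' the reaction point, and every reaction carries input and output
#' connectors (plus an occasional catalyst or inhibitor). Subpathways
#' partition the reactions into contiguous spatial clusters. The result
#' always passes [validate_diagram()], and identical specs give identical
#' output.
#'
#' @param spec A [fixture_spec()].
#' @return A `diagram_document` (with a subpathway assignment when
#'   `n_subpathways > 0`).
#' @export
generate_diagram <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_reactions > 0 && spec$n_nodes < 2L) {
    stop("need at least 2 nodes to draw reactions", call. = FALSE)
  }
  if (spec$n_subpathways > spec$n_reactions) {
    stop("more subpathways than reactions", call. = FALSE)
  }
  with_fixture_seed(spec$seed, 0L, {
    cv <- spec$canvas
    n <- spec$n_nodes
    ncol <- max(1L, ceiling(sqrt(n * cv$w / max(cv$h, 1))))
    nrow <- max(1L, ceiling(n / ncol))
    cell_w <- cv$w / ncol
    cell_h <- cv$h / nrow
    if (cell_w < NODE_W + 8 || cell_h < NODE_H + 8) {
      stop("overcrowded fixture: ", n, " nodes cannot fit a ",
           cv$w, "x", cv$h, " canvas", call. = FALSE)
    }
    classes <- sample(SCHEMA_CLASSES, n, replace = TRUE)
    nodes <- vector("list", n)
    for (i in seq_len(n)) {
      col <- (i - 1L) %% ncol
      row <- (i - 1L) %/% ncol
      jx <- stats::runif(1, 4, cell_w - NODE_W - 4)
      jy <- stats::runif(1, 4, cell_h - NODE_H - 4)
      nodes[[i]] <- node_glyph(
        paste0("N", i), classes[i],
        paste0(tools::toTitleCase(classes[i]), " ", i),
        rect(cv$x + col * cell_w + jx, cv$y + row * cell_h + jy,
             NODE_W, NODE_H))
    }
    compartments <- list()
    if (spec$n_compartments > 0L) {
      slab_w <- cv$w / spec$n_compartments
      for (k in seq_len(spec$n_compartments)) {
        outer <- rect(cv$x + (k - 1) * slab_w + 2, cv$y + 2, slab_w - 4,
                      cv$h - 4)
        compartments[[k]] <- compartment(
          paste0("C", k), paste0("compartment ", k), outer,
          inner = rect_pad(outer, -5))
      }
      cids <- vapply(compartments, `[[`, character(1), "id")
      for (i in seq_len(n)) {
        for (k in seq_along(compartments)) {
          if (rect_contains_rect(compartments[[k]]$outer,
                                 nodes[[i]]$bounds)) {
            nodes[[i]]$compartment_id <- cids[k]
            break
          }
        }
      }
    }
    centres <- t(vapply(nodes, function(nd) rect_centre(nd$bounds),
                        numeric(2)))
    clamp_pt <- function(p) {
      c(min(max(p[1], cv$x), rect_x2(cv)), min(max(p[2], cv$y), rect_y2(cv)))
    }
    edges <- vector("list", spec$n_reactions)
    for (r in seq_len(spec$n_reactions)) {
      a <- sample.int(n, 1L)
      d2 <- rowSums((centres - matrix(centres[a, ], n, 2,
                                      byrow = TRUE))^2)
      d2[a] <- Inf
      b <- which.min(d2)
      pa <- centres[a, ]
      pb <- centres[b, ]
      rp <- clamp_pt((pa + pb) / 2)
      seg <- matrix(pa, ncol = 2L)
      if (stats::runif(1) < 0.5) {
        seg <- rbind(seg, clamp_pt((pa + rp) / 2 +
                                     stats::runif(2, -20, 20)))
      }
      seg <- rbind(seg, rp)
      if (stats::runif(1) < 0.5) {
        seg <- rbind(seg, clamp_pt((rp + pb) / 2 +
                                     stats::runif(2, -20, 20)))
      }
      seg <- rbind(seg, pb)
      conns <- list(
        connector("input", nodes[[a]]$id, rbind(pa, rp)),
        connector("output", nodes[[b]]$id, rbind(pb, rp),
                  ending = "arrow"))
      if (n >= 3L && stats::runif(1) < 0.5) {
        d2[b] <- Inf
        cat_i <- which.min(d2)
        conns <- c(conns, list(connector(
          if (stats::runif(1) < 0.75) "catalyst" else "inhibitor",
          nodes[[cat_i]]$id, rbind(centres[cat_i, ], rp),
          ending = if (stats::runif(1) < 0.75) "circle" else "bar")))
      }
      # repair role/ending mismatches from independent draws
      conns <- lapply(conns, function(cn) {
        if (!cn$ending %in% ROLE_ENDINGS[[cn$role]]) cn$ending <- "none"
        cn
      })
      edges[[r]] <- reaction_edge(paste0("R", r), rp, seg, conns)
    }
    assignment <- NULL
    if (spec$n_subpathways > 0L && spec$n_reactions > 0L) {
      rx <- vapply(edges, function(e) e$reaction_point[1], numeric(1))
      ord <- order(rx, vapply(edges, `[[`, character(1), "id"))
      cuts <- split(ord, cut(seq_along(ord), spec$n_subpathways,
                             labels = FALSE))
      groups <- lapply(cuts, function(ix) {
        vapply(edges[ix], `[[`, character(1), "id")
      })
      names(groups) <- sprintf("SP%d", seq_along(groups))
      assignment <- subpathway_assignment(
        "PW-FIXTURE", groups,
        display_names = stats::setNames(
          sprintf("Subpathway %s cluster", seq_along(groups)),
          names(groups)))
    }
    diagram <- pathway_diagram("PW-FIXTURE", cv, nodes, edges,
                               compartments)
    diagram_document(diagram, assignment)
  })
}

#' Generate a synthetic pathway hierarchy
#'
#' A three-level tree: one higher-level root, a rank of higher-level
#' children, and lower-level leaves distributed among them.
#'
#' @param spec A [fixture_spec()].
#' @param n_entries Total number of entries including the root.
#' @return The root [pathway_entry()].
#' @export
generate_hierarchy <- function(spec, n_entries = 12L) {
  stopifnot(n_entries >= 1L)
  with_fixture_seed(spec$seed, 1L, {
    if (n_entries == 1L) {
      return(pathway_entry("HLP-1", "Root process", "higher_level"))
    }
    n_mid <- max(1L, floor(sqrt(n_entries - 1L)))
    n_leaf <- n_entries - 1L - n_mid
    leaf_owner <- if (n_leaf > 0L) {
      sort(sample.int(n_mid, n_leaf, replace = TRUE))
    } else integer(0)
    leaf_id <- 0L
    mids <- lapply(seq_len(n_mid), function(m) {
      kids <- lapply(which(leaf_owner == m), function(ignored) {
        leaf_id <<- leaf_id + 1L
        pathway_entry(sprintf("LLP-%d", leaf_id),
                      sprintf("Detailed pathway %d", leaf_id),
                      "lower_level")
      })
      pathway_entry(sprintf("HLP-%d", m + 1L),
                    sprintf("Domain %d", m), "higher_level", kids)
    })
    pathway_entry("HLP-1", "Root process", "higher_level", mids)
  })
}

#' Generate a synthetic annotated EHLD
#'
#' An SVG document with `ehld_regions` annotated subpathway triples
#' (`REGION-`/`TEXT-`/`OVERLAY-` ids over the default [ehld_config()]
#' conventions) laid out on a grid, plus decorative elements with no
#' technical annotation (background, a membrane-like path, connecting
#' arrows). Parsing the result yields exactly `ehld_regions` active
#' regions.
#'
#' @param spec A [fixture_spec()].
#' @return SVG text.
#' @export
generate_ehld <- function(spec) {
  with_fixture_seed(spec$seed, 2L, {
    W <- 1200; H <- 800
    root <- svg_root(c(0, 0, W, H), W, H)
    # decorations: no technical annotation
    add_rect_el(root, rect(0, 0, W, H), fill = "#F4F9FF", id = "deco-bg")
    xml2::xml_add_child(root, "path",
                        d = sprintf("M 0 %g C %g %g %g %g %g %g",
                                    H * 0.85, W * 0.3, H * 0.7, W * 0.7,
                                    H * 0.95, W, H * 0.8),
                        fill = "none", stroke = "#B8CFE5",
                        "stroke-width" = "8", id = "deco-membrane")
    k <- spec$ehld_regions
    if (k > 0L) {
      ncol <- ceiling(sqrt(k))
      nrow <- ceiling(k / ncol)
      cw <- W / ncol
      chh <- (H * 0.8) / nrow
      for (i in seq_len(k)) {
        col <- (i - 1L) %% ncol
        row <- (i - 1L) %/% ncol
        pid <- paste0("EH", i)
        x <- col * cw + stats::runif(1, 8, 20)
        y <- row * chh + stats::runif(1, 8, 20)
        w <- cw - 50
        h <- chh - 60
        g <- xml2::xml_add_child(root, "g", class = "subpathway-art")
        add_rect_el(g, rect(x, y, w, h), id = paste0("REGION-", pid),
                    fill = sprintf("#%02X%02XD8",
                                   100 + (i * 37) %% 120,
                                   120 + (i * 53) %% 100),
                    stroke = "#5A7A9A", rx = "12")
        # a decoration inside the region (iconography stand-in)
        xml2::xml_add_child(g, "circle", cx = fmt_num(x + w * 0.3),
                            cy = fmt_num(y + h * 0.4),
                            r = fmt_num(min(w, h) * 0.15),
                            fill = "#FFFFFF", stroke = "#5A7A9A")
        add_rect_el(g, rect(x + w * 0.1, y + h - 34, w * 0.8, 22),
                    id = paste0("OVERLAY-", pid), fill = "#FFFFFF",
                    "fill-opacity" = "0.65")
        xml2::xml_add_child(g, "text", x = fmt_num(x + w * 0.12),
                            y = fmt_num(y + h - 18), "font-size" = "16",
                            id = paste0("TEXT-", pid),
                            paste("Subprocess", i))
      }
    }
    as.character(root)
  })
}

#' Generate an analysis fixture with a planted enriched pathway
#'
#' Draws `n_pathway_sets` pathway sets of `set_size` entities from a
#' universe of `universe_size`, designates one as enriched, and builds a
#' query of `query_size` identifiers of which a fraction `hit_fraction`
#' comes from the enriched set and the remainder is background drawn
#' uniformly from the rest of the universe.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `sets` (a [entity_sets()]), `query` (character
#'   vector) and `truth` (list with `enriched`, the planted pathway id).
#' @export
generate_analysis_fixture <- function(spec) {
  stopifnot(spec$universe_size >= 10L)
  with_fixture_seed(spec$seed, 3L, {
    universe <- sprintf("ENT%05d", seq_len(spec$universe_size))
    sets <- lapply(seq_len(spec$n_pathway_sets), function(i) {
      sample(universe, min(spec$set_size, spec$universe_size))
    })
    # pathway ids line up with the generated EHLD's region ids so the two
    # fixtures compose into an end-to-end overlay run
    names(sets) <- sprintf("EH%d", seq_len(spec$n_pathway_sets))
    enriched <- sample(names(sets), 1L)
    n_hit <- min(round(spec$hit_fraction * spec$query_size),
                 length(sets[[enriched]]))
    hits <- sample(sets[[enriched]], n_hit)
    pool <- setdiff(universe, sets[[enriched]])
    n_bg <- min(spec$query_size - n_hit, length(pool))
    query <- c(hits, sample(pool, n_bg))
    list(sets = entity_sets(sets, universe = universe), query = query,
         truth = list(enriched = enriched))
  })
}

#' Write a complete fixture directory
#'
#' Materialises every generated input as files: `diagram.json`,
#' `hierarchy.json`, `ehld.svg`, `sets.gmt` and `query.txt`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_dir <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(diagram = file.path(dir, "diagram.json"),
             hierarchy = file.path(dir, "hierarchy.json"),
             ehld = file.path(dir, "ehld.svg"),
             sets = file.path(dir, "sets.gmt"),
             query = file.path(dir, "query.txt"))
  write_diagram(generate_diagram(spec), paths[["diagram"]])
  write_hierarchy(generate_hierarchy(spec), paths[["hierarchy"]])
  writeLines(generate_ehld(spec), paths[["ehld"]], useBytes = TRUE)
  fx <- generate_analysis_fixture(spec)
  write_gmt(fx$sets, paths[["sets"]])
  writeLines(fx$query, paths[["query"]], useBytes = TRUE)
  invisible(paths)
}
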