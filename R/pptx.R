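# Editable presentation export.
#
# A classic diagram is converted into an anchored shape graph: every glyph,
# reaction centre and line bend becomes a shape, and every line segment
# becomes a connector whose two endpoints REFERENCE shapes — never bare
# coordinates. Invisible anchor shapes (no fill, no line) join the segments
# of one reaction line, and the shapes that visually define reaction
# properties (catalysis/regulation line endings) are grouped with their
# final segment, so that moving a glyph in a presentation editor drags the
# whole attached line along. The OOXML package is written directly.

EMU_PER_UNIT <- 9525  # 1 canvas unit = 1 px at 96 dpi = 9525 EMU

ANCHOR_SIZE <- 2     # canvas units; selectable but invisible
CENTRE_SIZE <- 6     # reaction-node square
DECOR_SIZE <- 8      # catalysis circle / inhibition bar extent

node_prst <- function(schema_class) {
  switch(schema_class,
         protein = "roundRect", entity_set = "roundRect",
         chemical = "ellipse", complex = "round2SameRect",
         gene = "rect", rna = "rect", process_node = "rect",
         "rect")
}

#' Build the anchored shape graph of a diagram
#'
#' Conversion rule: each node glyph becomes one autoshape styled per schema
#' class; each reaction gets a small centre shape at its reaction point;
#' every polyline (backbone and role connectors) with k interior bends
#' contributes k invisible anchor shapes and k+1 connectors chained through
#' them. Polyline points within `eps` of the reaction point attach to the
#' centre shape; endpoints inside a node's bounds attach to that node's
#' shape; any other endpoint gets its own anchor. Output connectors carry an
#' arrowhead; catalysis/activation and inhibition endings become small
#' decoration shapes (circle, bar) grouped with their final connector.
#'
#' @param diagram A valid [pathway_diagram()].
#' @param profile A [color_profile()].
#' @param eps Attachment tolerance in canvas units (default 0.5).
#' @return An `anchored_shape_graph` with fields `shapes` (named list),
#'   `connectors` (list of `{id, from, to, ending, dashed}`), `groups`
#'   (list of id vectors) and `slide_size`.
#' @export
build_shape_graph <- function(diagram, profile = color_profile(),
                              eps = 0.5) {
  violations <- validate_diagram(diagram, eps = eps)
  if (length(violations)) {
    stop("cannot export invalid diagram:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  shapes <- list()
  connectors <- list()
  groups <- list()
  add_shape <- function(id, kind, r, ...) {
    shapes[[id]] <<- c(list(id = id, kind = kind, x = r$x, y = r$y,
                            w = r$w, h = r$h), list(...))
    id
  }
  for (n in diagram$nodes) {
    add_shape(n$id, "node", n$bounds,
              prst = node_prst(n$schema_class),
              fill = unname(profile$node_fill[n$schema_class]),
              stroke = unname(profile$node_stroke[n$schema_class]),
              text = n$display_name)
  }
  node_list <- diagram$nodes
  near <- function(p, q) sqrt(sum((p - q)^2)) <= eps
  for (e in diagram$edges) {
    rp <- e$reaction_point
    centre_id <- add_shape(
      paste0(e$id, "::centre"), "reaction_centre",
      rect(rp[1] - CENTRE_SIZE / 2, rp[2] - CENTRE_SIZE / 2,
           CENTRE_SIZE, CENTRE_SIZE),
      prst = "rect", fill = "#FFFFFF", stroke = "#000000", text = NULL)
    anchor_n <- 0L
    new_anchor <- function(p) {
      anchor_n <<- anchor_n + 1L
      add_shape(paste0(e$id, "::a", anchor_n), "anchor",
                rect(p[1] - ANCHOR_SIZE / 2, p[2] - ANCHOR_SIZE / 2,
                     ANCHOR_SIZE, ANCHOR_SIZE),
                prst = "rect", fill = NULL, stroke = NULL, text = NULL)
    }
    resolve_end <- function(p, own_node_id = NULL) {
      if (near(p, rp)) return(centre_id)
      if (!is.null(own_node_id)) {
        nd <- find_node(diagram, own_node_id)
        if (rect_contains_point(rect_pad(nd$bounds, eps), p[1], p[2])) {
          return(own_node_id)
        }
      }
      for (nd in node_list) {
        if (rect_contains_point(nd$bounds, p[1], p[2])) return(nd$id)
      }
      new_anchor(p)
    }
    conn_n <- 0L
    chain <- function(pts, own_node_id = NULL, ending = "none",
                      tag = "seg") {
      m <- nrow(pts)
      ids <- character(m)
      ids[1] <- resolve_end(pts[1, ], own_node_id)
      if (m > 2L) {
        for (i in 2:(m - 1L)) {
          ids[i] <- if (near(pts[i, ], rp)) centre_id else new_anchor(pts[i, ])
        }
      }
      ids[m] <- resolve_end(pts[m, ])
      last_conn_id <- NULL
      for (i in seq_len(m - 1L)) {
        conn_n <<- conn_n + 1L
        cid <- paste0(e$id, "::", tag, conn_n)
        connectors[[length(connectors) + 1L]] <<-
          list(id = cid, from = ids[i], to = ids[i + 1L],
               ending = if (i == m - 1L) ending else "none")
        last_conn_id <- cid
      }
      list(last_conn = last_conn_id, tip = pts[m, ])
    }
    chain(e$segments, tag = "b")
    dec_n <- 0L
    for (cn in e$connectors) {
      res <- chain(cn$points, own_node_id = cn$node_id,
                   ending = if (cn$ending == "arrow") "arrow" else "none",
                   tag = "c")
      if (cn$ending %in% c("circle", "bar")) {
        dec_n <- dec_n + 1L
        tip <- res$tip
        dec_id <- if (cn$ending == "circle") {
          add_shape(paste0(e$id, "::dec", dec_n), "decoration",
                    rect(tip[1] - DECOR_SIZE / 2, tip[2] - DECOR_SIZE / 2,
                         DECOR_SIZE, DECOR_SIZE),
                    prst = "ellipse", fill = "#FFFFFF",
                    stroke = "#000000", text = NULL)
        } else {
          add_shape(paste0(e$id, "::dec", dec_n), "decoration",
                    rect(tip[1] - DECOR_SIZE / 2, tip[2] - 1.5,
                         DECOR_SIZE, 3),
                    prst = "rect", fill = "#000000", stroke = "#000000",
                    text = NULL)
        }
        if (!is.null(res$last_conn)) {
          groups[[length(groups) + 1L]] <- c(dec_id, res$last_conn)
        }
      }
    }
  }
  structure(list(shapes = shapes, connectors = connectors, groups = groups,
                 slide_size = c(diagram$canvas$w + diagram$canvas$x,
                                diagram$canvas$h + diagram$canvas$y)),
            class = "anchored_shape_graph")
}

#' @export
print.anchored_shape_graph <- function(x, ...) {
  kinds <- table(vapply(x$shapes, `[[`, character(1), "kind"))
  cat(sprintf(
    "<anchored_shape_graph: %d shapes (%s), %d connectors, %d groups>\n",
    length(x$shapes),
    paste(sprintf("%s=%d", names(kinds), as.integer(kinds)),
          collapse = ", "),
    length(x$connectors), length(x$groups)))
  invisible(x)
}

emu <- function(x) format(round(x * EMU_PER_UNIT), scientific = FALSE,
                          trim = TRUE)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  s <- gsub("\"", "&quot;", s, fixed = TRUE)
  s
}

srgb <- function(col) sub("^#", "", toupper(substr(col, 1, 7)))

# connection-site index on a rectangular preset: nearest of the four
# side-midpoint sites (0 top, 1 left, 2 bottom, 3 right) to the other end
cxn_site <- function(shape, toward) {
  cx <- shape$x + shape$w / 2
  cy <- shape$y + shape$h / 2
  dx <- toward[1] - cx
  dy <- toward[2] - cy
  if (abs(dx) >= abs(dy)) {
    if (dx >= 0) 3L else 1L
  } else {
    if (dy >= 0) 2L else 0L
  }
}

shape_centre <- function(s) c(s$x + s$w / 2, s$y + s$h / 2)

sp_xml <- function(s, num_id) {
  fill <- if (is.null(s$fill)) "<a:noFill/>" else {
    sprintf('<a:solidFill><a:srgbClr val="%s"/></a:solidFill>',
            srgb(s$fill))
  }
  line <- if (is.null(s$stroke)) "<a:ln><a:noFill/></a:ln>" else {
    sprintf('<a:ln w="12700"><a:solidFill><a:srgbClr val="%s"/></a:solidFill></a:ln>',
            srgb(s$stroke))
  }
  txt <- if (is.null(s$text)) "" else sprintf(
    '<p:txBody><a:bodyPr anchor="ctr"/><a:lstStyle/><a:p><a:pPr algn="ctr"/><a:r><a:rPr lang="en-US" sz="900"><a:solidFill><a:srgbClr val="000000"/></a:solidFill></a:rPr><a:t>%s</a:t></a:r></a:p></p:txBody>',
    xml_escape(s$text))
  sprintf(paste0(
    '<p:sp><p:nvSpPr><p:cNvPr id="%d" name="%s"/><p:cNvSpPr/><p:nvPr/></p:nvSpPr>',
    '<p:spPr><a:xfrm><a:off x="%s" y="%s"/><a:ext cx="%s" cy="%s"/></a:xfrm>',
    '<a:prstGeom prst="%s"><a:avLst/></a:prstGeom>%s%s</p:spPr>%s</p:sp>'),
    num_id, xml_escape(s$id), emu(s$x), emu(s$y), emu(s$w), emu(s$h),
    s$prst, fill, line, txt)
}

cxn_xml <- function(cn, num_id, shapes, num_ids) {
  from <- shapes[[cn$from]]
  to <- shapes[[cn$to]]
  p1 <- shape_centre(from)
  p2 <- shape_centre(to)
  x <- min(p1[1], p2[1]); y <- min(p1[2], p2[2])
  w <- abs(p1[1] - p2[1]); h <- abs(p1[2] - p2[2])
  flip <- paste0(if (p2[1] < p1[1]) ' flipH="1"' else "",
                 if (p2[2] < p1[2]) ' flipV="1"' else "")
  head <- if (identical(cn$ending, "arrow")) {
    '<a:tailEnd type="triangle" w="med" len="med"/>'
  } else ""
  sprintf(paste0(
    '<p:cxnSp><p:nvCxnSpPr><p:cNvPr id="%d" name="%s"/>',
    '<p:cNvCxnSpPr><a:stCxn id="%d" idx="%d"/><a:endCxn id="%d" idx="%d"/></p:cNvCxnSpPr>',
    '<p:nvPr/></p:nvCxnSpPr>',
    '<p:spPr><a:xfrm%s><a:off x="%s" y="%s"/><a:ext cx="%s" cy="%s"/></a:xfrm>',
    '<a:prstGeom prst="line"><a:avLst/></a:prstGeom>',
    '<a:ln w="9525"><a:solidFill><a:srgbClr val="000000"/></a:solidFill>%s</a:ln>',
    '</p:spPr></p:cxnSp>'),
    num_id, xml_escape(cn$id),
    num_ids[[cn$from]], cxn_site(from, p2),
    num_ids[[cn$to]], cxn_site(to, p1),
    flip, emu(x), emu(y), emu(w), emu(h), head)
}

#' Write an anchored shape graph as an OOXML presentation
#'
#' Produces a single-slide PresentationML package. Connectors are
#' serialized with start and end connection references (`stCxn`/`endCxn`)
#' to shape ids, so moving a glyph in an editor drags every attached line
#' along; anchor shapes carry no fill and no line. Canvas units are
#' converted to EMU at 9525 EMU per unit (1 unit = 1 px at 96 dpi). The
#' writer emits identical bytes for identical graphs (fixed timestamps).
#'
#' @param graph An [build_shape_graph()] result.
#' @param path Output `.pptx` path.
#' @param slide_size Slide width/height in canvas units (default: the
#'   graph's own extent).
#' @return `path`, invisibly. Validate with [verify_export()].
#' @export
write_pptx <- function(graph, path, slide_size = NULL) {
  stopifnot(inherits(graph, "anchored_shape_graph"))
  if (is.null(slide_size)) slide_size <- graph$slide_size
  grouped_ids <- unlist(graph$groups)
  num_ids <- list()
  next_id <- 2L
  take_id <- function() {
    id <- next_id
    next_id <<- next_id + 1L
    id
  }
  for (sid in names(graph$shapes)) num_ids[[sid]] <- take_id()
  body <- character(0)
  for (sid in names(graph$shapes)) {
    if (sid %in% grouped_ids) next
    body <- c(body, sp_xml(graph$shapes[[sid]], num_ids[[sid]]))
  }
  conn_by_id <- stats::setNames(graph$connectors,
                                vapply(graph$connectors, `[[`,
                                       character(1), "id"))
  for (cn in graph$connectors) {
    if (cn$id %in% grouped_ids) next
    body <- c(body, cxn_xml(cn, take_id(), graph$shapes, num_ids))
  }
  for (grp in graph$groups) {
    members_s <- grp[grp %in% names(graph$shapes)]
    members_c <- grp[grp %in% names(conn_by_id)]
    rects <- lapply(members_s, function(sid) {
      s <- graph$shapes[[sid]]
      rect(s$x, s$y, s$w, s$h)
    })
    for (cid in members_c) {
      cn <- conn_by_id[[cid]]
      for (end in c(cn$from, cn$to)) {
        s <- graph$shapes[[end]]
        rects <- c(rects, list(rect(s$x, s$y, s$w, s$h)))
      }
    }
    bb <- rect_union(rects)
    inner <- character(0)
    for (sid in members_s) {
      inner <- c(inner, sp_xml(graph$shapes[[sid]], num_ids[[sid]]))
    }
    for (cid in members_c) {
      inner <- c(inner, cxn_xml(conn_by_id[[cid]], take_id(),
                                graph$shapes, num_ids))
    }
    body <- c(body, sprintf(paste0(
      '<p:grpSp><p:nvGrpSpPr><p:cNvPr id="%d" name="%s"/>',
      '<p:cNvGrpSpPr/><p:nvPr/></p:nvGrpSpPr>',
      '<p:grpSpPr><a:xfrm><a:off x="%s" y="%s"/><a:ext cx="%s" cy="%s"/>',
      '<a:chOff x="%s" y="%s"/><a:chExt cx="%s" cy="%s"/></a:xfrm></p:grpSpPr>',
      '%s</p:grpSp>'),
      take_id(), xml_escape(paste0("group-", grp[1])),
      emu(bb$x), emu(bb$y), emu(bb$w), emu(bb$h),
      emu(bb$x), emu(bb$y), emu(bb$w), emu(bb$h),
      paste(inner, collapse = "")))
  }
  slide <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<p:sld xmlns:a="http://schemas.openxmlformats.org/drawingml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships" ',
    'xmlns:p="http://schemas.openxmlformats.org/presentationml/2006/main">',
    '<p:cSld><p:spTree><p:nvGrpSpPr><p:cNvPr id="1" name=""/>',
    '<p:cNvGrpSpPr/><p:nvPr/></p:nvGrpSpPr><p:grpSpPr/>',
    '%s</p:spTree></p:cSld><p:clrMapOvr><a:masterClrMapping/></p:clrMapOvr></p:sld>'),
    paste(body, collapse = ""))
  entries <- pptx_static_parts(slide_size)
  entries[["ppt/slides/slide1.xml"]] <- slide
  zip_write(path, entries)
  invisible(path)
}

pptx_static_parts <- function(slide_size) {
  ct <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/ppt/presentation.xml" ContentType="application/vnd.openxmlformats-officedocument.presentationml.presentation.main+xml"/>',
    '<Override PartName="/ppt/slideMasters/slideMaster1.xml" ContentType="application/vnd.openxmlformats-officedocument.presentationml.slideMaster+xml"/>',
    '<Override PartName="/ppt/slideLayouts/slideLayout1.xml" ContentType="application/vnd.openxmlformats-officedocument.presentationml.slideLayout+xml"/>',
    '<Override PartName="/ppt/slides/slide1.xml" ContentType="application/vnd.openxmlformats-officedocument.presentationml.slide+xml"/>',
    '<Override PartName="/ppt/theme/theme1.xml" ContentType="application/vnd.openxmlformats-officedocument.theme+xml"/>',
    '</Types>')
  root_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="ppt/presentation.xml"/>',
    '</Relationships>')
  pres <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<p:presentation xmlns:a="http://schemas.openxmlformats.org/drawingml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships" ',
    'xmlns:p="http://schemas.openxmlformats.org/presentationml/2006/main">',
    '<p:sldMasterIdLst><p:sldMasterId id="2147483648" r:id="rId1"/></p:sldMasterIdLst>',
    '<p:sldIdLst><p:sldId id="256" r:id="rId2"/></p:sldIdLst>',
    '<p:sldSz cx="%s" cy="%s"/><p:notesSz cx="6858000" cy="9144000"/>',
    '</p:presentation>'),
    emu(slide_size[1]), emu(slide_size[2]))
  pres_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/slideMaster" Target="slideMasters/slideMaster1.xml"/>',
    '<Relationship Id="rId2" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/slide" Target="slides/slide1.xml"/>',
    '</Relationships>')
  empty_tree <- paste0(
    '<p:cSld><p:spTree><p:nvGrpSpPr><p:cNvPr id="1" name=""/>',
    '<p:cNvGrpSpPr/><p:nvPr/></p:nvGrpSpPr><p:grpSpPr/></p:spTree></p:cSld>')
  master <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<p:sldMaster xmlns:a="http://schemas.openxmlformats.org/drawingml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships" ',
    'xmlns:p="http://schemas.openxmlformats.org/presentationml/2006/main">',
    empty_tree,
    '<p:clrMap bg1="lt1" tx1="dk1" bg2="lt2" tx2="dk2" accent1="accent1" ',
    'accent2="accent2" accent3="accent3" accent4="accent4" accent5="accent5" ',
    'accent6="accent6" hlink="hlink" folHlink="folHlink"/>',
    '<p:sldLayoutIdLst><p:sldLayoutId id="2147483649" r:id="rId1"/></p:sldLayoutIdLst>',
    '</p:sldMaster>')
  master_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/slideLayout" Target="../slideLayouts/slideLayout1.xml"/>',
    '<Relationship Id="rId2" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/theme" Target="../theme/theme1.xml"/>',
    '</Relationships>')
  layout <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<p:sldLayout xmlns:a="http://schemas.openxmlformats.org/drawingml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships" ',
    'xmlns:p="http://schemas.openxmlformats.org/presentationml/2006/main" type="blank">',
    empty_tree,
    '<p:clrMapOvr><a:overrideClrMapping bg1="lt1" tx1="dk1" bg2="lt2" tx2="dk2" ',
    'accent1="accent1" accent2="accent2" accent3="accent3" accent4="accent4" ',
    'accent5="accent5" accent6="accent6" hlink="hlink" folHlink="folHlink"/></p:clrMapOvr>',
    '</p:sldLayout>')
  layout_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/slideMaster" Target="../slideMasters/slideMaster1.xml"/>',
    '</Relationships>')
  slide_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/slideLayout" Target="../slideLayouts/slideLayout1.xml"/>',
    '</Relationships>')
  theme <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<a:theme xmlns:a="http://schemas.openxmlformats.org/drawingml/2006/main" name="Plain">',
    '<a:themeElements><a:clrScheme name="Plain">',
    '<a:dk1><a:srgbClr val="000000"/></a:dk1><a:lt1><a:srgbClr val="FFFFFF"/></a:lt1>',
    '<a:dk2><a:srgbClr val="44546A"/></a:dk2><a:lt2><a:srgbClr val="E7E6E6"/></a:lt2>',
    '<a:accent1><a:srgbClr val="4472C4"/></a:accent1><a:accent2><a:srgbClr val="ED7D31"/></a:accent2>',
    '<a:accent3><a:srgbClr val="A5A5A5"/></a:accent3><a:accent4><a:srgbClr val="FFC000"/></a:accent4>',
    '<a:accent5><a:srgbClr val="5B9BD5"/></a:accent5><a:accent6><a:srgbClr val="70AD47"/></a:accent6>',
    '<a:hlink><a:srgbClr val="0563C1"/></a:hlink><a:folHlink><a:srgbClr val="954F72"/></a:folHlink>',
    '</a:clrScheme><a:fontScheme name="Plain">',
    '<a:majorFont><a:latin typeface="Arial"/><a:ea typeface=""/><a:cs typeface=""/></a:majorFont>',
    '<a:minorFont><a:latin typeface="Arial"/><a:ea typeface=""/><a:cs typeface=""/></a:minorFont>',
    '</a:fontScheme><a:fmtScheme name="Plain">',
    '<a:fillStyleLst><a:solidFill><a:schemeClr val="phClr"/></a:solidFill>',
    '<a:solidFill><a:schemeClr val="phClr"/></a:solidFill>',
    '<a:solidFill><a:schemeClr val="phClr"/></a:solidFill></a:fillStyleLst>',
    '<a:lnStyleLst><a:ln w="6350"><a:solidFill><a:schemeClr val="phClr"/></a:solidFill></a:ln>',
    '<a:ln w="12700"><a:solidFill><a:schemeClr val="phClr"/></a:solidFill></a:ln>',
    '<a:ln w="19050"><a:solidFill><a:schemeClr val="phClr"/></a:solidFill></a:ln></a:lnStyleLst>',
    '<a:effectStyleLst><a:effectStyle><a:effectLst/></a:effectStyle>',
    '<a:effectStyle><a:effectLst/></a:effectStyle>',
    '<a:effectStyle><a:effectLst/></a:effectStyle></a:effectStyleLst>',
    '<a:bgFillStyleLst><a:solidFill><a:schemeClr val="phClr"/></a:solidFill>',
    '<a:solidFill><a:schemeClr val="phClr"/></a:solidFill>',
    '<a:solidFill><a:schemeClr val="phClr"/></a:solidFill></a:bgFillStyleLst>',
    '</a:fmtScheme></a:themeElements></a:theme>')
  list(
    "[Content_Types].xml" = ct,
    "_rels/.rels" = root_rels,
    "ppt/presentation.xml" = pres,
    "ppt/_rels/presentation.xml.rels" = pres_rels,
    "ppt/slideMasters/slideMaster1.xml" = master,
    "ppt/slideMasters/_rels/slideMaster1.xml.rels" = master_rels,
    "ppt/slideLayouts/slideLayout1.xml" = layout,
    "ppt/slideLayouts/_rels/slideLayout1.xml.rels" = layout_rels,
    "ppt/theme/theme1.xml" = theme,
    "ppt/slides/_rels/slide1.xml.rels" = slide_rels
  )
}

PML_NS <- c(p = "http://schemas.openxmlformats.org/presentationml/2006/main",
            a = "http://schemas.openxmlformats.org/drawingml/2006/main",
            rel = "http://schemas.openxmlformats.org/package/2006/relationships")

#' Structurally validate an exported presentation
#'
#' Re-opens a `.pptx` file and checks the contract that makes the export
#' editable: every connector must carry both a start and an end connection
#' reference, every reference must resolve to a shape present on the slide,
#' and every top-level shape must lie within the slide bounds. Package
#' structure is checked too (required parts present, all relationship
#' targets resolving).
#'
#' @param path Path to a `.pptx` file.
#' @return A `pptx_report` list with counts `dangling_refs`,
#'   `unattached_connectors`, `out_of_bounds`, `missing_parts`,
#'   `unresolved_rels`, totals `n_shapes`/`n_connectors`, and the logical
#'   `ok` (TRUE iff all defect counts are zero).
#' @export
verify_export <- function(path) {
  exdir <- zip_extract(path)
  on.exit(unlink(exdir, recursive = TRUE))
  required <- c("[Content_Types].xml", "_rels/.rels",
                "ppt/presentation.xml", "ppt/slides/slide1.xml")
  present <- file.exists(file.path(exdir, required))
  missing_parts <- sum(!present)
  unresolved <- 0L
  rels_files <- list.files(exdir, pattern = "\\.rels$", recursive = TRUE,
                           full.names = TRUE, all.files = TRUE)
  for (rf in rels_files) {
    rels <- xml2::read_xml(rf)
    targets <- xml2::xml_attr(
      xml2::xml_find_all(rels, "//rel:Relationship", PML_NS), "Target")
    modes <- xml2::xml_attr(
      xml2::xml_find_all(rels, "//rel:Relationship", PML_NS), "TargetMode")
    base <- dirname(dirname(rf))  # .rels live in <base>/_rels/
    for (k in seq_along(targets)) {
      if (!is.na(modes[k]) && modes[k] == "External") next
      tp <- normalizePath(file.path(base, targets[k]), mustWork = FALSE)
      if (!file.exists(tp)) unresolved <- unresolved + 1L
    }
  }
  dangling <- 0L
  unattached <- 0L
  oob <- 0L
  n_shapes <- 0L
  n_conn <- 0L
  slide_path <- file.path(exdir, "ppt/slides/slide1.xml")
  if (file.exists(slide_path)) {
    slide <- xml2::read_xml(slide_path)
    ids <- xml2::xml_attr(
      xml2::xml_find_all(slide, "//p:sp/p:nvSpPr/p:cNvPr", PML_NS), "id")
    n_shapes <- length(ids)
    cxns <- xml2::xml_find_all(slide, "//p:cxnSp", PML_NS)
    n_conn <- length(cxns)
    for (cx in cxns) {
      st <- xml2::xml_find_first(cx, ".//a:stCxn", PML_NS)
      en <- xml2::xml_find_first(cx, ".//a:endCxn", PML_NS)
      if (inherits(st, "xml_missing") || inherits(en, "xml_missing")) {
        unattached <- unattached + 1L
        next
      }
      for (ref in c(xml2::xml_attr(st, "id"), xml2::xml_attr(en, "id"))) {
        if (!ref %in% ids) dangling <- dangling + 1L
      }
    }
    sz <- c(NA_real_, NA_real_)
    pres_path <- file.path(exdir, "ppt/presentation.xml")
    if (file.exists(pres_path)) {
      pres <- xml2::read_xml(pres_path)
      sldsz <- xml2::xml_find_first(pres, "//p:sldSz", PML_NS)
      sz <- c(as.numeric(xml2::xml_attr(sldsz, "cx")),
              as.numeric(xml2::xml_attr(sldsz, "cy")))
    }
    if (all(is.finite(sz))) {
      tops <- xml2::xml_find_all(
        slide, "/p:sld/p:cSld/p:spTree/*[self::p:sp or self::p:grpSp]",
        PML_NS)
      for (el in tops) {
        off <- xml2::xml_find_first(el, ".//a:off", PML_NS)
        ext <- xml2::xml_find_first(el, ".//a:ext", PML_NS)
        if (inherits(off, "xml_missing")) next
        x <- as.numeric(xml2::xml_attr(off, "x"))
        y <- as.numeric(xml2::xml_attr(off, "y"))
        cx <- as.numeric(xml2::xml_attr(ext, "cx"))
        cy <- as.numeric(xml2::xml_attr(ext, "cy"))
        if (x < 0 || y < 0 || x + cx > sz[1] || y + cy > sz[2]) {
          oob <- oob + 1L
        }
      }
    }
  }
  report <- list(dangling_refs = dangling,
                 unattached_connectors = unattached,
                 out_of_bounds = oob, missing_parts = missing_parts,
                 unresolved_rels = unresolved,
                 n_shapes = n_shapes, n_connectors = n_conn)
  report$ok <- dangling + unattached + oob + missing_parts +
    unresolved == 0L
  structure(report, class = "pptx_report")
}

#' @export
print.pptx_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<pptx_report: %s>\n  shapes: %d, connectors: %d\n",
    "  dangling refs: %d, unattached connectors: %d, out of bounds: %d\n",
    "  missing parts: %d, unresolved relationships: %d\n"),
    if (x$ok) "OK" else "DEFECTS FOUND", x$n_shapes, x$n_connectors,
    x$dangling_refs, x$unattached_connectors, x$out_of_bounds,
    x$missing_parts, x$unresolved_rels))
  invisible(x)
}

#' Export a diagram straight to PPTX
#'
#' Convenience wrapper: [build_shape_graph()] then [write_pptx()].
#'
#' @inheritParams build_shape_graph
#' @param path Output `.pptx` path.
#' @return The `anchored_shape_graph`, invisibly.
#' @export
export_pptx <- function(diagram, path, profile = color_profile()) {
  graph <- build_shape_graph(diagram, profile)
  write_pptx(graph, path)
  invisible(graph)
}
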