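# pathcanvas

Interactive pathway-diagram rendering, subpathway highlighting, analysis
overlays, and editable presentation export for hierarchical pathway
knowledge bases.

Curated pathway databases organise biology hierarchically: broad domains
(immune system, cell cycle) aggregate subpathways down to detailed
diagrams in which molecular events are drawn as SBGN-style reactions.
`pathcanvas` implements the visual layer of such a resource as a
standalone R toolkit, for bioinformaticians building pathway portals or
preparing publication figures:

- **Classic diagram model and IO** — a geometric model of lower-level
  pathway diagrams (glyph nodes, segmented reaction edges with role-typed
  connectors, compartments), a canonical JSON exchange format
  (`docs/format-diagram.md`), SVG rendering with zoom-dependent label
  omission, and navigation thumbnails.
- **Subpathway highlighting** — each subpathway of a diagram gets a
  coloured box around its member reactions. The label is placed by a
  space-partitioning rule: among all *maximal empty rectangles* of the box
  left after overlapping it with every other subpathway box, the largest
  and widest one wins, and the label font is sized to fit (omitted when
  nothing legible fits). Boxes fade out linearly as the user zooms in.
  The whole computation is deterministic, so it can be precomputed once
  per data release and reused unchanged.
- **Interactive EHLDs** — textbook-style SVG illustrations of higher-level
  pathways made interactive by three technical annotations per subpathway
  (clickable region, label, overlay slot; `docs/format-ehld.md`).
  Supports hit-testing, hover/selection/flagging states, and lossless SVG
  re-export with or without the analysis overlay.
- **Over-representation analysis overlay** — for a query set \(Q\) and a
  pathway with entity set \(S\) inside a universe \(U\), the p-value is the
  hypergeometric upper tail
  \(P(X \ge |Q \cap S|)\), \(X \sim \mathrm{Hypergeom}(|U|, |S|, |Q|)\),
  adjusted across pathways by Benjamini–Hochberg. The overlay colours each
  subpathway label along a p-value gradient (grey at and above the 0.05
  threshold), draws a bar whose width is exactly the hit fraction
  `found/total` of the label width, annotates `found/total` and the FDR,
  and adds a legend bar.
- **Editable PPTX export** — a diagram becomes an *anchored shape graph*:
  every glyph, reaction centre and line bend is a shape, and every line
  segment is an OOXML connector whose endpoints reference shapes (never
  bare coordinates). Invisible anchor shapes join the segments of one
  reaction line and catalysis/inhibition endings are grouped with their
  final segment, so moving a glyph in a presentation editor drags the
  whole reaction line along. `verify_export()` re-opens a file and checks
  the contract structurally.
- **Synthetic fixtures + CLI** — seeded generators for every input format,
  and a command line (`inst/cli/pathcanvas`) with `synth`, `render`,
  `highlight`, `overlay`, `export-pptx` and `verify` subcommands.

## Worked example

```r
library(pathcanvas)

doc <- generate_diagram(fixture_spec(seed = 7))
doc
#> <diagram_document v1>
#> <pathway_diagram 'PW-FIXTURE': 12 nodes, 6 reactions, 1 compartments, canvas (0, 0, 1000, 700)>
#>   + 3 subpathway group(s)

boxes <- highlight_diagram(doc$diagram, doc$subpathways)
boxes[[1]]
#> <highlight_box 'SP1' (36.8422, 317.292, 353.912, 349.153) fill=#E6194B55 label@(40.8422, 360.292, 345.912, 302.153) 24pt>
```

The box `(x, y, w, h)` is the padded bounding rectangle of subpathway
SP1's reactions; its label was placed at 24 pt inside the largest empty
rectangle left by the other boxes. Render it:

```r
svg <- render_svg(doc$diagram, highlights = boxes, zoom = 0.4)
```

Over-representation analysis against a fixture with a planted enriched
pathway:

```r
fx  <- generate_analysis_fixture(fixture_spec(seed = 7))
res <- ora(fx$query, fx$sets)
head(res[order(res$p_value), ], 3)
#>  pathway_id found total      p_value          fdr
#>         EH8    16    20 1.276787e-16 1.276787e-15
#>         EH6     4    20 1.222418e-01 6.112088e-01
#>         EH2     3    20 3.213230e-01 8.033076e-01
```

EH8 is the planted pathway: 16 of its 20 entities occur among the 20
query identifiers, giving a hypergeometric tail p of about 1.3e-16; the
other pathways only overlap by chance. Overlay the result on an EHLD and
export:

```r
ehld <- parse_ehld(generate_ehld(fixture_spec(seed = 7)))
apply_overlay(ehld, res)
writeLines(export_svg(ehld), "ehld-overlay.svg")
```

Editable presentation export:

```r
graph <- export_pptx(doc$diagram, "diagram.pptx")
graph
#> <anchored_shape_graph: 24 shapes (anchor=4, decoration=2, node=12, reaction_centre=6), 32 connectors, 2 groups>
verify_export("diagram.pptx")$ok
#> [1] TRUE
```

32 connectors — one per polyline segment across all six reactions — each
attached by reference to two of the 24 shapes; the 4 anchors are the
backbone bends and the 2 decoration groups are catalysis/inhibition line
endings. The same operations are available from a shell:

```sh
Rscript inst/cli/pathcanvas synth --seed 1 --out fixtures/
Rscript inst/cli/pathcanvas highlight --diagram fixtures/diagram.json --out h.svg
Rscript inst/cli/pathcanvas export-pptx --diagram fixtures/diagram.json --out d.pptx
Rscript inst/cli/pathcanvas verify --pptx d.pptx
```

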