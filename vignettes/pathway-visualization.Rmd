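---
title: "Methods: pathway diagram highlighting, analysis overlays and editable export"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway diagram highlighting, analysis overlays and editable export}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcanvas)
```

`pathcanvas` implements the visual layer of a hierarchically organised
pathway knowledge base: classic lower-level diagrams drawn in an
SBGN-style process notation, textbook-style higher-level illustrations
(EHLDs) made interactive through technical annotations, subpathway
highlight boxes with automatic label placement, over-representation
overlays, and export to an editable presentation format. This vignette
documents the models, the algorithms, the tunable parameters and the
design decisions, in that order of importance.

## The diagram model

A diagram is pure given geometry — the package never computes layout.
Coordinates are abstract canvas units with the origin top-left and y
growing downward (the SVG convention; 1 unit renders as 1 CSS pixel at
zoom 1). Rectangles are stored `(x, y, w, h)` with closed edges for
containment tests, the simplest convention for hit-testing.

Nodes carry one of seven schema classes (`protein`, `chemical`,
`complex`, `entity_set`, `gene`, `rna`, `process_node`) — a deliberately
minimal subset of SBGN process-description glyph classes, sufficient to
draw and export the diagrams this toolkit targets; styling per class
lives in colour profiles, so extension is configuration, not code.
Reaction edges have a backbone polyline, a reaction point (the position
of the reaction node square) and role-typed connectors whose polylines
run from the participating node toward the reaction centre. Connector
endpoints must terminate within a tolerance of the backbone or the
reaction point; the tolerance defaults to 0.5 canvas units and is
configurable, since published layouts carry no stated precision.
`validate_diagram()` reports every broken invariant as data (a character
vector naming the element), not as an exception — a deliberate choice so
that file readers can report all defects at once.

## Subpathway highlight boxes

Each subpathway of a diagram is assigned a box: the bounding rectangle of
all backbone points, connector points *and participating node bounds* of
its member reactions, grown by a padding (default 8 units) and clipped to
the canvas. Including node bounds is a design decision: a box that clips
glyphs in half reads worse than one that is slightly generous. A
subpathway whose geometry degenerates to a point still yields a box of
`2 * padding` square. Box colours are drawn cyclically from the
profile's semi-transparent palette over subpathways in sorted-id order.
Determinism matters here: these boxes are meant to be precomputed once
per data release and to look identical for the release's whole lifetime,
so every step of the computation (colour assignment, candidate ordering,
serialization) is fully ordered with no randomness.

### Label placement by maximal empty rectangles

The label of a box must avoid the regions where other subpathway boxes
overlap it. The placement rule is a space-partitioning search: the
obstacles are the intersections of every other box with the target box
(clipping to the target is equivalent to subtracting full boxes for
placement purposes, and keeps the search local); the candidates are all
*maximal empty rectangles* — axis-aligned rectangles inside the target
whose interiors meet no obstacle interior and that are not contained in
any larger such rectangle.

`maximal_empty_rectangles()` sweeps every pair of horizontal cut lines
drawn from obstacle and container edges, computes the maximal free
x-intervals of each band, and discards candidates contained in another
candidate. A maximal empty rectangle necessarily has each edge pinned
against an obstacle or the container boundary, so the cut-line sweep is
complete. The test suite cross-checks the sweep against an exhaustive
enumeration over the coordinate-compressed grid on random instances.

"Largest and widest" is made precise as an ordering: primary key area,
secondary key width, ties broken topmost then leftmost. The ordering is a
design decision (any total order would do); it is documented and tested
so the precomputed artefact is stable.

Text fitting uses a fixed approximate font model: every character
advances 0.6 × font size, a line occupies 1.2 × font size, and text wraps
greedily at word boundaries. Real renderer metrics vary per machine and
font; a fixed metric keeps placement deterministic and
device-independent, at the cost of slightly conservative boxes. The
chosen candidate is shrunk by an inner margin (4 units), and font sizes
are tried in whole points descending from 24 pt; if nothing fits at
8 pt or larger the label is omitted rather than rendered illegibly. All
four numbers are configurable defaults.

Highlight boxes fade as the user zooms in: opacity 1 up to zoom 0.6,
linearly down to 0 at zoom 1.0 (`fade_alpha()`). The production
thresholds of the viewer this emulates are unpublished; the defaults were
chosen so that boxes are prominent in overview renderings and gone at
full molecular detail, and both ends are parameters. For the same reason
the rendering threshold below which entity text is omitted defaults to
zoom 0.5; only entity text is omitted, not edge decorations.

## Interactive EHLDs

An EHLD is an SVG document in which three technical annotations per
subpathway — clickable region, label element, overlay slot — are encoded
in element ids (`REGION-`/`TEXT-`/`OVERLAY-` + stable id). The production
convention for these annotations is not published beyond the fact that a
database id attribute is used, so the prefixes here are a documented
reconstruction and are configurable (`ehld_config()`). Everything without
an annotation is a decoration, and decorations are never touched: the
test suite asserts byte-identical decoration subtrees across all
operations.

Hit-testing is exact for `rect`, `circle`, `ellipse` and `polygon`
elements and falls back to the coordinate bounding box for `path`
elements — full Bézier containment would buy little for click targets
that are, in practice, drawn as simple shapes. The topmost (last in
document order) containing region wins. Interaction states
(highlight/selection/flagging) are rendered by *adding* a state element
rather than editing the artwork, which makes state changes exactly
reversible and keeps exported files self-contained (explicit attributes,
no CSS classes).

## Over-representation overlay

For query \(Q\), pathway set \(S\) and universe \(U\), the p-value is the
hypergeometric upper tail \(P(X \ge |Q \cap S|)\) with population
\(|U|\), \(|S|\) successes and \(|Q \cap U|\) draws, computed via
`stats::phyper` (exact and numerically stable); the Benjamini–Hochberg
step-up (`stats::p.adjust`) adjusts across the tested pathways. Both are
cross-checked in the tests against independent oracles: direct
combinatorial summation with `choose()`, and the step-up definition by
enumeration. Query identifiers outside the universe are dropped with a
reported count; entity identifiers are opaque strings — mapping between
identifier namespaces is upstream of this package.

The overlay encodes, per subpathway label: hit fraction as a bar whose
width is exactly `found/total` of the label width; significance as a
colour interpolated linearly in RGB between the profile's gradient
endpoints, parameterized by `p / threshold`; and grey for
`p >= threshold` (default 0.05). The gradient is keyed to the p-value
(not the FDR), and the legend bar marks each displayed p-value on the
gradient, with non-significant entries ticked in the grey block. The
FDR is displayed textually next to the label as `found/total
FDR = x.xxE±ee` — a display convention of this package. All overlay
elements live in one SVG group, which makes re-application idempotent
and overlay stripping exact.

## Editable presentation export

The exchange formats above carry no interconnection information: lines
are bare polylines. For an export that survives editing, the diagram is
first converted to an *anchored shape graph*: every glyph, reaction
centre and bend becomes a shape, and every polyline segment becomes a
connector whose two endpoints reference shapes. The resolution rule for
polyline points: a point within the attachment tolerance of the reaction
point attaches to the reaction-centre shape; an endpoint inside a node's
bounds attaches to that node's shape; anything else gets an invisible
anchor shape (2 × 2 units, no fill, no line — invisible in a rendered
slide yet still selectable in editors). A polyline with k interior bends
therefore contributes k anchors and k + 1 chained connectors, and the
total connector count equals the total segment count — an invariant the
tests check exactly.

Connectors are serialized as OOXML `cxnSp` elements with `stCxn`/`endCxn`
references, straight lines between consecutive anchors (the source
polylines already encode all bends, so straight segments preserve the
published layout exactly). The connection site on a shape is the nearest
of its four side-midpoint sites to the opposite endpoint. Output arrows
are connector tail ends; catalysis/activation circles and inhibition bars
are small decoration shapes grouped with their final connector segment,
so the ending travels with the line. One canvas unit maps to 9525 EMU
(96 units per inch). The OOXML package is written directly — content
types, relationships, a minimal slide master/layout/theme and one slide —
and the archive container is written with stored (uncompressed) entries
and fixed timestamps, which makes exports byte-reproducible.

`verify_export()` closes the loop: it re-opens the package with no help
from the writer's in-memory state and counts dangling connector
references, connectors lacking either reference, shapes outside the
slide, missing parts and unresolved relationships. The closed-loop
contract (all zeros for every written file) is the testable form of
"moved glyphs drag their lines along".

## Synthetic fixtures

All tests and the acceptance script run on generated inputs. The
generators are pure functions of a `fixture_spec()` (seeded; the caller's
RNG state is saved and restored). The diagram generator places nodes on a
jittered grid (refusing overcrowded specs), connects nearest neighbours
with 0–2 bend backbones through the reaction point, adds catalyst or
inhibitor connectors at a fixed rate, and partitions reactions into
spatially contiguous subpathway clusters. The analysis generator plants
one enriched pathway: with the defaults (universe 200, sets of 20, query
of 20, hit fraction 0.8) the planted pathway receives 16 of the 20 query
identifiers and the remaining 4 are uniform background — a strong but not
degenerate signal, chosen so that recovery is expected in the vast
majority of replicates but not guaranteed. What the fixtures deliberately
do not emulate: biologically realistic topology, glyph artwork, shared
entities between pathway sets' annotation biases, or curator-drawn EHLD
geometry. Green tests therefore demonstrate the geometric and statistical
contracts, not fidelity to any curated data release.

Problem sizes used by the default suite and acceptance script — diagrams
up to 50 reactions and 1000 nodes, 100 random rectangle instances with
coordinates up to 20 and up to 6 obstacles, 50 analysis replicates with a
universe of 200 — were chosen to exercise every code path at sizes where
the brute-force oracles remain exact and fast.

## Known limitations

- Path-element hit testing is bounding-box only; curved clickable regions
  are approximated.
- The font model is approximate: a renderer with wider metrics than
  0.6 em per character may overflow a tightly fitted label.
- PPTX export is single-slide with inline styling; slide-master theming
  of colour profiles is not attempted.
- Highlight boxes are bounding boxes and are never re-laid-out to reduce
  overlap; heavily interleaved subpathways can leave no room for a label,
  in which case the label is omitted by design.
- SVG/PDF-style flat exports of classic diagrams intentionally remain
  non-interconnected; the anchored representation exists only in the
  PPTX path.
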