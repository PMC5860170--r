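# EHLD annotation format

An enhanced high-level diagram (EHLD) is an ordinary SVG 1.1 document — a
textbook-style illustration of a higher-level pathway — made interactive
through three kinds of technical annotations carried in element ids. The
join key is the subpathway's stable identifier:

| annotation            | default id pattern    | meaning                                   |
|-----------------------|-----------------------|-------------------------------------------|
| clickable region      | `REGION-<stableId>`   | the area that navigates to the subpathway |
| label                 | `TEXT-<stableId>`     | the text element holding its name         |
| analysis overlay slot | `OVERLAY-<stableId>`  | the element covered by analysis results   |

Any element without one of these annotations is a **decoration**: it is
never modified, restyled or removed by any operation. The id prefixes are
configurable (`ehld_config()`) to accommodate other annotation dialects.

Requirements and behaviour:

- The SVG root must carry a `viewBox`; it defines the canvas for
  hit-testing.
- A stable id may annotate at most one region element; duplicates are
  rejected. A region whose label or overlay element is missing yields a
  partial active region and a warning.
- Hit-testing uses exact containment for `rect`, `circle`, `ellipse` and
  `polygon` region elements, group elements test their children, and
  `path` elements fall back to the bounding box of their coordinate data.
  The topmost region (last in document order) wins.
- Interaction states are rendered as an extra element with id
  `STATE-<stableId>` (explicit attributes, no CSS), so returning a region
  to its normal state restores the document exactly.
- Analysis overlays live in a single group with id
  `analysis-result-overlay`; exporting with the overlay stripped removes
  only this group.
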