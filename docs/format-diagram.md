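# Diagram JSON exchange format (schema version 1)

A diagram file describes one classic lower-level pathway diagram: glyph
nodes, segmented reaction edges with role-typed connectors, compartments,
and (optionally) the assignment of reactions to subpathways. Positions are
always given; the toolkit never computes layout.

Coordinate convention: origin at the top-left corner, y grows downward,
abstract "canvas units" (1 unit = 1 CSS pixel at zoom 1). Rectangles are
`{x, y, w, h}` with `w > 0`, `h > 0`; rectangle edges are closed intervals
for containment tests.

Top-level keys:

| key             | type   | meaning                                        |
|-----------------|--------|------------------------------------------------|
| `schemaVersion` | int    | must be `1`                                    |
| `pathwayId`     | string | stable identifier of the depicted pathway      |
| `canvas`        | rect   | canvas bounds; contains all geometry           |
| `nodes`         | array  | glyph nodes (below)                            |
| `edges`         | array  | reaction edges (below)                         |
| `compartments`  | array  | compartments (below)                           |
| `subpathways`   | object | optional subpathway assignment (below)         |

Unknown top-level keys are preserved on read and written back unchanged.

**Node**: `{id, schemaClass, displayName, bounds, compartmentId?}`.
`schemaClass` is one of `protein, chemical, complex, entity_set, gene, rna,
process_node` (a minimal subset of SBGN process-description glyph classes).
Node ids are unique and `bounds` lies within the canvas.

**Edge**: `{id, reactionPoint: {x, y}, segments: [{x, y}, ...],
connectors: [...]}`. `segments` is the backbone polyline (at least two
points). Each connector is `{role, nodeId, points, ending}` with `role` in
`input | output | catalyst | activator | inhibitor` and `ending` in
`none | arrow | circle | bar`; `points` runs from the node toward the
reaction centre and must terminate within a tolerance (default 0.5 canvas
units) of the backbone or the reaction point. Ending legality: `arrow` only
on outputs, `circle` only on catalysts/activators, `bar` only on
inhibitors. Every edge has at least one input and one output connector.

**Compartment**: `{id, name, outer, inner?}`; `inner`, when present, is
strictly inside `outer` (membrane ring).

**Subpathways**: `{parentPathwayId, groups: {subpathwayId: [reactionId,
...]}, displayNames: {subpathwayId: label}}`. Every reaction id must occur
in this diagram and belongs to at most one subpathway.

Serialization is canonical — fixed key order as produced by the writer,
2-space indent — so a read/write cycle is byte-stable. A machine-readable
JSON Schema is provided in `diagram.schema.json`.

Pathway hierarchy files are a single rooted tree of
`{stableId, name, kind, children}` entries with `kind` in
`higher_level | lower_level`; lower-level entries are leaves, ids are
unique, and a child naming one of its ancestors is rejected as a cycle.
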