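{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "pathcanvas diagram exchange format, schema version 1",
  "type": "object",
  "required": ["schemaVersion", "pathwayId", "canvas", "nodes", "edges", "compartments"],
  "properties": {
    "schemaVersion": {"const": 1},
    "pathwayId": {"type": "string", "minLength": 1},
    "canvas": {"$ref": "#/definitions/rect"},
    "nodes": {"type": "array", "items": {"$ref": "#/definitions/node"}},
    "edges": {"type": "array", "items": {"$ref": "#/definitions/edge"}},
    "compartments": {"type": "array", "items": {"$ref": "#/definitions/compartment"}},
    "subpathways": {"$ref": "#/definitions/subpathways"}
  },
  "definitions": {
    "rect": {
      "type": "object",
      "required": ["x", "y", "w", "h"],
      "properties": {
        "x": {"type": "number"},
        "y": {"type": "number"},
        "w": {"type": "number", "exclusiveMinimum": 0},
        "h": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "point": {
      "type": "object",
      "required": ["x", "y"],
      "properties": {"x": {"type": "number"}, "y": {"type": "number"}}
    },
    "node": {
      "type": "object",
      "required": ["id", "schemaClass", "displayName", "bounds"],
      "properties": {
        "id": {"type": "string", "minLength": 1},
        "schemaClass": {
          "enum": ["protein", "chemical", "complex", "entity_set", "gene", "rna", "process_node"]
        },
        "displayName": {"type": "string"},
        "bounds": {"$ref": "#/definitions/rect"},
        "compartmentId": {"type": "string"}
      }
    },
    "connector": {
      "type": "object",
      "required": ["role", "nodeId", "points", "ending"],
      "properties": {
        "role": {"enum": ["input", "output", "catalyst", "activator", "inhibitor"]},
        "nodeId": {"type": "string"},
        "points": {"type": "array", "minItems": 1, "items": {"$ref": "#/definitions/point"}},
        "ending": {"enum": ["none", "arrow", "circle", "bar"]}
      }
    },
    "edge": {
      "type": "object",
      "required": ["id", "reactionPoint", "segments", "connectors"],
      "properties": {
        "id": {"type": "string", "minLength": 1},
        "reactionPoint": {"$ref": "#/definitions/point"},
        "segments": {"type": "array", "minItems": 2, "items": {"$ref": "#/definitions/point"}},
        "connectors": {"type": "array", "minItems": 2, "items": {"$ref": "#/definitions/connector"}}
      }
    },
    "compartment": {
      "type": "object",
      "required": ["id", "name", "outer"],
      "properties": {
        "id": {"type": "string", "minLength": 1},
        "name": {"type": "string"},
        "outer": {"$ref": "#/definitions/rect"},
        "inner": {"$ref": "#/definitions/rect"}
      }
    },
    "subpathways": {
      "type": "object",
      "required": ["parentPathwayId", "groups"],
      "properties": {
        "parentPathwayId": {"type": "string"},
        "groups": {
          "type": "object",
          "additionalProperties": {
            "type": "array", "minItems": 1, "items": {"type": "string"}
          }
        },
        "displayNames": {
          "type": "object",
          "additionalProperties": {"type": "string"}
        }
      }
    }
  }
}
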