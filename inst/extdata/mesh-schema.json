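{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "rootsim cell-complex mesh",
  "description": "Segmented 2D cellular mesh: typed cell polygons over shared vertices, with per-wall apoplast state and per-side membrane carrier amounts. Lengths in micrometres, concentrations in nM.",
  "type": "object",
  "required": ["version", "vertices", "cells"],
  "properties": {
    "version": {"type": "integer"},
    "vertices": {
      "type": "array",
      "items": {"type": "array", "items": {"type": "number"}, "minItems": 2, "maxItems": 2}
    },
    "pinned": {
      "description": "1-based indices of immobile vertices (organ attachment)",
      "type": "array",
      "items": {"type": "integer"}
    },
    "cells": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "type", "vertex_ring"],
        "properties": {
          "id": {"type": "integer"},
          "type": {
            "enum": ["QC", "ColumellaInitial", "Columella", "EpidermisLRCInitial",
                     "CEI", "CEID", "LRC", "Epidermis", "Endodermis", "Cortex",
                     "Pericycle", "Vascular", "VascularInitial", "Source", "Sink"]
          },
          "vertex_ring": {
            "description": "counter-clockwise 1-based vertex indices of the cell polygon",
            "type": "array", "items": {"type": "integer"}, "minItems": 3
          },
          "state": {
            "type": "object",
            "properties": {
              "IAA": {"type": "number"}, "PIN": {"type": "number"},
              "AUX1": {"type": "number"}, "REG": {"type": "number"},
              "POL": {"type": "number"},
              "af": {"type": "array", "items": {"type": "number"}},
              "A_max": {"type": "number"}, "parity": {"type": "integer"},
              "row": {"type": ["integer", "null"]}
            }
          }
        }
      }
    },
    "walls": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["vertices"],
        "properties": {
          "id": {"type": "integer"},
          "vertices": {"type": "array", "items": {"type": "integer"}, "minItems": 2, "maxItems": 2},
          "cells": {
            "description": "ids of the 1 or 2 adjoining cells",
            "type": "array", "items": {"type": "integer"}, "minItems": 1, "maxItems": 2
          },
          "IAA": {"type": "number"},
          "rest_length": {"type": "number"},
          "sides": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["cell"],
              "properties": {
                "cell": {"type": "integer"},
                "PIN": {"type": "number"}, "AUX1": {"type": "number"},
                "REG": {"type": "number"}, "POL": {"type": "number"}
              }
            }
          }
        }
      }
    }
  }
}
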