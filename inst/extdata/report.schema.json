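{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ragmm combined report",
  "type": "object",
  "required": ["sample_id", "kb_version", "rag", "adverse_count", "ultrahigh"],
  "properties": {
    "sample_id": {"type": "string", "minLength": 1},
    "kb_version": {"type": "string", "minLength": 1},
    "rag": {
      "type": "object",
      "required": ["band", "matches", "unmatched", "filtered"],
      "properties": {
        "score": {"type": ["number", "null"], "minimum": 1.0, "maximum": 3.0},
        "band": {"enum": ["low", "low_intermediate", "high_intermediate", "high", "unscorable"]},
        "matches": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["category", "group", "weight", "supporting"],
            "properties": {
              "category": {"type": "string"},
              "group": {"enum": ["red", "amber", "green"]},
              "weight": {"enum": [3, 2, 1]},
              "supporting": {"type": "array", "minItems": 1, "items": {"$ref": "#/definitions/aberration"}}
            }
          }
        },
        "unmatched": {"type": "array", "items": {"$ref": "#/definitions/aberration"}},
        "filtered": {"type": "array", "items": {"$ref": "#/definitions/aberration"}}
      }
    },
    "iss": {
      "type": ["object", "null"],
      "required": ["stage"],
      "properties": {
        "stage": {"enum": ["I", "II", "III"]},
        "beta2m": {"type": "number", "minimum": 0},
        "albumin": {"type": "number", "minimum": 0}
      }
    },
    "adverse_count": {"type": "integer", "minimum": 0},
    "ultrahigh": {"type": "boolean"}
  },
  "definitions": {
    "aberration": {
      "type": "object",
      "required": ["kind", "method"],
      "properties": {
        "kind": {"enum": ["translocation", "trisomy", "deletion", "gain", "mutation"]},
        "descriptor": {"type": "string"},
        "gene": {"type": "string"},
        "method": {"enum": ["FISH", "karyotype", "GEP", "sequencing"]},
        "consequence": {"enum": ["nonsynonymous", "synonymous", "other"]}
      }
    }
  }
}
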