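{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Coverage report",
  "description": "Schema of the YAML coverage report (after YAML-to-JSON conversion): per-use-case rows with nested concept-group rows, plus an overall row. Percentages are integer percents of the row's concept count under half-up rounding.",
  "type": "object",
  "required": ["overall", "use_cases"],
  "additionalProperties": false,
  "properties": {
    "overall": { "$ref": "#/$defs/row" },
    "use_cases": {
      "type": "object",
      "additionalProperties": { "$ref": "#/$defs/use_case_row" }
    }
  },
  "$defs": {
    "row": {
      "type": "object",
      "required": ["concepts", "label", "mapped", "mapped_pct",
                   "structured", "structured_pct"],
      "additionalProperties": false,
      "properties": {
        "concepts": { "type": "integer", "minimum": 0 },
        "label": { "type": "string" },
        "mapped": { "type": "integer", "minimum": 0 },
        "mapped_pct": { "type": "integer", "minimum": 0, "maximum": 100 },
        "structured": { "type": "integer", "minimum": 0 },
        "structured_pct": { "type": "integer", "minimum": 0, "maximum": 100 }
      }
    },
    "use_case_row": {
      "type": "object",
      "required": ["concepts", "groups", "label", "mapped", "mapped_pct",
                   "structured", "structured_pct"],
      "additionalProperties": false,
      "properties": {
        "concepts": { "type": "integer", "minimum": 0 },
        "groups": { "type": "array", "items": { "$ref": "#/$defs/row" } },
        "label": { "type": "string" },
        "mapped": { "type": "integer", "minimum": 0 },
        "mapped_pct": { "type": "integer", "minimum": 0, "maximum": 100 },
        "structured": { "type": "integer", "minimum": 0 },
        "structured_pct": { "type": "integer", "minimum": 0, "maximum": 100 }
      }
    }
  }
}
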