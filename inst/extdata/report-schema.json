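{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "runcoord coordination report",
  "type": "object",
  "required": ["label", "n_cycles", "K_EMG_pct", "stability", "software"],
  "properties": {
    "label": {"type": "string"},
    "speed_kmh": {"type": ["number", "null"]},
    "n_cycles": {"type": "integer", "minimum": 2},
    "K_EMG_pct": {"type": "number", "minimum": 0, "maximum": 100},
    "alpha_pct": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
    "symmetry": {
      "type": ["object", "null"],
      "required": ["per_muscle", "alpha_pct"],
      "properties": {
        "per_muscle": {
          "type": "object",
          "additionalProperties": {"type": "number", "minimum": 0, "maximum": 100}
        },
        "alpha_pct": {"type": "number", "minimum": 0, "maximum": 100}
      }
    },
    "stability": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["side", "K_EMG_pct", "n_cycles", "M", "F"],
        "properties": {
          "side": {"enum": ["left", "right"]},
          "K_EMG_pct": {"type": "number", "minimum": 0, "maximum": 100},
          "n_cycles": {"type": "integer"},
          "M": {"type": "integer"},
          "F": {"type": "integer"},
          "n_excluded": {"type": "integer"},
          "per_phase": {"type": "array"}
        }
      }
    },
    "config": {"type": ["object", "null"]},
    "seed": {"type": ["integer", "null"]},
    "software": {"type": "string"}
  }
}
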