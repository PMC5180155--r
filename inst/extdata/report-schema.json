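{
  "type": "object",
  "required": ["provenance", "coding"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "version", "seed", "timestamp"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "seed": {"type": "integer"},
        "timestamp": {"type": "string"}
      }
    },
    "coding": {
      "type": "object",
      "required": ["status"],
      "properties": {
        "status": {"type": "string"},
        "attrition": {
          "type": "object",
          "required": ["input", "retained"],
          "properties": {
            "input": {"type": "integer"},
            "not_on_tree": {"type": "integer"},
            "defence_unknown": {"type": "integer"},
            "iucn_not_codable": {"type": "integer"},
            "retained": {"type": "integer"}
          }
        }
      }
    },
    "regression": {
      "type": "object",
      "required": ["status"],
      "properties": {"status": {"type": "string"}}
    },
    "confounds": {
      "type": "object",
      "required": ["status"],
      "properties": {"status": {"type": "string"}}
    },
    "ordinal": {
      "type": "object",
      "required": ["status"],
      "properties": {
        "status": {"type": "string"},
        "beta_mean": {"type": "number"},
        "ci_lower": {"type": "number"},
        "ci_upper": {"type": "number"},
        "p_mcmc": {"type": "number"}
      }
    },
    "tipages": {
      "type": "object",
      "required": ["status"],
      "properties": {
        "status": {"type": "string"},
        "young_tip_excess": {"type": "number"},
        "permutation_p": {"type": "number"}
      }
    },
    "pathway": {
      "type": "object",
      "required": ["status"],
      "properties": {"status": {"type": "string"}}
    },
    "fates": {
      "type": "object",
      "required": ["status"],
      "properties": {"status": {"type": "string"}}
    }
  }
}
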