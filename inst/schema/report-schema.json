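{
  "type": "object",
  "required": ["provenance", "population", "classification", "ploidy",
               "fitness", "associationScan"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["configHash", "seed", "package", "version"],
      "properties": {
        "configHash": {"type": "string"},
        "seed": {"type": "number"},
        "package": {"type": "string"},
        "version": {"type": "string"}
      }
    },
    "population": {
      "type": "object",
      "required": ["n", "meanEvents", "totalEvents", "pctCircular",
                   "pctLinear", "typeFractions"],
      "properties": {
        "n": {"type": "number"},
        "meanEvents": {"type": "number"},
        "totalEvents": {"type": "number"},
        "pctCircular": {"type": "number"},
        "pctLinear": {"type": "number"}
      }
    },
    "classification": {
      "type": "object",
      "required": ["typeFractions", "meanEvents", "circularFraction"],
      "properties": {
        "meanEvents": {"type": "number"},
        "circularFraction": {"type": "number"},
        "typeFractions": {
          "type": "object",
          "required": ["deletion", "inversion", "duplication"],
          "properties": {
            "deletion": {"type": "number"},
            "inversion": {"type": "number"},
            "duplication": {"type": "number"}
          }
        }
      }
    },
    "ploidy": {
      "type": "object",
      "required": ["nFlagged"],
      "properties": {"nFlagged": {"type": "number"}}
    },
    "fitness": {
      "type": "object",
      "required": ["r", "slope", "intercept"],
      "properties": {
        "r": {"type": "number"},
        "slope": {"type": "number"},
        "intercept": {"type": "number"}
      }
    },
    "associationScan": {
      "type": "object",
      "required": ["nTested", "topSegment", "topP"],
      "properties": {
        "nTested": {"type": "number"},
        "topSegment": {"type": "string"},
        "topP": {"type": "number"}
      }
    }
  }
}
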