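{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "purgekit pipeline report",
  "type": "object",
  "required": ["seed", "filters", "roh", "diversity", "load"],
  "properties": {
    "seed": {"type": "integer"},
    "filters": {
      "type": "object",
      "required": ["n_input", "n_retained"]
    },
    "roh": {
      "type": "object",
      "required": ["samples", "populations"]
    },
    "diversity": {
      "type": "object",
      "required": ["pi", "heterozygosity"]
    },
    "load": {
      "type": "object",
      "required": ["individual", "population", "hom_ratio"]
    },
    "purging": {
      "type": "object",
      "required": ["rohf", "gerp"]
    },
    "sfs": {"type": "object"}
  }
}
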