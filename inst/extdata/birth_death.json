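{
  "species": ["X"],
  "initial": {"X": 0},
  "reactions": [
    {"name": "birth", "products": {"X": 1}, "rate": 10},
    {"name": "death", "reactants": {"X": 1}, "rate": 1}
  ]
}
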