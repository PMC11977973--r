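{
  "species": ["G", "M"],
  "initial": {"G": 1, "M": 0},
  "reactions": [
    {"name": "transcription",
     "propensity": "5*G/(1 + pow(M,2)/400)",
     "delay": {"kind": "consuming", "value": 2},
     "s_delay_change": {"M": 1}},
    {"name": "decay", "reactants": {"M": 1}, "rate": 0.2},
    {"name": "delayed_decay", "reactants": {"M": 1}, "rate": 0.05,
     "delay": {"kind": "completion_only",
               "distribution": "exponential", "params": {"rate": 1}}}
  ]
}
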