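[
  {"t_start": 0,    "left": "air",      "right": "nitrogen"},
  {"t_start": 1800, "left": "nitrogen", "right": "air"}
]
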