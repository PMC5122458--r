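{
  "chamber_width": 1000,
  "gas_width": 1000,
  "gas_gap": 500,
  "margin": 500,
  "slab_height": 575,
  "channel_thickness": 115,
  "dy": 25,
  "dz": 23
}
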