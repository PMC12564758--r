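{
  "pools": ["upstream", "downstream"],
  "u": [1, 0],
  "B": [
    [-1, 0],
    [1, -1]
  ],
  "time_unit": "yr",
  "mass_unit": "gC"
}
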