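{
  "v8":      {"p1_fast": ["E"], "p1_slow": ["D"], "p1prime_block": ["P"], "p1prime_slow": ["E", "D"]},
  "trypsin": {"p1_fast": ["K", "R"], "p1prime_block": ["P"]},
  "elastase": {"p1_fast": ["A", "V", "S", "G", "L", "I"]},
  "thermolysin": {"p1prime_target": ["I", "L", "V", "F", "M", "A"]}
}
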