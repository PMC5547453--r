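{
  "chrom": [20],
  "pos": [17330, 14370],
  "ref": ["T", "G"],
  "alt": ["A"]
}
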