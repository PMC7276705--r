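{
  "cds_start": 101,
  "cds_end": 1441,
  "note": "synthetic LamB-like amplicon: 1341 bp CDS with 100 bp flanks, generated by synthetic_reference(seed = 20)"
}
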