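{
  "sim": {
    "m_snps": 4000,
    "ld_block_size": 40,
    "n_ref": 400,
    "h2_1": 0.092,
    "h2_2": 0.22,
    "rg": 0.44,
    "n_overlap": 0
  },
  "n_blocks": 100,
  "vse": {
    "n_loci": 10,
    "n_perm": 1000,
    "coverage_background": 0.1,
    "planted": true
  },
  "smr": {
    "n_probes_tested": 2000,
    "scenario": "pleiotropy"
  }
}
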