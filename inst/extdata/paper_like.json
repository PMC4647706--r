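{
  "name": "paper_like",
  "n_samples": 74,
  "n_loci": 239,
  "K": 2,
  "fst": 0.03,
  "admixed_fraction": 0.2,
  "admix_alpha": [0.5, 0.5],
  "missing_rate": 0.05
}
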