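{
  "seed": 42,
  "karyon": {"n_permutations": 199},
  "simulation": {
    "total_len_bp": 50000,
    "n_contigs": 2,
    "repeat_fraction": 0.2,
    "coding_fraction": 0.2,
    "n_nuclei": 2,
    "mode": "heterokaryon",
    "divergence_per_kb": 1.0,
    "class_ratio": 0.5,
    "private_mut_per_kb": 0.05,
    "obs": {"mean_depth": 20}
  }
}
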