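{
  "config": {
    "n_samples": 60,
    "n_genes": 40,
    "planted": [
      {
        "mode": "deep_amp",
        "beta": 1.5,
        "carrier_frac": 0.15
      },
      {
        "mode": "deep_amp",
        "beta": 1.5,
        "carrier_frac": 0.15
      },
      {
        "mode": "deep_amp",
        "beta": 1.5,
        "carrier_frac": 0.15
      }
    ],
    "bg_shape1": 2,
    "bg_shape2": 40,
    "deep_frac": 0.3,
    "baseline_rate": 0.000633011123799037,
    "censor_rate": 0.0005,
    "horizon": 3650,
    "seed": 404
  },
  "files": {
    "all_thresholded_by_genes.txt": "c4b3c70a631d914fd8142b8aac7cc190",
    "clinical.tsv": "b1867e7507ee73d0fb6b7371d1e0cfd1",
    "truth_genes.tsv": "372002c2dd594f695a8cc43b04b00728"
  }
}
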