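{
  "experiment": "initial_sweep",
  "params": { "n1": 50, "n2": 50, "l1": 250, "l2": 250, "l12": 100 },
  "x0_grid": [0, 0.25, 0.5, 0.75, 1],
  "replicates": 5,
  "horizon": 200000,
  "seed": 1
}
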