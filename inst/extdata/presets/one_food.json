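{
  "type": "scenario",
  "M": 50, "N": 50, "n": 500,
  "x0": [25, 25],
  "food_sources": [[40, 25]],
  "D": 10, "gamma": 0.001, "A_dep": 1, "sigma_decay": 1,
  "epsilon": 0.001, "dt": 0.001, "dx": 1,
  "T_max": 300, "seed": 1
}
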