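{
  "subcommand": "frobnicate",
  "branch": "branch",
  "scenario": "herbivore-ancestor",
  "genes": 30,
  "alpha": 0.05,
  "bonferroni_n": 2,
  "seed": 1,
  "out": "phylotroph-out",
  "timestamp": "2026-10-01T22:52:21+0000"
}
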