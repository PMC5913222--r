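# End-to-end demonstration: simulate a two-group qPCR experiment whose
# target is mildly downregulated while one normalizer responds to
# treatment more strongly, then ask whether the target's direction call
# survives a change of reference gene.
seed: 42
stages:
  - stage: simulate_qpcr
    n_per_group: 13
  - stage: sensitivity
    target: Bcl2
    references: [Actb, Mapk6, Ankrd11]
  - stage: stability
    n_samples: 80
  - stage: evidence
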