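# example pipeline configuration; unset keys fall back to package defaults
alpha: 0.05
nPermutations: 100
groupFraction: 0.10
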