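structure: island
n_subpops: 8
deme_size: 500
migration_rate: 0.001
selection: stabilizing
omega: 22
fst_target: 0.15
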