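structure: hierarchical_139
n_subpops: 9
deme_size: 900
migration_rate: 0
selection: neutral
fst_target: 0.2
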