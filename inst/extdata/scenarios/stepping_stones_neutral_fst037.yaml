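structure: stepping_stones_1d
n_subpops: 20
deme_size: 1000
migration_rate: 0.001
selection: neutral
fst_target: 0.37
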