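# Synthetic input bundle plus pipeline config for one wild-type-like
# protein; thin alias over the exported generator (returns the config path).

write_sis1_bundle <- function(dir, seed = 1)
  simulate_protein_bundle(dir, seed = seed)
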