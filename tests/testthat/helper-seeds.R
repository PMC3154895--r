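# fixed offset so test seeds do not collide with simulation seeds
derive_seed_for_tests <- function(s) 1000L + s
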