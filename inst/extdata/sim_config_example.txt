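# example simulator configuration (key: value)
mode: chemotaxis
bias: 0.7
n_worms: 150
duration: 3600
seed: 7
n_arenas_per_orientation: 4
n_dispersal: 4
odorant: butanone 10%
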