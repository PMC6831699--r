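# mixed regime: SD converges to the balance point of typicality and novelty
model = sce
init_mu = 0.02
init_sigma = 0.01
beta_T = 0.2
beta_N = 1
generations = 80
start_year = 1500
years_per_generation = 25
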