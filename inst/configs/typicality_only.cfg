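# typicality-only regime: mean and SD both shrink, mean -> mode
model = sce
init_mu = 0.2
init_sigma = 0.1
beta_T = 0.5
beta_N = 0
generations = 100
start_year = 1500
years_per_generation = 25
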