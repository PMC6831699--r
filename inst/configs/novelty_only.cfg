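# novelty-only regime: slow manifold with sigma/mu slightly below 1,
# near-exponential growth of the mean toward 1/2
model = sce
init_mu = 0.02
init_sigma = 0.01
beta_T = 0
beta_N = 1
generations = 60
start_year = 1500
years_per_generation = 25
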