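# Operating-characteristics run for the linear-gradient scenario:
# one-stage design, 10 patients per subgroup, two-subset pipeline with a
# Bayes-factor threshold of 100.
seed: 20260929
scenario: scenario8
method: ibis
sigma: 1
n_per_subgroup: 10
n_sim: 200
theta0: 0
prior_odds: 1
bf_effective: 100
bf_promising: 10
mcmc:
  n_iterations: 2500
  n_burnin: 500
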