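# Default configuration: Gemcitabine (drug A) + Cyclophosphamide (drug B)
# combination study. Doses standardized to each agent's single-agent MTD.
grid:
  drug_a: [0.2, 0.5, 0.7, 0.8, 0.9, 0.95]
  drug_b: [0.2, 0.5, 0.7, 0.8, 0.9, 0.95]

# Elicited prior means and variances; all priors are gamma, moment-matched.
priors:
  six_param:
    alpha1: {mean: 0.43, variance: 0.11}
    beta1:  {mean: 7.65, variance: 5.71}
    alpha2: {mean: 0.43, variance: 0.08}
    beta2:  {mean: 7.80, variance: 3.99}
    alpha3: {mean: 1.00, variance: 0.90}
    beta3:  {mean: 1.00, variance: 0.90}
  copula:
    delta: {mean: 1.0, variance: 0.5}
    psi:   {mean: 1.0, variance: 0.5}
    gamma: {mean: 1.0, variance: 0.5}

trial:
  ttl: 0.30
  epsilon: 0.025
  cohort_size: 2
  n_cohorts: 20
  start: [1, 1]
  model: six_param     # six_param | copula
  rule: d1             # d1 | d2
  omega: omega1        # omega1 | omega2 | omega3

posterior:
  n_draws: 5000        # importance sample size per update
  n_info_draws: 128    # equally-weighted draws for the D-optimality average
  min_ess: 50
  skeleton_draws: 100000
  skeleton_seed: 1
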