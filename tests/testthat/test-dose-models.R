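test_that("six-parameter model matches hand-evaluated cases", {
  ones <- stats::setNames(rep(1, 6),
                          c("alpha1", "beta1", "alpha2", "beta2",
                            "alpha3", "beta3"))
  # all terms vanish with both drugs absent
  expect_identical(six_param_prob(0, 0, ones), 0)
  # a = b = 0.5, interaction = (0.5 * 0.5)^1 = 0.25 -> 1.25 / 2.25
  expect_equal(six_param_prob(0.5, 0.5, ones), 1.25 / 2.25,
               tolerance = 1e-12)
})

test_that("six-parameter margins are the single-agent odds exactly", {
  set.seed(41)
  for (r in 1:50) {
    th <- random_six_params()
    xa <- runif(1, 0.05, 1)
    a <- th["alpha1"] * xa^th["beta1"]
    expect_equal(six_param_prob(xa, 0, th), unname(a / (1 + a)),
                 tolerance = 1e-12)
    xb <- runif(1, 0.05, 1)
    b <- th["alpha2"] * xb^th["beta2"]
    expect_equal(six_param_prob(0, xb, th), unname(b / (1 + b)),
                 tolerance = 1e-12)
  }
})

test_that("copula model matches hand-evaluated cases and margins", {
  ones <- c(delta = 1, psi = 1, gamma = 1)
  # unit powers, p = q = 0.2: 1 - (0.8^-1 + 0.8^-1 - 1)^-1 = 1/3
  expect_equal(copula_prob(0.2, 0.2, ones), 1 / 3, tolerance = 1e-12)
  expect_equal(copula_prob(0.37, 0, ones), 0.37, tolerance = 1e-12)
  set.seed(42)
  for (r in 1:50) {
    th <- random_copula_params()
    p <- runif(1, 0.01, 0.95)
    expect_equal(copula_prob(p, 0, th), unname(p^th["delta"]),
                 tolerance = 1e-12)
    q <- runif(1, 0.01, 0.95)
    expect_equal(copula_prob(0, q, th), unname(q^th["psi"]),
                 tolerance = 1e-12)
  }
})

test_that("copula interaction vanishes in the small-gamma limit", {
  set.seed(43)
  for (r in 1:20) {
    p <- runif(1, 0.05, 0.9); q <- runif(1, 0.05, 0.9)
    de <- rlnorm(1, 0, 0.4); ps <- rlnorm(1, 0, 0.4)
    got <- copula_prob(p, q, c(delta = de, psi = ps, gamma = 1e-6))
    indep <- 1 - (1 - p^de) * (1 - q^ps)
    expect_equal(got, indep, tolerance = 1e-4)
  }
})

test_that("both model surfaces are monotone in each dose", {
  g <- default_grid()
  set.seed(44)
  for (r in 1:25) {
    th6 <- random_six_params()
    surf <- outer(g$levels_a, g$levels_b,
                  function(xa, xb) six_param_prob(xa, xb, th6))
    expect_true(all(apply(surf, 1, diff) >= 0))
    expect_true(all(apply(surf, 2, diff) >= 0))
    th3 <- random_copula_params()
    sk <- test_skeleton()
    surf3 <- outer(seq_len(6), seq_len(6),
                   function(i, j) copula_prob(sk$p[i], sk$q[j], th3))
    expect_true(all(apply(surf3, 1, diff) >= 0))
    expect_true(all(apply(surf3, 2, diff) >= 0))
  }
})

test_that("model inputs are validated", {
  ones <- rep(1, 6)
  expect_error(six_param_prob(1.2, 0.5, ones), "doses")
  expect_error(six_param_prob(0.5, 0.5, c(-1, 1, 1, 1, 1, 1)), "positive")
  expect_error(copula_prob(1, 0.2, c(1, 1, 1)), "skeleton")
  expect_error(copula_prob(0.2, 0.2, c(1, 1, -2)), "positive")
  expect_error(skeleton(c(0.3, 0.2), c(0.1, 0.2)), "increasing")
})

test_that("binomial log likelihood accumulates over the history", {
  m <- six_param_model()
  ones <- stats::setNames(rep(1, 6), m$prior$names)
  expect_identical(log_likelihood(m, trial_history(), ones), 0)
  # pick a combo and parameters with known pi, check the sum longhand
  h1 <- trial_history(i = 3, j = 2, y = 1)
  pi1 <- six_param_prob(m$grid$levels_a[3], m$grid$levels_b[2], ones)
  expect_equal(log_likelihood(m, h1, ones), log(pi1), tolerance = 1e-12)
  h2 <- trial_history(i = c(3, 3), j = c(2, 2), y = c(1, 0))
  expect_equal(log_likelihood(m, h2, ones), log(pi1) + log(1 - pi1),
               tolerance = 1e-12)
  # the printed two-observation example: pi = 0.3, outcomes (1, 0)
  expect_equal(log(0.3) + log(0.7), -1.5606, tolerance = 1e-4)
})

test_that("analytic gradients agree with the central-difference oracle", {
  g <- default_grid()
  m6 <- six_param_model()
  m3 <- copula_model(g, test_skeleton())
  set.seed(45)
  for (r in 1:50) {
    cmb <- dose_combo(sample(6, 1), sample(6, 1), g)
    th6 <- random_six_params()
    got <- prob_gradient(m6, cmb, th6)
    want <- numeric_gradient(m6, cmb, th6)
    expect_equal(got, want, tolerance = 1e-4)
    th3 <- random_copula_params()
    got3 <- prob_gradient(m3, cmb, th3)
    want3 <- numeric_gradient(m3, cmb, th3)
    expect_equal(got3, want3, tolerance = 1e-4)
  }
  # numeric backend exposed behind the same contract
  cmb <- dose_combo(2, 5, g)
  th <- random_six_params()
  expect_equal(prob_gradient(m6, cmb, th, method = "numeric"),
               prob_gradient(m6, cmb, th), tolerance = 1e-4)
})

test_that("gradients vanish where the surface cannot move", {
  m3 <- copula_model(default_grid(), test_skeleton())
  # at the drug-A margin the copula surface depends only on delta; emulate
  # q = 0 through the public scalar function
  th <- c(delta = 1.3, psi = 0.7, gamma = 2)
  h <- 1e-6
  for (nm in c("psi", "gamma")) {
    up <- th; up[nm] <- up[nm] + h
    expect_equal(copula_prob(0.3, 0, up), copula_prob(0.3, 0, th),
                 tolerance = 1e-12)
  }
})

test_that("Fisher information is rank-one positive semidefinite", {
  g <- default_grid()
  m6 <- six_param_model()
  m3 <- copula_model(g, test_skeleton())
  set.seed(46)
  for (r in 1:25) {
    cmb <- dose_combo(sample(6, 1), sample(6, 1), g)
    for (m in list(m6, m3)) {
      th <- if (m$type == "six_param") random_six_params() else
        random_copula_params()
      info <- fisher_information(m, cmb, th)
      expect_equal(info, t(info))
      ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
      expect_true(all(ev >= -1e-12))
      expect_lte(sum(ev > 1e-12 * max(ev)), 1)
      # trace identity |g|^2 / (pi (1 - pi))
      gr <- prob_gradient(m, cmb, th)
      xd <- combo_doses(cmb, g)
      pi_x <- if (m$type == "six_param")
        six_param_prob(xd[1, 1], xd[1, 2], th)
      else copula_prob(m$skeleton$p[cmb[["i"]]], m$skeleton$q[cmb[["j"]]],
                       th)
      expect_equal(sum(diag(info)), sum(gr^2) / (pi_x * (1 - pi_x)),
                   tolerance = 1e-10)
    }
  }
})

test_that("Fisher information is zero with a warning at degenerate pi", {
  m6 <- six_param_model()
  # enormous alpha pushes pi to 1 numerically at the top combo
  th <- c(alpha1 = 1e280, beta1 = 0.01, alpha2 = 1e280, beta2 = 0.01,
          alpha3 = 1, beta3 = 1)
  expect_warning(info <- fisher_information(m6, dose_combo(6, 6), th),
                 "information is zero")
  expect_true(all(info == 0))
})

test_that("gamma moment matching round-trips and matches known pairs", {
  expect_equal(gamma_from_moments(1, 0.5), c(shape = 2, rate = 2))
  expect_equal(gamma_from_moments(1, 1), c(shape = 1, rate = 1))
  sr <- gamma_from_moments(0.43, 0.11)
  expect_equal(unname(sr["shape"]), 0.43^2 / 0.11, tolerance = 1e-12)
  expect_equal(unname(sr["rate"]), 0.43 / 0.11, tolerance = 1e-12)
  set.seed(47)
  for (r in 1:25) {
    m <- rlnorm(1); v <- rlnorm(1)
    sr <- gamma_from_moments(m, v)
    expect_equal(unname(sr["shape"] / sr["rate"]), m, tolerance = 1e-12)
    expect_equal(unname(sr["shape"] / sr["rate"]^2), v, tolerance = 1e-12)
  }
  expect_error(gamma_from_moments(-1, 1), "positive")
  expect_error(gamma_from_moments(1, 0), "positive")
})

test_that("skeleton equals the prior-mean single-agent margins", {
  g <- default_grid()
  # near-degenerate prior at alpha = beta = 1: margin is x / (1 + x)
  pr <- prior_spec(
    means = c(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1,
              alpha3 = 1, beta3 = 1),
    variances = stats::setNames(rep(1e-10, 6),
                                c("alpha1", "beta1", "alpha2", "beta2",
                                  "alpha3", "beta3")))
  sk <- skeleton_from_prior(pr, g, n_draws = 5000, seed = 1)
  expect_equal(sk$p, g$levels_a / (1 + g$levels_a), tolerance = 1e-4)
  expect_equal(sk$q, g$levels_b / (1 + g$levels_b), tolerance = 1e-4)
  # Monte Carlo stability across seeds at large draw counts
  pr2 <- default_six_param_prior()
  s1 <- skeleton_from_prior(pr2, g, n_draws = 1e5, seed = 11)
  s2 <- skeleton_from_prior(pr2, g, n_draws = 1e5, seed = 22)
  expect_lt(max(abs(s1$p - s2$p)), 0.005)
  expect_lt(max(abs(s1$q - s2$q)), 0.005)
  expect_true(all(diff(s1$p) > 0))
  expect_true(all(diff(s1$q) > 0))
  # the margin at dose zero is zero by construction
  th <- c(alpha1 = 0.4, beta1 = 7, alpha2 = 0.4, beta2 = 7,
          alpha3 = 1, beta3 = 1)
  expect_identical(six_param_prob(0, 0, th), 0)
})
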