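# Independent oracles used across test files. These deliberately avoid the
# package's internal gradient / posterior code paths.

# Central-difference gradient of the DLT probability through the public
# scalar probability functions.
numeric_gradient <- function(model, combo, params) {
  xd <- combo_doses(combo, model$grid)
  f <- if (model$type == "six_param") {
    function(th) six_param_prob(xd[1, "xa"], xd[1, "xb"], th)
  } else {
    p <- model$skeleton$p[combo[["i"]]]
    q <- model$skeleton$q[combo[["j"]]]
    function(th) copula_prob(p, q, th)
  }
  g <- numeric(length(params))
  for (k in seq_along(params)) {
    h <- 1e-6 * abs(params[k])
    up <- params; up[k] <- up[k] + h
    dn <- params; dn[k] <- dn[k] - h
    g[k] <- (f(up) - f(dn)) / (2 * h)
  }
  names(g) <- names(params)
  g
}

# Longhand copula probability at one skeleton pair for a node matrix.
copula_pi_nodes <- function(nodes, p, q) {
  pd <- p^nodes[, "delta"]
  qd <- q^nodes[, "psi"]
  ga <- nodes[, "gamma"]
  1 - ((1 - pd)^(-ga) + (1 - qd)^(-ga) - 1)^(-1 / ga)
}

# Dense grid-quadrature posterior mean of pi at given combos for the
# three-parameter copula model: log-spaced nodes per parameter, trapezoid
# weights, prior density x binomial likelihood.
quadrature_posterior_mean <- function(model, history, combos, n_nodes = 51) {
  stopifnot(model$type == "copula")
  nodes1d <- list(); w1d <- list()
  for (k in seq_len(3)) {
    lo <- qgamma(1e-5, model$prior$shape[k], model$prior$rate[k])
    hi <- qgamma(1 - 1e-5, model$prior$shape[k], model$prior$rate[k])
    lx <- seq(log(lo), log(hi), length.out = n_nodes)
    x <- exp(lx)
    dlog <- numeric(n_nodes)
    dlog[1] <- (lx[2] - lx[1]) / 2
    dlog[n_nodes] <- (lx[n_nodes] - lx[n_nodes - 1]) / 2
    dlog[2:(n_nodes - 1)] <- (lx[3:n_nodes] - lx[1:(n_nodes - 2)]) / 2
    nodes1d[[k]] <- x
    w1d[[k]] <- dgamma(x, model$prior$shape[k], model$prior$rate[k]) * x *
      dlog
  }
  nodes <- as.matrix(expand.grid(delta = nodes1d[[1]], psi = nodes1d[[2]],
                                 gamma = nodes1d[[3]]))
  wg <- as.matrix(expand.grid(w1 = w1d[[1]], w2 = w1d[[2]],
                              w3 = w1d[[3]]))
  wts <- wg[, 1] * wg[, 2] * wg[, 3]
  ll <- rep(0, nrow(nodes))
  if (history$n > 0) {
    for (r in seq_len(history$n)) {
      pk <- copula_pi_nodes(nodes, model$skeleton$p[history$i[r]],
                            model$skeleton$q[history$j[r]])
      ll <- ll + if (history$y[r] == 1) log(pk) else log1p(-pk)
    }
  }
  post_w <- wts * exp(ll - max(ll))
  post_w <- post_w / sum(post_w)
  vapply(seq_len(nrow(combos)), function(r) {
    sum(post_w * copula_pi_nodes(nodes, model$skeleton$p[combos[r, 1]],
                                 model$skeleton$q[combos[r, 2]]))
  }, numeric(1))
}

# Random positive parameter vectors for property sweeps.
random_six_params <- function() {
  stats::setNames(stats::rlnorm(6, meanlog = 0, sdlog = 0.6),
                  c("alpha1", "beta1", "alpha2", "beta2", "alpha3", "beta3"))
}

random_copula_params <- function() {
  stats::setNames(stats::rlnorm(3, meanlog = 0, sdlog = 0.6),
                  c("delta", "psi", "gamma"))
}

test_skeleton <- function() {
  skeleton(p = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
           q = c(0.04, 0.12, 0.22, 0.32, 0.42, 0.52))
}

# First per-trial seed spawned by run_study's master seed.
with_seed_probe <- function(seed) {
  combodose:::with_seed(seed, sample.int(2147483646L, 1))
}
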