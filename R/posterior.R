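# Posterior computation over model parameters.
#
# The priors are proper and low-dimensional (3 or 6 gamma margins) and the
# likelihood from a Phase I history (<= a few dozen Bernoulli outcomes) is
# mild, so self-normalized importance sampling with the prior as proposal is
# the default backend: draws never move, only the weights, which makes
# repeated posterior updates within a simulated trial cheap and exactly
# reproducible. An adaptive random-walk Metropolis backend on log-parameters
# is available behind the same contract.

#' Posterior draws of model parameters given a trial history
#'
#' The posterior is proportional to the binomial likelihood of the history
#' times the independent gamma priors. With an empty history the weights are
#' uniform and the draws are prior draws.
#'
#' @param model a [six_param_model()] or [copula_model()].
#' @param history a [trial_history()].
#' @param n_draws number of draws (importance sample size, or retained MCMC
#'   iterations).
#' @param seed integer seed; identical seeds give bit-identical results.
#' @param backend "importance" (default) or "mcmc".
#' @param min_ess if the effective sample size of the importance weights
#'   falls below this, the draw count is increased tenfold once (with a
#'   warning) before returning.
#' @return Object of class `posterior_draws`: list with `theta` (n x p draw
#'   matrix), `weights` (normalized, summing to 1), `ess`, `seed`, `backend`.
#' @export
posterior_draws <- function(model, history = trial_history(),
                            n_draws = 5000, seed = 1L,
                            backend = c("importance", "mcmc"),
                            min_ess = 50) {
  backend <- match.arg(backend)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  with_seed(seed, {
    if (backend == "mcmc") {
      theta <- mcmc_draws(model, history, n_draws)
      out <- list(theta = theta,
                  weights = rep(1 / nrow(theta), nrow(theta)),
                  ess = nrow(theta), seed = seed, backend = backend)
      return(structure(out, class = "posterior_draws"))
    }
    res <- is_fit(model, history, n_draws)
    if (res$ess < min_ess && n_draws >= 1) {
      warning("effective sample size ", round(res$ess, 1), " < ", min_ess,
              "; increasing draws tenfold", call. = FALSE)
      res <- is_fit(model, history, 10 * n_draws)
    }
    structure(list(theta = res$theta, weights = res$weights, ess = res$ess,
                   seed = seed, backend = backend),
              class = "posterior_draws")
  })
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior draws (", x$backend, "): ", nrow(x$theta), " draws, ESS ",
      round(x$ess, 1), "\n", sep = "")
  pm <- drop(crossprod(x$theta, x$weights))
  cat("posterior means:\n")
  print(round(pm, 4))
  invisible(x)
}

# Importance-sampling fit using the current RNG stream.
is_fit <- function(model, history, n_draws) {
  theta <- prior_draw_matrix(model$prior, n_draws)
  lw <- loglik_vector(model, history, theta)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  list(theta = theta, weights = w, ess = 1 / sum(w^2))
}

# Log likelihood of the history for every row of a draw matrix.
loglik_vector <- function(model, history, theta) {
  if (history$n == 0L) return(rep(0, nrow(theta)))
  lin <- combo_lin(cbind(history$i, history$j), model$grid)
  ncell <- model$grid$I * model$grid$J
  n1 <- tabulate(lin[history$y == 1L], nbins = ncell)
  n0 <- tabulate(lin[history$y == 0L], nbins = ncell)
  used <- which(n1 + n0 > 0L)
  mats <- model_loglik_mats(model, grid_combos(model$grid)[used, , drop = FALSE],
                            theta)
  drop(n1[used] %*% mats$lp + n0[used] %*% mats$l1p)
}

# All grid combos as a 2-column matrix in linear-index order (i fastest).
grid_combos <- function(grid) {
  cbind(i = rep(seq_len(grid$I), times = grid$J),
        j = rep(seq_len(grid$J), each = grid$I))
}

# log pi and log(1 - pi) at a set of combos, computed in numerically stable
# form for each model. Returns C x N matrices `pi`, `lp`, `l1p`.
model_loglik_mats <- function(model, combos, theta) {
  im <- as_combo_matrix(combos)
  if (model$type == "six_param") {
    xd <- combo_doses(im, model$grid)
    s <- sixp_s_terms(xd[, "xa"], xd[, "xb"], theta)$s
    list(pi = s / (1 + s), lp = log(s) - log1p(s), l1p = -log1p(s))
  } else {
    p <- model$skeleton$p[im[, 1L]]
    q <- model$skeleton$q[im[, 2L]]
    lu <- log1p(-exp(outer(log(p), theta[, "delta"])))
    lv <- log1p(-exp(outer(log(q), theta[, "psi"])))
    s1 <- expm1(sweep(lu, 2, -theta[, "gamma"], "*")) +
          expm1(sweep(lv, 2, -theta[, "gamma"], "*"))
    l1p <- -sweep(log1p(s1), 2, theta[, "gamma"], "/")
    pi <- -expm1(l1p)
    list(pi = pi, lp = log(pi), l1p = l1p)
  }
}

#' Posterior mean toxicity surface
#'
#' Weight-averaged probability of DLT at every grid combination.
#'
#' @param draws a [posterior_draws()] object.
#' @param model the `combo_model` the draws were generated under.
#' @return I x J matrix of posterior mean DLT probabilities, rows indexed by
#'   drug-A level and columns by drug-B level, with dose levels as dimnames.
#' @export
posterior_mean_surface <- function(draws, model) {
  pm <- model_prob_mat(model, grid_combos(model$grid), draws$theta)
  surf <- matrix(drop(pm %*% draws$weights), model$grid$I, model$grid$J,
                 dimnames = list(model$grid$levels_a, model$grid$levels_b))
  surf
}

#' Posterior expected log determinant of the accumulated Fisher information
#'
#' The Bayesian D-optimality criterion for assigning the next cohort: for
#' each parameter draw, the information accumulated over the trial history
#' plus one observation at the candidate combination,
#' \eqn{M(\theta) = \sum_k I(x_k, \theta) + I(\xi, \theta)}, is formed and
#' regularized as \eqn{M + \tau I_p}; the weighted average of
#' \eqn{\log\det} over draws is returned. A single Bernoulli observation has
#' rank-one information, so the criterion is only meaningful over the
#' accumulated trial information; the ridge \eqn{\tau} handles early-trial
#' singularity uniformly across candidates.
#'
#' @param draws a [posterior_draws()] object.
#' @param model the `combo_model`.
#' @param history a [trial_history()].
#' @param candidate the candidate [dose_combo()].
#' @param ridge regularization constant added to the diagonal (default 1e-8).
#' @return scalar; larger values are more informative allocations.
#' @export
expected_log_det_info <- function(draws, model, history, candidate,
                                  ridge = 1e-8) {
  p <- n_params(model$prior)
  Mh <- info_accum_mat(model, draws$theta, history)
  Mc <- Mh + info_outer_mat(model, draws$theta, candidate)
  ld <- logdet_cols(Mc, p, ridge)
  sum(draws$weights * ld)
}

# Accumulated information over a history, flattened: p^2 x N matrix whose
# column n is vec(M(theta_n)).
info_accum_mat <- function(model, theta, history) {
  p <- n_params(model$prior)
  M <- matrix(0, p * p, nrow(theta))
  if (history$n == 0L) return(M)
  im <- experimented_set(history)
  lin <- combo_lin(cbind(history$i, history$j), model$grid)
  cnt <- tabulate(lin, nbins = model$grid$I * model$grid$J)
  for (r in seq_len(nrow(im))) {
    cmb <- im[r, , drop = FALSE]
    M <- M + cnt[combo_lin(cmb, model$grid)] *
      info_outer_mat(model, theta, cmb)
  }
  M
}

# vec(g g^T / (pi (1 - pi))) for one combo, all draws: p^2 x N.
info_outer_mat <- function(model, theta, combo) {
  p <- n_params(model$prior)
  g <- model_grad_mat(model, combo, theta)          # p x N
  pi_x <- drop(model_prob_mat(model, combo, theta)) # N
  v <- 1 / (pi_x * (1 - pi_x))
  v[pi_x <= .Machine$double.eps | pi_x >= 1 - .Machine$double.eps] <- 0
  gv <- sweep(g, 2, v, "*")
  g[rep(seq_len(p), each = p), , drop = FALSE] *
    gv[rep(seq_len(p), times = p), , drop = FALSE]
}

# log det(M + ridge I) for every column of a p^2 x N flattened matrix.
logdet_cols <- function(Mflat, p, ridge) {
  n <- ncol(Mflat)
  out <- numeric(n)
  dix <- (seq_len(p) - 1L) * p + seq_len(p)
  for (k in seq_len(n)) {
    M <- matrix(Mflat[, k], p, p)
    M[dix] <- M[dix] + ridge
    R <- tryCatch(chol(M), error = function(e) NULL)
    out[k] <- if (is.null(R)) -Inf else 2 * sum(log(diag(R)))
  }
  out
}

# ---- MCMC backend ----------------------------------------------------------

# Adaptive random-walk Metropolis on log-parameters. Returns n_draws rows
# after burn-in and thinning; uses the current RNG stream.
mcmc_draws <- function(model, history, n_draws, burnin = 2000, thin = 5) {
  p <- n_params(model$prior)
  log_post <- function(lth) {
    th <- exp(lth)
    sum(stats::dgamma(th, shape = model$prior$shape, rate = model$prior$rate,
                      log = TRUE)) + sum(lth) +
      log_likelihood(model, history, stats::setNames(th, model$prior$names))
  }
  cur <- log(model$prior$mean)
  cur_lp <- log_post(cur)
  step <- 0.3
  total <- burnin + n_draws * thin
  keep <- matrix(0, n_draws, p, dimnames = list(NULL, model$prior$names))
  acc <- 0L; kept <- 0L
  for (it in seq_len(total)) {
    prop <- cur + stats::rnorm(p, 0, step)
    prop_lp <- log_post(prop)
    if (is.finite(prop_lp) && log(stats::runif(1)) < prop_lp - cur_lp) {
      cur <- prop; cur_lp <- prop_lp; acc <- acc + 1L
    }
    if (it <= burnin && it %% 100 == 0) {
      step <- step * exp((acc / it - 0.3))
    }
    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1L
      keep[kept, ] <- exp(cur)
    }
  }
  keep
}
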