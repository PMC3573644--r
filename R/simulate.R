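#' Simulate a single two-agent escalation trial
#'
#' Runs one full trial under a known true-toxicity scenario. The first
#' cohort is treated at the configured start combination; before each
#' subsequent cohort the posterior is updated on all accumulated data, the
#' admissible set is built around the current combination, the configured
#' decision rule picks the next combination, and `cohort_size` Bernoulli
#' outcomes are drawn from the scenario's true probability at that
#' combination. After the last cohort the final posterior-mean surface and
#' the recommended Phase II set are computed. Fully deterministic given the
#' seed.
#'
#' @param model a [six_param_model()] or [copula_model()].
#' @param scen a [scenario()].
#' @param config a [trial_config()].
#' @param seed integer seed for this trial.
#' @return Object of class `trial_result`: list with `history`, `surface`
#'   (final posterior mean), `rpii` (recommended combos), `true_prob_seq`
#'   (true DLT probability of each patient's dose, in recruitment order),
#'   `ess_upgrades` (number of posterior updates that needed a larger
#'   importance sample), `seed`.
#' @export
simulate_trial <- function(model, scen, config, seed = 1L) {
  stopifnot(inherits(model, "combo_model"), inherits(scen, "scenario"),
            inherits(config, "trial_config"))
  if (!identical(dim(scen$true_prob), c(model$grid$I, model$grid$J)))
    stop("scenario and model grid dimensions disagree", call. = FALSE)
  with_seed(seed, simulate_trial_impl(model, scen, config, seed))
}

simulate_trial_impl <- function(model, scen, config, seed) {
  grid <- model$grid
  prop <- make_proposal(model, config$n_draws)
  history <- trial_history()
  current <- dose_combo(config$start[1], config$start[2], grid)
  ess_upgrades <- 0L
  post <- NULL
  for (co in seq_len(config$n_cohorts)) {
    if (co > 1L) {
      post <- posterior_from_proposal(prop, model, history)
      if (post$ess < config$min_ess) {
        ess_upgrades <- ess_upgrades + 1L
        prop <- make_proposal(model, 10L * config$n_draws)
        post <- posterior_from_proposal(prop, model, history)
      }
      adm <- admissible_set(current, grid, config$omega, history)
      current <- if (config$rule == "d1") {
        choose_next_D1(adm, post$surface, config$ttl, grid)
      } else {
        choose_d2_fast(adm, post$surface, prop, post, model, history, config)
      }
    }
    pr <- scen$true_prob[current[["i"]], current[["j"]]]
    y <- stats::rbinom(config$cohort_size, 1L, pr)
    history <- history_append(history, current, y)
  }
  post <- posterior_from_proposal(prop, model, history)
  if (post$ess < config$min_ess) {
    ess_upgrades <- ess_upgrades + 1L
    prop <- make_proposal(model, 10L * config$n_draws)
    post <- posterior_from_proposal(prop, model, history)
  }
  rpii <- rpii_set(history, post$surface, config$ttl, config$epsilon)
  structure(list(history = history, surface = post$surface, rpii = rpii,
                 true_prob_seq = scen$true_prob[cbind(history$i, history$j)],
                 final_ess = post$ess, ess_upgrades = ess_upgrades,
                 seed = seed),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("simulated trial:", x$history$n, "patients,", sum(x$history$y),
      "DLTs\n")
  cat("recommended Phase II combos:",
      if (nrow(x$rpii) == 0L) "none" else
        paste0("(", x$rpii[, 1L], ",", x$rpii[, 2L], ")", collapse = " "),
      "\n")
  invisible(x)
}

# ---- shared-proposal posterior updates (simulation fast path) --------------

# Draw a prior importance sample once per trial and precompute, for every
# grid combination, pi, log pi and log(1 - pi) for every draw. Posterior
# updates within the trial then only recompute weights.
make_proposal <- function(model, n_draws) {
  theta <- prior_draw_matrix(model$prior, n_draws)
  mats <- model_loglik_mats(model, grid_combos(model$grid), theta)
  list(theta = theta, pi = mats$pi, lp = mats$lp, l1p = mats$l1p,
       n = n_draws)
}

posterior_from_proposal <- function(prop, model, history) {
  ncell <- model$grid$I * model$grid$J
  if (history$n == 0L) {
    w <- rep(1 / prop$n, prop$n)
  } else {
    lin <- combo_lin(cbind(history$i, history$j), model$grid)
    n1 <- tabulate(lin[history$y == 1L], nbins = ncell)
    n0 <- tabulate(lin[history$y == 0L], nbins = ncell)
    lw <- drop(n1 %*% prop$lp + n0 %*% prop$l1p)
    w <- exp(lw - max(lw))
    w <- w / sum(w)
  }
  surface <- matrix(drop(prop$pi %*% w), model$grid$I, model$grid$J,
                    dimnames = list(model$grid$levels_a,
                                    model$grid$levels_b))
  list(weights = w, ess = 1 / sum(w^2), surface = surface)
}

# D2 with the per-trial proposal: systematic resampling to a small
# equally-weighted draw set, shared accumulated information across
# candidates.
choose_d2_fast <- function(adm, surface, prop, post, model, history,
                           config) {
  grid <- model$grid
  restr <- restrict_by_tolerance(adm, surface, config$ttl, config$epsilon)
  if (nrow(restr) == 0L)
    return(choose_next_D1(adm, surface, config$ttl, grid))
  if (nrow(restr) == 1L)
    return(dose_combo(restr[1, 1L], restr[1, 2L], grid))
  m <- min(config$n_info_draws, prop$n)
  idx <- systematic_resample(post$weights, m)
  theta_m <- prop$theta[idx, , drop = FALSE]
  p <- n_params(model$prior)
  Mh <- info_accum_mat(model, theta_m, history)
  restr <- order_candidates(restr, grid)
  crit <- vapply(seq_len(nrow(restr)), function(r) {
    Mc <- Mh + info_outer_mat(model, theta_m, restr[r, , drop = FALSE])
    mean(logdet_cols(Mc, p, 1e-8))
  }, numeric(1))
  k <- which.max(crit)
  dose_combo(restr[k, 1L], restr[k, 2L], grid)
}

# Systematic resampling: m indices with expected multiplicity m * w.
systematic_resample <- function(w, m) {
  u <- (stats::runif(1) + seq_len(m) - 1) / m
  findInterval(u, cumsum(w)) + 1L
}

# ---- study-level aggregation -----------------------------------------------

#' Operating characteristics of a design over repeated simulated trials
#'
#' Repeats [simulate_trial()] `n_sims` times (per-trial seeds are derived
#' from the master seed) and aggregates:
#' \describe{
#'   \item{experimentation_pct}{distribution over toxicity bands of the true
#'     DLT probability at each treated patient's dose, pooled over all
#'     patients and simulations (sums to 100).}
#'   \item{recommendation_pct}{same distribution over all recommended
#'     Phase II doses pooled across simulations; trials with an empty
#'     recommendation set contribute nothing (their rate is reported as
#'     `pct_empty_rpii`).}
#'   \item{pct_mtd_selected}{mean over simulations of 100 x |RPII
#'     intersected with the true MTD set| / |true MTD set|.}
#'   \item{mean_tox_by_patient}{mean true DLT probability of the dose given
#'     to the k-th recruited patient, a per-patient escalation curve.}
#' }
#'
#' @param model a `combo_model`.
#' @param scen a [scenario()].
#' @param config a [trial_config()].
#' @param n_sims number of simulated trials.
#' @param seed master seed; spawns one sub-seed per trial.
#' @param verbose print progress every 50 simulations.
#' @return object of class `operating_characteristics`.
#' @export
run_study <- function(model, scen, config, n_sims = 1000, seed = 1L,
                      verbose = FALSE) {
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  trial_seeds <- with_seed(seed, sample.int(2147483646L, n_sims))
  mtd <- true_mtd_set(scen, config$ttl, config$epsilon)
  mtd_key <- paste(mtd[, 1L], mtd[, 2L])
  n_pat <- config$cohort_size * config$n_cohorts
  exp_counts <- stats::setNames(numeric(5), band_levels())
  rec_counts <- stats::setNames(numeric(5), band_levels())
  tox_sum <- numeric(n_pat)
  pct_mtd <- numeric(n_sims)
  n_empty <- 0L
  n_rec <- 0L
  ess_upgrades <- 0L
  mtd_sd <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    res <- simulate_trial(model, scen, config, seed = trial_seeds[s])
    exp_counts <- exp_counts +
      tabulate(classify_band(res$true_prob_seq), nbins = 5L)
    tox_sum <- tox_sum + res$true_prob_seq
    if (nrow(res$rpii) == 0L) {
      n_empty <- n_empty + 1L
    } else {
      rec_p <- scen$true_prob[res$rpii]
      rec_counts <- rec_counts + tabulate(classify_band(rec_p), nbins = 5L)
      n_rec <- n_rec + length(rec_p)
    }
    hit <- sum(paste(res$rpii[, 1L], res$rpii[, 2L]) %in% mtd_key)
    pct_mtd[s] <- 100 * hit / nrow(mtd)
    ess_upgrades <- ess_upgrades + res$ess_upgrades
    if (verbose && s %% 50 == 0)
      message("  ", s, " / ", n_sims, " simulations")
  }
  structure(list(
    experimentation_pct = 100 * exp_counts / (n_sims * n_pat),
    recommendation_pct = if (n_rec > 0) 100 * rec_counts / n_rec
                         else rec_counts,
    pct_mtd_selected = mean(pct_mtd),
    se_pct_mtd_selected = stats::sd(pct_mtd) / sqrt(n_sims),
    mean_tox_by_patient = tox_sum / n_sims,
    pct_empty_rpii = 100 * n_empty / n_sims,
    n_recommended = n_rec,
    ess_upgrades = ess_upgrades,
    n_sims = n_sims, seed = seed,
    scenario = scen$name, model = model$type,
    rule = config$rule, omega = config$omega),
    class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat("operating characteristics: ", x$model, ", ", x$rule, ", ", x$omega,
      ", ", x$scenario, " (", x$n_sims, " simulations)\n", sep = "")
  df <- data.frame(band = band_levels(),
                   experimentation = round(unname(x$experimentation_pct), 1),
                   recommendation = round(unname(x$recommendation_pct), 1))
  print(df, row.names = FALSE)
  cat("% of true MTDs selected:", round(x$pct_mtd_selected, 1), "\n")
  cat("% trials with empty recommendation set:",
      round(x$pct_empty_rpii, 1), "\n")
  invisible(x)
}
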