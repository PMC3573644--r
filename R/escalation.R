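#' Trial configuration
#'
#' Bundles the design constants of a two-agent escalation trial: target
#' toxicity level (TTL), the tolerance defining both the D-optimality
#' restriction and the Phase II recommendation window, cohorting, the
#' starting combination, the decision rule and the admissible-set strategy.
#'
#' @param ttl target toxicity level, in (0, 1) (default 0.30).
#' @param epsilon tolerance around the TTL, in (0, ttl) (default 0.025, i.e.
#'   the window \[0.275, 0.325\] at the default TTL).
#' @param cohort_size patients per cohort (default 2).
#' @param n_cohorts cohorts per trial (default 20, i.e. 40 patients).
#' @param start starting combination as c(i, j) (default c(1, 1), the lowest
#'   combination).
#' @param rule decision rule: "d1" (posterior mean closest to TTL) or "d2"
#'   (tolerance-restricted Bayesian D-optimality).
#' @param omega admissible-set strategy: "omega1" (orthogonal neighbours),
#'   "omega2" (adds diagonal moves), "omega3" (adds previously experimented
#'   combinations).
#' @param n_draws importance-sample size per posterior update (default 5000).
#' @param n_info_draws equally-weighted draws (systematic resampling) used to
#'   average the D-optimality criterion (default 128).
#' @param min_ess effective-sample-size floor triggering a one-off tenfold
#'   increase of the importance sample (default 50).
#' @return object of class `trial_config`.
#' @export
trial_config <- function(ttl = 0.30, epsilon = 0.025, cohort_size = 2,
                         n_cohorts = 20, start = c(1, 1),
                         rule = c("d1", "d2"),
                         omega = c("omega1", "omega2", "omega3"),
                         n_draws = 5000, n_info_draws = 128, min_ess = 50) {
  rule <- match.arg(rule)
  omega <- match.arg(omega)
  if (!(ttl > 0 && ttl < 1)) stop("ttl must be in (0, 1)", call. = FALSE)
  if (!(epsilon > 0 && epsilon < ttl))
    stop("epsilon must be in (0, ttl)", call. = FALSE)
  if (cohort_size < 1 || n_cohorts < 1)
    stop("cohort_size and n_cohorts must be >= 1", call. = FALSE)
  structure(list(ttl = ttl, epsilon = epsilon,
                 cohort_size = as.integer(cohort_size),
                 n_cohorts = as.integer(n_cohorts),
                 start = as.integer(start), rule = rule, omega = omega,
                 n_draws = as.integer(n_draws),
                 n_info_draws = as.integer(n_info_draws),
                 min_ess = min_ess),
            class = "trial_config")
}

#' @export
print.trial_config <- function(x, ...) {
  cat("trial config: TTL ", x$ttl, " +/- ", x$epsilon, ", ",
      x$n_cohorts, " cohorts x ", x$cohort_size, ", start (",
      x$start[1], ",", x$start[2], "), rule ", x$rule, ", ", x$omega,
      "\n", sep = "")
  invisible(x)
}

#' Admissible dose combinations for the next cohort
#'
#' To prevent dose skipping, the next cohort may only be treated at
#' combinations close to the current one. Three strategies are supported:
#' \describe{
#'   \item{omega1}{the current combination and its orthogonal neighbours
#'     (one drug changed by one level, escalation or de-escalation).}
#'   \item{omega2}{omega1 plus the diagonal moves: both drugs changed by one
#'     level at once. By default all four diagonal neighbours are admissible
#'     (simultaneous escalation or de-escalation of both drugs, and the
#'     anti-diagonal moves that travel along a toxicity contour);
#'     `diagonal = "main"` restricts to both-up / both-down only.}
#'   \item{omega3}{omega2 plus every combination already experimented on
#'     during the trial, allowing jumps back into explored territory.}
#' }
#' The set always contains the current combination, so it is never empty.
#'
#' @param current the current [dose_combo()].
#' @param grid a [dose_grid()].
#' @param strategy "omega1", "omega2" or "omega3".
#' @param history a [trial_history()] (used by omega3 for the experimented
#'   set).
#' @param diagonal which diagonal moves omega2/omega3 add: "all" (default;
#'   the full eight-cell neighbourhood) or "main" (both-up and both-down
#'   only).
#' @return 2-column integer matrix of admissible combos (columns `i`, `j`),
#'   ordered by total standardized dose then drug-A index.
#' @export
admissible_set <- function(current, grid, strategy = c("omega1", "omega2",
                                                       "omega3"),
                           history = trial_history(),
                           diagonal = c("all", "main")) {
  strategy <- match.arg(strategy)
  diagonal <- match.arg(diagonal)
  i <- current[["i"]]; j <- current[["j"]]
  if (i < 1L || i > grid$I || j < 1L || j > grid$J)
    stop("current combo outside grid", call. = FALSE)
  cand <- rbind(c(i, j), c(i + 1L, j), c(i - 1L, j), c(i, j + 1L),
                c(i, j - 1L))
  if (strategy %in% c("omega2", "omega3")) {
    cand <- rbind(cand, c(i + 1L, j + 1L), c(i - 1L, j - 1L))
    if (diagonal == "all")
      cand <- rbind(cand, c(i + 1L, j - 1L), c(i - 1L, j + 1L))
  }
  if (strategy == "omega3")
    cand <- rbind(cand, experimented_set(history))
  keep <- cand[, 1L] >= 1L & cand[, 1L] <= grid$I &
          cand[, 2L] >= 1L & cand[, 2L] <= grid$J
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[!duplicated(cand), , drop = FALSE]
  colnames(cand) <- c("i", "j")
  order_candidates(cand, grid)
}

# Deterministic candidate ordering: total standardized dose, then drug-A
# index, then drug-B index. which.min on this ordering realises the
# documented tie-break.
order_candidates <- function(cand, grid) {
  tot <- grid$levels_a[cand[, 1L]] + grid$levels_b[cand[, 2L]]
  cand[order(tot, cand[, 1L], cand[, 2L]), , drop = FALSE]
}

#' Restrict candidates to a tolerance window around the TTL
#'
#' Keeps combinations whose posterior mean DLT probability lies within
#' `epsilon` of the target (inclusive). May return an empty set.
#'
#' @param candidates 2-column matrix of combos.
#' @param surface posterior-mean matrix from [posterior_mean_surface()].
#' @param ttl target toxicity level.
#' @param epsilon tolerance.
#' @return subset of `candidates` (possibly zero rows).
#' @export
restrict_by_tolerance <- function(candidates, surface, ttl, epsilon) {
  im <- as_combo_matrix(candidates)
  keep <- abs(surface[im] - ttl) <= epsilon
  im[keep, , drop = FALSE]
}

#' Next dose by posterior-mean targeting (rule D1)
#'
#' Among the admissible candidates, picks the combination whose posterior
#' mean DLT probability is closest to the TTL. Exact ties are broken towards
#' the smaller total standardized dose, then the smaller drug-A index, so
#' the choice is deterministic and errs on the safe side.
#'
#' @param candidates non-empty 2-column matrix of admissible combos.
#' @param surface posterior-mean matrix.
#' @param ttl target toxicity level.
#' @param grid the [dose_grid()] (needed for the tie-break on total dose).
#' @return the chosen [dose_combo()].
#' @export
choose_next_D1 <- function(candidates, surface, ttl, grid) {
  im <- as_combo_matrix(candidates)
  if (nrow(im) == 0L) stop("candidate set is empty", call. = FALSE)
  im <- order_candidates(im, grid)
  k <- which.min(abs(surface[im] - ttl))
  dose_combo(im[k, 1L], im[k, 2L], grid)
}

#' Next dose by tolerance-restricted Bayesian D-optimality (rule D2)
#'
#' Restricts the admissible candidates to those whose posterior mean DLT
#' probability is within `epsilon` of the TTL, then picks the restricted
#' candidate maximizing the posterior expected log determinant of the
#' accumulated Fisher information ([expected_log_det_info()]). If the
#' restricted set is empty the rule falls back to [choose_next_D1()] over
#' the unrestricted candidates.
#'
#' @inheritParams choose_next_D1
#' @param draws a [posterior_draws()] object.
#' @param model the `combo_model`.
#' @param history the current [trial_history()].
#' @param epsilon tolerance for the restriction.
#' @return the chosen [dose_combo()].
#' @export
choose_next_D2 <- function(candidates, surface, draws, model, history,
                           ttl, epsilon) {
  grid <- model$grid
  im <- as_combo_matrix(candidates)
  if (nrow(im) == 0L) stop("candidate set is empty", call. = FALSE)
  restr <- restrict_by_tolerance(im, surface, ttl, epsilon)
  if (nrow(restr) == 0L)
    return(choose_next_D1(im, surface, ttl, grid))
  if (nrow(restr) == 1L)
    return(dose_combo(restr[1, 1L], restr[1, 2L], grid))
  restr <- order_candidates(restr, grid)
  crit <- vapply(seq_len(nrow(restr)), function(r) {
    expected_log_det_info(draws, model, history, restr[r, , drop = FALSE])
  }, numeric(1))
  k <- which.max(crit)
  dose_combo(restr[k, 1L], restr[k, 2L], grid)
}

#' Dose combinations recommended for Phase II
#'
#' At the end of the trial, the recommended Phase II (RPII) set contains the
#' combinations that were experimented on during the trial and whose final
#' posterior mean DLT probability lies within `epsilon` of the TTL. The set
#' may be empty and never contains an unexperimented combination.
#'
#' @param history the complete [trial_history()].
#' @param surface final posterior-mean matrix computed from the full history.
#' @param ttl target toxicity level.
#' @param epsilon tolerance.
#' @return 2-column integer matrix of recommended combos (possibly empty).
#' @export
rpii_set <- function(history, surface, ttl, epsilon) {
  restrict_by_tolerance(experimented_set(history), surface, ttl, epsilon)
}
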