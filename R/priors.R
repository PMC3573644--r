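#' Gamma shape and rate from a mean and variance
#'
#' Moment matching for the gamma family: a gamma distribution with shape
#' `mean^2/variance` and rate `mean/variance` has exactly the requested mean
#' and variance. Prior tables for dose-toxicity models are typically published
#' as (mean, variance) pairs, so this is the constructor used throughout.
#'
#' @param mean prior mean, > 0.
#' @param variance prior variance, > 0.
#' @return named numeric vector `c(shape =, rate =)`.
#' @examples
#' gamma_from_moments(1, 0.5)   # gamma(2, 2)
#' @export
gamma_from_moments <- function(mean, variance) {
  if (!is.numeric(mean) || !is.numeric(variance) ||
      any(mean <= 0) || any(variance <= 0) ||
      any(!is.finite(mean)) || any(!is.finite(variance)))
    stop("mean and variance must be positive finite numbers", call. = FALSE)
  c(shape = mean^2 / variance, rate = mean / variance)
}

#' Independent gamma prior specification for a model parameter vector
#'
#' One gamma distribution per parameter, given as (mean, variance) pairs and
#' stored as (shape, rate). Parameter order and names must match the model:
#' `alpha1, beta1, alpha2, beta2, alpha3, beta3` for the six-parameter model,
#' `delta, psi, gamma` for the copula model.
#'
#' @param means named numeric vector of prior means.
#' @param variances named numeric vector of prior variances (same names).
#' @return Object of class `prior_spec`: list with `names`, `mean`,
#'   `variance`, `shape`, `rate` (parallel numeric vectors).
#' @examples
#' prior_spec(c(delta = 1, psi = 1, gamma = 1),
#'            c(delta = 0.5, psi = 0.5, gamma = 0.5))
#' @export
prior_spec <- function(means, variances) {
  if (is.null(names(means)) || is.null(names(variances)) ||
      !identical(names(means), names(variances)))
    stop("means and variances must share the same parameter names",
         call. = FALSE)
  sr <- mapply(gamma_from_moments, means, variances)
  structure(list(names = names(means),
                 mean = as.numeric(means),
                 variance = as.numeric(variances),
                 shape = unname(sr["shape", ]),
                 rate = unname(sr["rate", ])),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  df <- data.frame(parameter = x$names, mean = x$mean, variance = x$variance,
                   shape = x$shape, rate = x$rate)
  cat("independent gamma priors:\n")
  print(df, row.names = FALSE)
  invisible(x)
}

n_params <- function(prior) length(prior$names)

# Internal: n draws from the prior, as an n x p matrix (uses the current RNG
# stream; callers control seeding).
prior_draw_matrix <- function(prior, n) {
  p <- n_params(prior)
  m <- matrix(0, nrow = n, ncol = p, dimnames = list(NULL, prior$names))
  for (k in seq_len(p))
    m[, k] <- stats::rgamma(n, shape = prior$shape[k], rate = prior$rate[k])
  m
}

#' Default elicited priors for the six-parameter model
#'
#' Priors for the Gemcitabine + Cyclophosphamide combination study that the
#' packaged simulations emulate: four parameters describe the single-agent
#' margins and two the drug interaction. Given as gamma distributions moment-
#' matched to elicited means and variances.
#'
#' @return a [prior_spec()] for parameters alpha1..beta3.
#' @export
default_six_param_prior <- function() {
  prior_spec(
    means = c(alpha1 = 0.43, beta1 = 7.65, alpha2 = 0.43, beta2 = 7.80,
              alpha3 = 1.00, beta3 = 1.00),
    variances = c(alpha1 = 0.11, beta1 = 5.71, alpha2 = 0.08, beta2 = 3.99,
                  alpha3 = 0.90, beta3 = 0.90))
}

#' Default priors for the three-parameter copula model
#'
#' Independent gamma(2, 2) priors (mean 1, variance 0.5) on all three
#' parameters. A vaguer gamma(0.1, 0.1) prior on the interaction parameter is
#' numerically unstable when evaluating the Fisher information, because
#' sampled values fall arbitrarily close to zero; gamma(2, 2) is used on all
#' three parameters instead.
#'
#' @return a [prior_spec()] for parameters delta, psi, gamma.
#' @export
default_copula_prior <- function() {
  prior_spec(means = c(delta = 1, psi = 1, gamma = 1),
             variances = c(delta = 0.5, psi = 0.5, gamma = 0.5))
}

#' Default six-level dose grid
#'
#' Six standardized dose levels per agent, concentrated near each agent's
#' single-agent MTD so that experimentation focuses around the presumed
#' target-toxicity contour.
#'
#' @return a [dose_grid()] with levels (0.2, 0.5, 0.7, 0.8, 0.9, 0.95) for
#'   both drugs.
#' @export
default_grid <- function() {
  lv <- c(0.2, 0.5, 0.7, 0.8, 0.9, 0.95)
  dose_grid(lv, lv)
}
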