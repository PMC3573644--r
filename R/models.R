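#' Six-parameter dose-toxicity model for a two-drug combination
#'
#' Probability of a dose-limiting toxicity at standardized doses
#' (xa, xb):
#' \deqn{\pi = \frac{a + b + \alpha_3 (x_A^{\beta_1} x_B^{\beta_2})^{\beta_3}}
#'                  {1 + a + b +
#'                   \alpha_3 (x_A^{\beta_1} x_B^{\beta_2})^{\beta_3}},}
#' with \eqn{a = \alpha_1 x_A^{\beta_1}} and \eqn{b = \alpha_2 x_B^{\beta_2}}.
#' Four parameters describe the single-agent margins and two the interaction.
#' When one drug is absent (dose 0) the model reduces to the single-agent
#' margin \eqn{a/(1+a)} (resp. \eqn{b/(1+b)}); all six parameters are
#' strictly positive and the surface is increasing in each dose.
#'
#' @param xa,xb standardized doses in \[0, 1\] (vectors are recycled to a
#'   common length).
#' @param params named numeric vector with elements alpha1, beta1, alpha2,
#'   beta2, alpha3, beta3, all > 0.
#' @return vector of DLT probabilities in \[0, 1).
#' @examples
#' six_param_prob(0.5, 0.5, c(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1,
#'                            alpha3 = 1, beta3 = 1))  # 1.25/2.25
#' @export
six_param_prob <- function(xa, xb, params) {
  check_dose(xa); check_dose(xb)
  th <- check_params(params, SIX_PARAM_NAMES)
  n <- max(length(xa), length(xb))
  xa <- rep_len(xa, n); xb <- rep_len(xb, n)
  unname(drop(sixp_prob_mat(xa, xb,
                            matrix(th, nrow = 1,
                                   dimnames = list(NULL, SIX_PARAM_NAMES)))))
}

#' Three-parameter copula-type dose-toxicity model
#'
#' A Clayton-copula combination of two single-agent CRM power models:
#' \deqn{\pi = 1 - \left[(1 - p^{\delta})^{-\gamma} +
#'       (1 - q^{\psi})^{-\gamma} - 1\right]^{-1/\gamma},}
#' where p and q are prespecified best-guess ("skeleton") single-agent DLT
#' probabilities and \eqn{\delta, \psi > 0} power parameters with prior mean
#' one. \eqn{\gamma > 0} characterises the drug interaction. When drug B is
#' absent (q = 0) the model reduces to the CRM power model \eqn{p^\delta},
#' and symmetrically to \eqn{q^\psi}; as \eqn{\gamma \to 0} it approaches
#' the independence surface \eqn{1-(1-p^\delta)(1-q^\psi)}.
#'
#' @param p,q skeleton DLT probabilities in \[0, 1); 0 means the drug is
#'   absent. Vectors are recycled to a common length.
#' @param params named numeric vector with elements delta, psi, gamma, all
#'   > 0.
#' @return vector of DLT probabilities in \[0, 1).
#' @examples
#' copula_prob(0.2, 0.2, c(delta = 1, psi = 1, gamma = 1))  # 1/3
#' @export
copula_prob <- function(p, q, params) {
  check_skel_prob(p); check_skel_prob(q)
  th <- check_params(params, COPULA_NAMES)
  n <- max(length(p), length(q))
  p <- rep_len(p, n); q <- rep_len(q, n)
  unname(drop(copula_prob_mat(p, q,
                              matrix(th, nrow = 1,
                                     dimnames = list(NULL, COPULA_NAMES)))))
}

SIX_PARAM_NAMES <- c("alpha1", "beta1", "alpha2", "beta2", "alpha3", "beta3")
COPULA_NAMES <- c("delta", "psi", "gamma")

check_dose <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("doses must lie in [0, 1]", call. = FALSE)
}

check_skel_prob <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x >= 1))
    stop("skeleton probabilities must lie in [0, 1)", call. = FALSE)
}

check_params <- function(params, nms) {
  if (is.null(names(params))) {
    if (length(params) != length(nms))
      stop("expected ", length(nms), " parameters", call. = FALSE)
    names(params) <- nms
  }
  if (!all(nms %in% names(params)))
    stop("params must contain ", paste(nms, collapse = ", "), call. = FALSE)
  th <- as.numeric(params[nms])
  if (any(!is.finite(th)) || any(th <= 0))
    stop("all model parameters must be strictly positive", call. = FALSE)
  names(th) <- nms
  th
}

# ---- vectorized workhorses (C combos x N parameter draws) ------------------

# theta: N x 6 matrix with the six-parameter columns; xa, xb: length-C doses.
# Returns C x N matrix of probabilities. Doses of 0 give exact margins.
sixp_prob_mat <- function(xa, xb, theta) {
  s <- sixp_s_terms(xa, xb, theta)$s
  s / (1 + s)
}

# Shared terms: a, b, c (interaction) and their sum, each C x N. The
# interaction acts on the bare dose powers, c = alpha3 (xa^b1 xb^b2)^b3, so
# it vanishes whenever either drug is absent and the margins are exact.
sixp_s_terms <- function(xa, xb, theta) {
  la <- suppressWarnings(log(xa))            # -Inf at dose 0
  lb <- suppressWarnings(log(xb))
  pa <- outer(la, theta[, "beta1"])          # log xa^beta1
  pb <- outer(lb, theta[, "beta2"])
  a <- exp(sweep(pa, 2, log(theta[, "alpha1"]), "+"))
  b <- exp(sweep(pb, 2, log(theta[, "alpha2"]), "+"))
  a[xa == 0, ] <- 0
  b[xb == 0, ] <- 0
  cc <- exp(sweep(sweep(pa + pb, 2, theta[, "beta3"], "*"),
                  2, log(theta[, "alpha3"]), "+"))
  cc[xa == 0 | xb == 0, ] <- 0
  list(a = a, b = b, cc = cc, s = a + b + cc,
       lxab = pa + pb)
}

# theta: N x 3 copula parameter matrix; p, q: length-C skeleton values.
copula_prob_mat <- function(p, q, theta) {
  lu <- log1p(-exp(outer(suppressWarnings(log(p)), theta[, "delta"])))
  lv <- log1p(-exp(outer(suppressWarnings(log(q)), theta[, "psi"])))
  lu[p == 0, ] <- 0
  lv[q == 0, ] <- 0
  # S - 1 computed via expm1 for stability as gamma -> 0
  s1 <- expm1(sweep(lu, 2, -theta[, "gamma"], "*")) +
        expm1(sweep(lv, 2, -theta[, "gamma"], "*"))
  1 - exp(-sweep(log1p(s1), 2, theta[, "gamma"], "/"))
}

# Analytic gradient of the six-parameter probability at one combo, for all
# draws. Returns 6 x N matrix (rows in SIX_PARAM_NAMES order).
sixp_grad_mat <- function(xa, xb, theta) {
  tt <- sixp_s_terms(xa, xb, theta)
  a <- drop(tt$a); b <- drop(tt$b); cc <- drop(tt$cc); s <- drop(tt$s)
  lxab <- drop(tt$lxab)
  dpids <- 1 / (1 + s)^2
  b3 <- theta[, "beta3"]
  g <- rbind(
    alpha1 = a / theta[, "alpha1"],
    beta1  = if (xa > 0) (a + b3 * cc) * log(xa) else 0 * a,
    alpha2 = b / theta[, "alpha2"],
    beta2  = if (xb > 0) (b + b3 * cc) * log(xb) else 0 * b,
    alpha3 = cc / theta[, "alpha3"],
    beta3  = if (xa > 0 && xb > 0) cc * lxab else 0 * cc)
  sweep(g, 2, dpids, "*")
}

# Analytic gradient of the copula probability at one combo (skeleton values
# p, q scalars), for all draws. Returns 3 x N matrix.
copula_grad_mat <- function(p, q, theta) {
  de <- theta[, "delta"]; ps <- theta[, "psi"]; ga <- theta[, "gamma"]
  pd <- if (p > 0) exp(de * log(p)) else rep(0, nrow(theta))
  qd <- if (q > 0) exp(ps * log(q)) else rep(0, nrow(theta))
  lu <- log1p(-pd); lv <- log1p(-qd)
  s1 <- expm1(-ga * lu) + expm1(-ga * lv)
  ls <- log1p(s1)
  # common factor S^{-1/gamma - 1}
  sm1g1 <- exp(-ls * (1 / ga + 1))
  gdelta <- if (p > 0) sm1g1 * exp(-(ga + 1) * lu) * pd * log(p) else 0 * ga
  gpsi   <- if (q > 0) sm1g1 * exp(-(ga + 1) * lv) * qd * log(q) else 0 * ga
  # d pi / d gamma = S^{-1/gamma} (L'/gamma - L/gamma^2), L = log S
  lprime <- (-exp(-ga * lu) * lu - exp(-ga * lv) * lv) / exp(ls)
  ggamma <- exp(-ls / ga) * (lprime / ga - ls / ga^2)
  rbind(delta = gdelta, psi = gpsi, gamma = ggamma)
}

# ---- model objects ---------------------------------------------------------

#' Dose-toxicity model objects
#'
#' Bundle a model form with the dose grid, prior, and (for the copula model)
#' skeleton, so that posterior and escalation functions can dispatch on a
#' single argument.
#'
#' @param grid a [dose_grid()].
#' @param prior a [prior_spec()] for the model's parameters.
#' @param skeleton a [skeleton()] of single-agent best-guess DLT
#'   probabilities (copula model only).
#' @return Object of class `combo_model` with elements `type` ("six_param"
#'   or "copula"), `grid`, `prior` and, for the copula model, `skeleton`.
#' @seealso [six_param_prob()], [copula_prob()], [skeleton_from_prior()]
#' @export
six_param_model <- function(grid = default_grid(),
                            prior = default_six_param_prior()) {
  stopifnot(inherits(grid, "dose_grid"), inherits(prior, "prior_spec"))
  if (!identical(prior$names, SIX_PARAM_NAMES))
    stop("prior must cover parameters ",
         paste(SIX_PARAM_NAMES, collapse = ", "), call. = FALSE)
  structure(list(type = "six_param", grid = grid, prior = prior,
                 skeleton = NULL), class = "combo_model")
}

#' @rdname six_param_model
#' @export
copula_model <- function(grid = default_grid(), skeleton,
                         prior = default_copula_prior()) {
  stopifnot(inherits(grid, "dose_grid"), inherits(prior, "prior_spec"),
            inherits(skeleton, "skeleton"))
  if (!identical(prior$names, COPULA_NAMES))
    stop("prior must cover parameters ",
         paste(COPULA_NAMES, collapse = ", "), call. = FALSE)
  if (length(skeleton$p) != grid$I || length(skeleton$q) != grid$J)
    stop("skeleton length must match the grid", call. = FALSE)
  structure(list(type = "copula", grid = grid, prior = prior,
                 skeleton = skeleton), class = "combo_model")
}

#' @export
print.combo_model <- function(x, ...) {
  cat(switch(x$type,
             six_param = "six-parameter combination dose-toxicity model",
             copula = "three-parameter copula-type dose-toxicity model"),
      "\n")
  print(x$grid)
  if (!is.null(x$skeleton)) {
    cat("  skeleton p:", paste(round(x$skeleton$p, 3), collapse = ", "), "\n")
    cat("  skeleton q:", paste(round(x$skeleton$q, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Single-agent skeleton probabilities for the copula model
#'
#' @param p best-guess DLT probabilities for drug A alone, one per grid
#'   level, strictly increasing, in (0, 1).
#' @param q same for drug B.
#' @return object of class `skeleton`.
#' @export
skeleton <- function(p, q) {
  chk <- function(x, nm) {
    if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
      stop(nm, " must lie strictly in (0, 1)", call. = FALSE)
    if (length(x) > 1L && any(diff(x) <= 0))
      stop(nm, " must be strictly increasing", call. = FALSE)
  }
  chk(p, "p"); chk(q, "q")
  structure(list(p = as.numeric(p), q = as.numeric(q)), class = "skeleton")
}

# Internal: probabilities at a set of combos (2-col index matrix) for a
# matrix of parameter draws. Returns C x N.
model_prob_mat <- function(model, combos, theta) {
  im <- as_combo_matrix(combos)
  if (model$type == "six_param") {
    xd <- combo_doses(im, model$grid)
    sixp_prob_mat(xd[, "xa"], xd[, "xb"], theta)
  } else {
    copula_prob_mat(model$skeleton$p[im[, 1L]], model$skeleton$q[im[, 2L]],
                    theta)
  }
}

# Internal: gradient at one combo for all draws; p x N matrix.
model_grad_mat <- function(model, combo, theta) {
  im <- as_combo_matrix(combo)
  if (model$type == "six_param") {
    xd <- combo_doses(im, model$grid)
    sixp_grad_mat(xd[1, "xa"], xd[1, "xb"], theta)
  } else {
    copula_grad_mat(model$skeleton$p[im[1, 1L]], model$skeleton$q[im[1, 2L]],
                    theta)
  }
}

theta_row <- function(model, params) {
  nms <- if (model$type == "six_param") SIX_PARAM_NAMES else COPULA_NAMES
  matrix(check_params(params, nms), nrow = 1, dimnames = list(NULL, nms))
}

#' Binomial log likelihood of a trial history
#'
#' \eqn{\sum_k Y_k \log \pi(x_k) + (1-Y_k)\log(1-\pi(x_k))} under the given
#' model and parameter vector. An empty history has log likelihood 0.
#'
#' @param model a [six_param_model()] or [copula_model()].
#' @param history a [trial_history()].
#' @param params model parameter vector.
#' @return scalar log likelihood (can be `-Inf` if the model puts probability
#'   exactly 0 or 1 on an observed contradicting outcome).
#' @export
log_likelihood <- function(model, history, params) {
  if (history$n == 0L) return(0)
  th <- theta_row(model, params)
  pi_k <- drop(model_prob_mat(model, cbind(history$i, history$j), th))
  sum(ifelse(history$y == 1L, log(pi_k), log1p(-pi_k)))
}

#' Gradient of the DLT probability in the model parameters
#'
#' Analytic \eqn{\partial\pi/\partial\theta} at one dose combination. Used to
#' build the Fisher information for the D-optimality escalation rule. A
#' finite-difference evaluation is available via `method = "numeric"` and is
#' used in tests as an independent check.
#'
#' @param model a `combo_model`.
#' @param combo a [dose_combo()].
#' @param params model parameter vector (strictly positive).
#' @param method "analytic" (default) or "numeric" (central differences,
#'   relative step 1e-6).
#' @return named numeric vector, one element per model parameter.
#' @export
prob_gradient <- function(model, combo, params,
                          method = c("analytic", "numeric")) {
  method <- match.arg(method)
  th <- theta_row(model, params)
  if (method == "analytic") return(drop(model_grad_mat(model, combo, th)))
  p0 <- drop(th)
  g <- numeric(length(p0))
  for (k in seq_along(p0)) {
    h <- 1e-6 * max(abs(p0[k]), 1e-6)
    up <- p0; up[k] <- up[k] + h
    dn <- p0; dn[k] <- dn[k] - h
    g[k] <- (drop(model_prob_mat(model, combo, theta_row(model, up))) -
             drop(model_prob_mat(model, combo, theta_row(model, dn)))) / (2 * h)
  }
  names(g) <- names(p0)
  g
}

#' Single-observation Fisher information at a dose combination
#'
#' For a Bernoulli outcome with success probability \eqn{\pi(\xi,\theta)},
#' the information contributed by one patient treated at \eqn{\xi} is the
#' rank-one matrix \eqn{g g^\top / (\pi(1-\pi))} with
#' \eqn{g = \partial\pi/\partial\theta}. If \eqn{\pi} is numerically 0 or 1
#' the observation carries no usable information and a zero matrix is
#' returned with a warning.
#'
#' @inheritParams prob_gradient
#' @return symmetric positive semidefinite matrix (rank at most 1).
#' @export
fisher_information <- function(model, combo, params) {
  th <- theta_row(model, params)
  pi_x <- drop(model_prob_mat(model, combo, th))
  if (pi_x <= .Machine$double.eps || pi_x >= 1 - .Machine$double.eps) {
    warning("DLT probability numerically 0 or 1 at this combo; ",
            "information is zero", call. = FALSE)
    p <- ncol(th)
    return(matrix(0, p, p, dimnames = list(colnames(th), colnames(th))))
  }
  g <- drop(model_grad_mat(model, combo, th))
  (g %o% g) / (pi_x * (1 - pi_x))
}

#' Skeleton from the prior of the six-parameter model
#'
#' The copula model needs prespecified single-agent DLT probabilities. These
#' are obtained as the prior mean probability of DLT when each drug is used
#' in isolation, computed from the six-parameter model by Monte Carlo:
#' \eqn{p_i = E[a/(1+a)]} at \eqn{x_{Ai}} with drug B absent, and
#' symmetrically for \eqn{q_j}.
#'
#' @param prior a [prior_spec()] for the six-parameter model.
#' @param grid a [dose_grid()].
#' @param n_draws Monte Carlo sample size (>= 1000).
#' @param seed integer seed for reproducibility.
#' @return a [skeleton()].
#' @export
skeleton_from_prior <- function(prior, grid, n_draws = 1e5, seed = 1L) {
  if (n_draws < 1000) stop("n_draws must be at least 1000", call. = FALSE)
  if (!identical(prior$names, SIX_PARAM_NAMES))
    stop("prior must be a six-parameter prior", call. = FALSE)
  with_seed(seed, {
    th <- prior_draw_matrix(prior, n_draws)
    p <- rowMeans(sixp_prob_mat(grid$levels_a, rep(0, grid$I), th))
    q <- rowMeans(sixp_prob_mat(rep(0, grid$J), grid$levels_b, th))
    if (any(diff(p) <= 0) || any(diff(q) <= 0))
      stop("Monte Carlo skeleton is not strictly increasing; ",
           "increase n_draws", call. = FALSE)
    skeleton(p, q)
  })
}

# Evaluate expr with a local, restored RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
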