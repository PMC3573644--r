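#' Standardized dose grid for a two-agent trial
#'
#' The discrete dose space is the Cartesian product of I ordered standardized
#' doses of drug A and J ordered standardized doses of drug B. Doses are
#' standardized to each agent's known single-agent maximum tolerated dose, so
#' a value of 1 is that single-agent MTD and all trial doses lie in (0, 1].
#' Dose 0 is representable in the model functions (it is needed for the
#' single-agent margins and the skeleton) but is not part of the trial grid.
#'
#' @param levels_a numeric vector of standardized doses for drug A, strictly
#'   increasing, all in (0, 1].
#' @param levels_b numeric vector of standardized doses for drug B, strictly
#'   increasing, all in (0, 1].
#' @return An object of class `dose_grid` with elements `levels_a`,
#'   `levels_b`, `I`, `J`.
#' @examples
#' g <- dose_grid(c(0.2, 0.5, 0.7, 0.8, 0.9, 0.95),
#'                c(0.2, 0.5, 0.7, 0.8, 0.9, 0.95))
#' g$I
#' @export
dose_grid <- function(levels_a, levels_b) {
  check_levels <- function(x, nm) {
    if (!is.numeric(x) || length(x) < 1L)
      stop(nm, " must be a non-empty numeric vector", call. = FALSE)
    if (any(!is.finite(x)) || any(x <= 0) || any(x > 1))
      stop(nm, " must lie in (0, 1]", call. = FALSE)
    if (length(x) > 1L && any(diff(x) <= 0))
      stop(nm, " must be strictly increasing", call. = FALSE)
  }
  check_levels(levels_a, "levels_a")
  check_levels(levels_b, "levels_b")
  structure(
    list(levels_a = as.numeric(levels_a), levels_b = as.numeric(levels_b),
         I = length(levels_a), J = length(levels_b)),
    class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("Two-agent dose grid (", x$I, " x ", x$J, ")\n", sep = "")
  cat("  drug A:", paste(x$levels_a, collapse = ", "), "\n")
  cat("  drug B:", paste(x$levels_b, collapse = ", "), "\n")
  invisible(x)
}

#' Dose-combination index pair
#'
#' A dose combination is identified by the 1-based level indices (i, j) of
#' drug A and drug B within a [dose_grid()].
#'
#' @param i level index of drug A (1..I).
#' @param j level index of drug B (1..J).
#' @param grid optional `dose_grid`; if supplied, indices are range-checked.
#' @return Object of class `dose_combo`: a named integer vector with elements
#'   `i` and `j`.
#' @export
dose_combo <- function(i, j, grid = NULL) {
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != 1L || length(j) != 1L || is.na(i) || is.na(j) ||
      i < 1L || j < 1L)
    stop("combo indices must be single positive integers", call. = FALSE)
  if (!is.null(grid)) {
    if (i > grid$I || j > grid$J)
      stop("combo (", i, ",", j, ") outside the ", grid$I, "x", grid$J,
           " grid", call. = FALSE)
  }
  structure(c(i = i, j = j), class = "dose_combo")
}

#' @export
print.dose_combo <- function(x, ...) {
  cat("dose combo (i = ", x[["i"]], ", j = ", x[["j"]], ")\n", sep = "")
  invisible(x)
}

# Internal: combos as a 2-column integer matrix (one row per combo).
as_combo_matrix <- function(combos) {
  if (inherits(combos, "dose_combo")) combos <- list(combos)
  if (is.matrix(combos)) {
    storage.mode(combos) <- "integer"
    colnames(combos) <- c("i", "j")
    return(combos)
  }
  out <- matrix(0L, nrow = length(combos), ncol = 2L,
                dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(combos)) out[k, ] <- as.integer(combos[[k]][c(1L, 2L)])
  out
}

# Internal: linear index i + (j-1)*I for fast tabulation.
combo_lin <- function(im, grid) im[, 1L] + (im[, 2L] - 1L) * grid$I

#' Standardized doses of a combination
#'
#' @param combo a [dose_combo()] (or 2-column matrix of index pairs).
#' @param grid a [dose_grid()].
#' @return numeric matrix with columns `xa`, `xb`.
#' @export
combo_doses <- function(combo, grid) {
  im <- as_combo_matrix(combo)
  if (any(im[, 1L] < 1L) || any(im[, 1L] > grid$I) ||
      any(im[, 2L] < 1L) || any(im[, 2L] > grid$J))
    stop("combo indices outside grid bounds", call. = FALSE)
  cbind(xa = grid$levels_a[im[, 1L]], xb = grid$levels_b[im[, 2L]])
}

#' Trial history of dose assignments and toxicity outcomes
#'
#' Ordered per-patient records of the administered dose combination and the
#' binary dose-limiting-toxicity (DLT) outcome. The set of distinct
#' combinations that appear is the experimented set used by the
#' previously-experimented escalation strategy and by Phase II selection.
#'
#' @param i,j integer vectors of 1-based level indices (recycled against each
#'   other must be equal length).
#' @param y binary DLT indicators (0/1), same length.
#' @param grid optional `dose_grid` for bound checking.
#' @return Object of class `trial_history`: list with integer vectors `i`,
#'   `j`, `y` and `n` (number of patients).
#' @export
trial_history <- function(i = integer(), j = integer(), y = integer(),
                          grid = NULL) {
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != length(j) || length(i) != length(y))
    stop("i, j and y must have equal length", call. = FALSE)
  if (any(!y %in% c(0, 1)))
    stop("outcomes y must be 0 or 1", call. = FALSE)
  if (length(i) && (any(i < 1L) | any(j < 1L)))
    stop("combo indices must be >= 1", call. = FALSE)
  if (!is.null(grid) && length(i) &&
      (any(i > grid$I) || any(j > grid$J)))
    stop("history contains combos outside the grid", call. = FALSE)
  structure(list(i = i, j = j, y = as.integer(y), n = length(i)),
            class = "trial_history")
}

#' Append one cohort to a trial history
#' @param history a [trial_history()].
#' @param combo the treated [dose_combo()].
#' @param y vector of 0/1 outcomes for the cohort.
#' @return updated `trial_history`.
#' @export
history_append <- function(history, combo, y) {
  trial_history(c(history$i, rep(combo[["i"]], length(y))),
                c(history$j, rep(combo[["j"]], length(y))),
                c(history$y, y))
}

#' Experimented dose combinations
#'
#' Distinct dose combinations appearing in a trial history, in order of first
#' administration.
#'
#' @param history a [trial_history()].
#' @return 2-column integer matrix (columns `i`, `j`), one row per distinct
#'   combination.
#' @export
experimented_set <- function(history) {
  if (history$n == 0L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  keep <- !duplicated(paste(history$i, history$j))
  cbind(i = history$i[keep], j = history$j[keep])
}

#' @export
print.trial_history <- function(x, ...) {
  cat("trial history:", x$n, "patients,", sum(x$y), "DLTs,",
      nrow(experimented_set(x)), "distinct combos\n")
  invisible(x)
}
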