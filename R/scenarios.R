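#' True-toxicity scenarios
#'
#' A scenario is the simulation ground truth: the matrix of true DLT
#' probabilities at every grid combination. Four scenarios are packaged,
#' matching the study the packaged defaults emulate:
#' \describe{
#'   \item{scenario1}{"in agreement with prior": truth equals the prior mean
#'     surface of the six-parameter model; four MTDs.}
#'   \item{scenario2}{"toxic": truth rises steeply above the MTD contour; a
#'     one-level increase of either drug from any of the five MTDs jumps the
#'     DLT probability to 0.45.}
#'   \item{scenario3}{"asymmetric toxic": drug A more toxic than presumed;
#'     four MTDs.}
#'   \item{scenario4}{"flat": DLT probability ranges only 0.19 to 0.415;
#'     nine MTDs.}
#' }
#'
#' @param name one of "scenario1".."scenario4".
#' @param true_prob I x J matrix of DLT probabilities, rows = drug-A levels,
#'   columns = drug-B levels, non-decreasing along each axis.
#' @param grid the [dose_grid()] the matrix refers to.
#' @return object of class `scenario` with elements `name`, `true_prob`,
#'   `grid`.
#' @export
scenario <- function(name, true_prob, grid = default_grid()) {
  true_prob <- as.matrix(true_prob)
  if (nrow(true_prob) != grid$I || ncol(true_prob) != grid$J)
    stop("scenario matrix must be ", grid$I, " x ", grid$J, call. = FALSE)
  if (any(true_prob <= 0) || any(true_prob >= 1))
    stop("true probabilities must lie in (0, 1)", call. = FALSE)
  if (any(apply(true_prob, 2, diff) < 0) ||
      any(apply(true_prob, 1, diff) < 0))
    stop("true probabilities must be non-decreasing in each dose",
         call. = FALSE)
  dimnames(true_prob) <- list(grid$levels_a, grid$levels_b)
  structure(list(name = name, true_prob = true_prob, grid = grid),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("scenario:", x$name, "\n")
  print(x$true_prob)
  invisible(x)
}

#' Packaged scenarios
#'
#' @param name scenario name; see [scenario()]. `packaged_scenarios()` lists
#'   the available names.
#' @return a [scenario()] object.
#' @export
packaged_scenario <- function(name = packaged_scenarios()) {
  name <- match.arg(name)
  # columns = drug-B levels 0.2 .. 0.95, rows (after byrow fill) = drug-A
  m <- switch(name,
    scenario1 = c(0.02, 0.03, 0.06, 0.11, 0.18, 0.23,
                  0.03, 0.05, 0.09, 0.14, 0.21, 0.27,
                  0.06, 0.09, 0.14, 0.18, 0.26, 0.30,
                  0.10, 0.13, 0.18, 0.23, 0.30, 0.36,
                  0.18, 0.21, 0.26, 0.30, 0.39, 0.44,
                  0.23, 0.27, 0.30, 0.36, 0.44, 0.49),
    scenario2 = c(0.02, 0.03, 0.06, 0.11, 0.18, 0.23,
                  0.03, 0.05, 0.09, 0.14, 0.21, 0.30,
                  0.06, 0.09, 0.14, 0.18, 0.30, 0.45,
                  0.10, 0.13, 0.18, 0.30, 0.45, 0.50,
                  0.18, 0.21, 0.30, 0.45, 0.50, 0.55,
                  0.23, 0.30, 0.45, 0.50, 0.55, 0.60),
    scenario3 = c(0.02, 0.06, 0.12, 0.17, 0.22, 0.30,
                  0.10, 0.14, 0.20, 0.25, 0.30, 0.38,
                  0.20, 0.24, 0.30, 0.35, 0.40, 0.48,
                  0.30, 0.34, 0.40, 0.45, 0.50, 0.58,
                  0.35, 0.39, 0.45, 0.50, 0.60, 0.68,
                  0.45, 0.49, 0.55, 0.60, 0.70, 0.78),
    scenario4 = c(0.190, 0.205, 0.220, 0.235, 0.250, 0.265,
                  0.220, 0.235, 0.250, 0.265, 0.280, 0.295,
                  0.250, 0.265, 0.280, 0.295, 0.310, 0.325,
                  0.280, 0.295, 0.310, 0.325, 0.340, 0.355,
                  0.310, 0.325, 0.340, 0.355, 0.370, 0.385,
                  0.340, 0.355, 0.370, 0.385, 0.400, 0.415))
  scenario(name, matrix(m, nrow = 6, ncol = 6, byrow = TRUE))
}

#' @rdname packaged_scenario
#' @export
packaged_scenarios <- function() {
  c("scenario1", "scenario2", "scenario3", "scenario4")
}

#' Read a scenario from a CSV file
#'
#' The expected layout mirrors the packaged files under
#' `system.file("extdata", package = "combodose")`: a header row naming the
#' drug-A dose levels, a first column `drug_b` with the drug-B levels
#' (increasing), and DLT probabilities in the body.
#'
#' @param path CSV file path.
#' @param name scenario name (defaults to the file name).
#' @param grid the [dose_grid()] to validate against.
#' @return a [scenario()] object.
#' @export
read_scenario <- function(path, name = NULL,
                          grid = default_grid()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "drug_b")
    stop("scenario file must have a first column named 'drug_b'",
         call. = FALSE)
  bj <- as.numeric(df[[1]])
  ai <- as.numeric(names(df)[-1])
  if (length(ai) != grid$I || length(bj) != grid$J ||
      max(abs(ai - grid$levels_a)) > 1e-8 ||
      max(abs(bj - grid$levels_b)) > 1e-8)
    stop("scenario file levels do not match the grid", call. = FALSE)
  m <- t(as.matrix(df[, -1]))   # rows drug-A, columns drug-B
  scenario(if (is.null(name)) sub("\\.csv$", "", basename(path)) else name,
           m, grid)
}

#' Write a scenario to CSV (the same layout [read_scenario()] accepts)
#' @param x a [scenario()].
#' @param path output file path.
#' @export
write_scenario <- function(x, path) {
  df <- cbind(drug_b = x$grid$levels_b,
              as.data.frame(t(x$true_prob), check.names = FALSE))
  names(df)[-1] <- x$grid$levels_a
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' True maximum tolerated dose combinations of a scenario
#'
#' A combination is a true MTD if its true DLT probability lies strictly
#' within `epsilon` of the target toxicity level: |p - ttl| < epsilon. On a
#' two-drug surface there are typically several.
#'
#' @param scen a [scenario()].
#' @param ttl target toxicity level.
#' @param epsilon tolerance (strict).
#' @return 2-column integer matrix of MTD combos.
#' @export
true_mtd_set <- function(scen, ttl = 0.30, epsilon = 0.025) {
  idx <- which(abs(scen$true_prob - ttl) < epsilon, arr.ind = TRUE)
  out <- cbind(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' Toxicity band of a DLT probability
#'
#' Half-open bands used for the operating-characteristics tables:
#' severe underdosing \[0, 0.15), underdosing \[0.15, 0.25), target dosing
#' \[0.25, 0.35), overdosing \[0.35, 0.45), severe overdosing \[0.45, 1\].
#'
#' @param prob vector of probabilities in \[0, 1\].
#' @return factor with levels `severe_under`, `under`, `target`, `over`,
#'   `severe_over`.
#' @export
classify_band <- function(prob) {
  if (any(prob < 0 | prob > 1)) stop("prob must be in [0, 1]", call. = FALSE)
  k <- findInterval(prob, c(0.15, 0.25, 0.35, 0.45)) + 1L
  factor(band_levels()[k], levels = band_levels())
}

band_levels <- function() {
  c("severe_under", "under", "target", "over", "severe_over")
}
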