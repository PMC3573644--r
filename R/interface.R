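# Configuration files, command-line entry points, and run manifests.

#' Read a trial configuration file
#'
#' YAML configuration with blocks `grid` (ordered dose lists `drug_a`,
#' `drug_b`), `priors` (per-parameter `{mean, variance}` blocks under
#' `six_param` and `copula`), `trial` (ttl, epsilon, cohort_size, n_cohorts,
#' start, model, rule, omega) and `posterior` (n_draws, n_info_draws,
#' min_ess, skeleton_draws, skeleton_seed). The packaged default is at
#' `system.file("extdata", "default_config.yaml", package = "combodose")`.
#'
#' @param path YAML file path; `NULL` loads the packaged default.
#' @return list with elements `grid` ([dose_grid()]), `config`
#'   ([trial_config()]), `model` (a `combo_model` built per the `trial`
#'   block), `priors` (both [prior_spec()]s), `raw` (the parsed YAML).
#' @export
read_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_config.yaml",
                        package = "combodose")
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  need <- function(block, field = NULL) {
    x <- raw[[block]]
    if (is.null(x)) stop("config is missing block '", block, "'",
                         call. = FALSE)
    if (is.null(field)) return(x)
    if (is.null(x[[field]]))
      stop("config is missing field '", block, ".", field, "'",
           call. = FALSE)
    x[[field]]
  }
  grid <- dose_grid(as.numeric(need("grid", "drug_a")),
                    as.numeric(need("grid", "drug_b")))
  pr_block <- function(nm, nms) {
    pb <- need("priors", nm)
    missing <- setdiff(nms, names(pb))
    if (length(missing))
      stop("config priors.", nm, " is missing parameter(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    prior_spec(vapply(pb[nms], function(z) as.numeric(z$mean), 0),
               vapply(pb[nms], function(z) as.numeric(z$variance), 0))
  }
  p6 <- pr_block("six_param", SIX_PARAM_NAMES)
  p3 <- pr_block("copula", COPULA_NAMES)
  tr <- need("trial")
  po <- raw$posterior
  config <- trial_config(
    ttl = tr$ttl %||% 0.30, epsilon = tr$epsilon %||% 0.025,
    cohort_size = tr$cohort_size %||% 2, n_cohorts = tr$n_cohorts %||% 20,
    start = as.integer(tr$start %||% c(1, 1)),
    rule = tr$rule %||% "d1", omega = tr$omega %||% "omega1",
    n_draws = po$n_draws %||% 5000,
    n_info_draws = po$n_info_draws %||% 128,
    min_ess = po$min_ess %||% 50)
  model_id <- tr$model %||% "six_param"
  if (!model_id %in% c("six_param", "copula"))
    stop("config field 'trial.model' must be six_param or copula",
         call. = FALSE)
  model <- build_model(model_id, grid, p6, p3,
                       skeleton_draws = po$skeleton_draws %||% 1e5,
                       skeleton_seed = po$skeleton_seed %||% 1L)
  list(grid = grid, config = config, model = model,
       priors = list(six_param = p6, copula = p3), raw = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The copula skeleton is always derived from the six-parameter prior's
# single-agent margins, mirroring how a combination trial would anchor the
# CRM-type model to the same elicited prior information.
build_model <- function(model_id, grid, p6, p3, skeleton_draws = 1e5,
                        skeleton_seed = 1L) {
  if (model_id == "six_param") return(six_param_model(grid, p6))
  sk <- skeleton_from_prior(p6, grid, n_draws = skeleton_draws,
                            seed = skeleton_seed)
  copula_model(grid, sk, p3)
}

#' Read a trial history file
#'
#' Three-column delimited text (comma or whitespace): drug-A level index,
#' drug-B level index (both 1-based), DLT indicator 0/1. A header line is
#' optional.
#'
#' @param path file path.
#' @param grid a [dose_grid()] used to validate indices.
#' @return a [trial_history()].
#' @export
read_history <- function(path, grid) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && grepl("[A-Za-z]", lines[1])) lines <- lines[-1]
  if (!length(lines)) return(trial_history())
  parts <- strsplit(lines, "[,[:space:]]+")
  for (ln in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[ln]]))
    if (length(v) != 3L || any(is.na(v)))
      stop("malformed history row at line ", ln, ": '", lines[ln], "'",
           call. = FALSE)
    if (v[1] < 1 || v[1] > grid$I || v[2] < 1 || v[2] > grid$J)
      stop("history row at line ", ln, " has a combo outside the ",
           grid$I, "x", grid$J, " grid", call. = FALSE)
    if (!v[3] %in% c(0, 1))
      stop("history row at line ", ln, " has a non-binary outcome",
           call. = FALSE)
  }
  m <- do.call(rbind, lapply(parts, as.numeric))
  trial_history(m[, 1], m[, 2], m[, 3], grid)
}

#' Run a simulation study from a configuration file
#'
#' Loads the configuration, runs [run_study()] on the requested scenario and
#' writes the operating characteristics as CSV files plus a JSON run
#' manifest into `out_dir`. Identical invocations produce byte-identical
#' outputs.
#'
#' @param config_path YAML config path (`NULL` for the packaged default).
#' @param scenario_name a packaged scenario name ("scenario1".."scenario4")
#'   or a path to a scenario CSV file.
#' @param n_sims number of simulated trials.
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @param model,rule,omega optional overrides of the config's `trial` block.
#' @param verbose print progress every 50 simulations.
#' @return (invisibly) the `operating_characteristics` object.
#' @export
cli_simulate <- function(config_path = NULL, scenario_name = "scenario1",
                         n_sims = 1000, seed = 1L, out_dir = ".",
                         model = NULL, rule = NULL, omega = NULL,
                         verbose = TRUE) {
  cfg <- read_config(config_path)
  if (!is.null(rule)) cfg$config$rule <- match.arg(rule, c("d1", "d2"))
  if (!is.null(omega))
    cfg$config$omega <- match.arg(omega, c("omega1", "omega2", "omega3"))
  if (!is.null(model)) {
    model <- match.arg(model, c("six_param", "copula"))
    po <- cfg$raw$posterior
    cfg$model <- build_model(model, cfg$grid, cfg$priors$six_param,
                             cfg$priors$copula,
                             skeleton_draws = po$skeleton_draws %||% 1e5,
                             skeleton_seed = po$skeleton_seed %||% 1L)
  }
  scen <- if (file.exists(scenario_name)) {
    read_scenario(scenario_name, grid = cfg$grid)
  } else if (scenario_name %in% packaged_scenarios()) {
    packaged_scenario(scenario_name)
  } else {
    stop("unknown scenario '", scenario_name, "'; packaged scenarios: ",
         paste(packaged_scenarios(), collapse = ", "), call. = FALSE)
  }
  oc <- run_study(cfg$model, scen, cfg$config, n_sims = n_sims, seed = seed,
                  verbose = verbose)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_oc(oc, out_dir)
  manifest <- list(
    tool = "combodose",
    version = as.character(utils::packageVersion("combodose")),
    scenario = scen$name, n_sims = n_sims, master_seed = seed,
    model = cfg$model$type, rule = cfg$config$rule,
    omega = cfg$config$omega,
    ttl = cfg$config$ttl, epsilon = cfg$config$epsilon,
    cohort_size = cfg$config$cohort_size, n_cohorts = cfg$config$n_cohorts,
    n_draws = cfg$config$n_draws,
    recommendation_denominator = "pooled over recommended doses; trials with an empty recommendation set excluded (rate reported as pct_empty_rpii)",
    outputs = c("experimentation_bands.csv", "recommendation_bands.csv",
                "mtd_selection.csv", "patient_mean_toxicity.csv"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(oc)
}

write_oc <- function(oc, out_dir) {
  bands <- data.frame(band = band_levels(),
                      percent = unname(oc$experimentation_pct))
  utils::write.csv(bands, file.path(out_dir, "experimentation_bands.csv"),
                   row.names = FALSE, quote = FALSE)
  bands$percent <- unname(oc$recommendation_pct)
  utils::write.csv(bands, file.path(out_dir, "recommendation_bands.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(pct_mtd_selected = oc$pct_mtd_selected,
               pct_empty_rpii = oc$pct_empty_rpii,
               n_recommended = oc$n_recommended, n_sims = oc$n_sims),
    file.path(out_dir, "mtd_selection.csv"), row.names = FALSE,
    quote = FALSE)
  utils::write.csv(
    data.frame(patient = seq_along(oc$mean_tox_by_patient),
               mean_true_toxicity = oc$mean_tox_by_patient),
    file.path(out_dir, "patient_mean_toxicity.csv"), row.names = FALSE,
    quote = FALSE)
  invisible(out_dir)
}

#' Next-dose recommendation for a live trial
#'
#' Reads an ongoing trial's history, updates the posterior under the
#' configured model, prints the admissible set, the posterior-mean surface,
#' the next recommended combination under the configured rule, and the
#' current (interim) Phase II recommendation set. With an empty history the
#' protocol start combination is recommended.
#'
#' @param history_path history file (see [read_history()]).
#' @param config_path YAML config path (`NULL` for the packaged default).
#' @param seed seed for the posterior computation.
#' @return (invisibly) a list with `next_combo`, `admissible`, `surface`,
#'   `rpii`.
#' @export
cli_recommend <- function(history_path, config_path = NULL, seed = 1L) {
  cfg <- read_config(config_path)
  history <- read_history(history_path, cfg$grid)
  if (history$n == 0L) {
    nxt <- dose_combo(cfg$config$start[1], cfg$config$start[2], cfg$grid)
    cat("empty history: recommending the protocol start combination\n")
    print(nxt)
    return(invisible(list(next_combo = nxt,
                          admissible = as_combo_matrix(list(nxt)),
                          surface = NULL,
                          rpii = matrix(integer(), ncol = 2))))
  }
  draws <- posterior_draws(cfg$model, history, n_draws = cfg$config$n_draws,
                           seed = seed)
  surface <- posterior_mean_surface(draws, cfg$model)
  current <- dose_combo(history$i[history$n], history$j[history$n],
                        cfg$grid)
  adm <- admissible_set(current, cfg$grid, cfg$config$omega, history)
  nxt <- if (cfg$config$rule == "d1") {
    choose_next_D1(adm, surface, cfg$config$ttl, cfg$grid)
  } else {
    choose_next_D2(adm, surface, draws, cfg$model, history,
                   cfg$config$ttl, cfg$config$epsilon)
  }
  rpii <- rpii_set(history, surface, cfg$config$ttl, cfg$config$epsilon)
  cat("history:", history$n, "patients,", sum(history$y), "DLTs\n")
  cat("admissible set (", cfg$config$omega, "): ",
      paste0("(", adm[, 1L], ",", adm[, 2L], ")", collapse = " "), "\n",
      sep = "")
  cat("posterior mean DLT surface:\n")
  print(round(surface, 3))
  cat("next recommended combination (rule ", cfg$config$rule, "): (",
      nxt[["i"]], ",", nxt[["j"]], ")\n", sep = "")
  cat("interim Phase II recommendation set: ",
      if (nrow(rpii) == 0L) "empty" else
        paste0("(", rpii[, 1L], ",", rpii[, 2L], ")", collapse = " "),
      "\n", sep = "")
  invisible(list(next_combo = nxt, admissible = adm, surface = surface,
                 rpii = rpii))
}
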