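#' Run configuration
#'
#' A flat key-value configuration covering model parameters (defaulting to the
#' reference parameter set), initial conditions, experiment settings and
#' variant switches. Serializes losslessly to YAML or JSON; unknown keys are
#' rejected by name.
#'
#' @param ... Overrides of the default fields (see [config_defaults()]).
#' @return An object of class `"run_config"` (a named list).
#' @examples
#' cfg <- run_config(alpha = 1e-6, reps = 10)
#' cfg$g
#' @export
run_config <- function(...) {
  defaults <- config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @export
config_defaults <- function() {
  list(
    alpha = 1e-5, mu = 3.4e-7, g = 0.44, K = 1e11, n_s = 100L,
    beta = 1e-6, b_wt = 190, b_m = 179, propensity = 0,
    S0 = 6e6, P0 = 1e5,
    competition = FALSE, S1 = 3e6, S2 = 3e6,
    alpha_b = 1e-5, mu_b = 3.4e-7, propensity_b = 0,
    reps = 100L, seed = 1L, t_max = 150, method = "tau_leap",
    record_dt = 0.5, all_mutant_progeny = FALSE)
}

validate_config <- function(cfg) {
  validate_params(crispr_params(alpha = cfg$alpha, mu = cfg$mu, g = cfg$g,
                                K = cfg$K, n_s = cfg$n_s, beta = cfg$beta,
                                b_wt = cfg$b_wt, b_m = cfg$b_m,
                                propensity = cfg$propensity))
  if (!cfg$method %in% c("tau_leap", "exact"))
    stop("method must be 'tau_leap' or 'exact', got '", cfg$method, "'")
  for (f in c("S0", "P0", "S1", "S2", "reps", "t_max"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop("configuration field '", f, "' must be a non-negative number")
  invisible(cfg)
}

#' Read and write run configurations
#'
#' `load_config()` reads a YAML (or JSON, by extension) key-value file and
#' returns a validated [run_config()]; omitted keys take their defaults and
#' unknown keys are rejected by name. `write_config()` writes one back so that
#' `load_config(write_config(cfg))` round-trips.
#'
#' @param path File path (`.yml`/`.yaml` or `.json`).
#' @param cfg A [run_config()].
#' @return `load_config()`: a `"run_config"`; `write_config()`: `path`,
#'   invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(run_config, raw)
}

#' @rdname load_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Write experiment results to disk
#'
#' Writes the per-replicate records as a tidy CSV and the summary (with the
#' configuration and master seed that produced it) as JSON.
#'
#' @param result A result list from one of the experiment runners (must carry
#'   a `records` tibble; other scalar elements go into the JSON summary).
#' @param path Output path stem; `<path>.csv` and `<path>.json` are written.
#' @param cfg Optional [run_config()] embedded in the summary.
#' @return The two file paths, invisibly.
#' @export
write_results <- function(result, path, cfg = NULL) {
  csv <- paste0(path, ".csv")
  js <- paste0(path, ".json")
  records <- if (is.data.frame(result)) result
             else if (!is.null(result$records)) result$records
             else stop("result carries no records to write")
  utils::write.csv(records, csv, row.names = FALSE)
  summary <- result[setdiff(names(result), c("records", "fitness"))]
  if (is.data.frame(result)) summary <- list(rows = nrow(result))
  if (!is.null(cfg)) summary$config <- unclass(cfg)
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(c(csv = csv, json = js))
}

#' Write a trajectory to disk
#'
#' Writes the sampled states as a tidy CSV (`time`, `strain`, `species`,
#' `count`) and a JSON summary: termination cause, final counts per species
#' group, peak free phage and the S-extinction snapshot(s).
#'
#' @param traj A `"trajectory"` from [simulate_outbreak()].
#' @param path Output path stem; `<path>.csv` and `<path>.json` are written.
#' @return The two file paths, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  csv <- paste0(path, ".csv")
  js <- paste0(path, ".json")
  utils::write.csv(as.data.frame(traj), csv, row.names = FALSE)
  fs <- traj$final_state
  snap <- lapply(traj$s_extinction, function(sn) {
    if (is.null(sn)) NULL
    else list(t = sn$t, S = sn$state$S, R_total = rowSums(sn$state$R),
              P_wt = sn$state$P_wt, P_esc_total = sum(sn$state$P_esc))
  })
  summary <- list(
    termination = traj$termination,
    t_final = fs$t,
    final = list(S = fs$S, R_total = rowSums(fs$R), P_wt = fs$P_wt,
                 P_esc_total = sum(fs$P_esc)),
    peak_phage = traj$peak_phage,
    s_extinction = snap)
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(csv = csv, json = js))
}

#' Miniature deterministic fixtures for tests and examples
#'
#' `"mini-system"` returns a scaled-down parameter set and initial state
#' (carrying capacity 1e4, 5 protospacers, amplified infectivity) on which the
#' exact and tau-leaping methods are both practical; `"toy-fasta"` writes a
#' small deterministic FASTA file and returns its path.
#'
#' @param kind `"mini-system"` or `"toy-fasta"`.
#' @param seed Seed controlling the toy FASTA content.
#' @param dir Directory for file-producing fixtures.
#' @return For `"mini-system"`, a list with `params` and `init`; for
#'   `"toy-fasta"`, a file path.
#' @export
make_fixture <- function(kind = c("mini-system", "toy-fasta"), seed = 1,
                         dir = tempdir()) {
  kind <- match.arg(kind)
  if (kind == "mini-system") {
    params <- crispr_params(alpha = 0.02, mu = 0.004, g = 0.44, K = 1e4,
                            n_s = 5L, beta = 1e-3, b_wt = 10, b_m = 8,
                            propensity = 0, type_iii = FALSE)
    list(params = params, init = model_state(S = 500, P_wt = 50, n_s = 5L))
  } else {
    set.seed(seed)
    n <- 40L
    seqs <- vapply(1:3, function(i)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      "")
    path <- file.path(dir, sprintf("toy_%d.fasta", seed))
    writeLines(c(rbind(sprintf(">toy_%d synthetic", 1:3), seqs)), path)
    path
  }
}
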