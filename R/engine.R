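#' Simulate the reaction network forward in time
#'
#' Realizes the continuous-time Markov chain defined by a
#' [build_reaction_network()] either with the exact Gillespie stochastic
#' simulation algorithm (`method = "exact"`, implemented in R, practical for
#' small systems) or with adaptive tau-leaping (`method = "tau_leap"`, the
#' compiled production path at realistic population sizes). The tau-leap uses
#' the standard species-relative error control (`eps`, default 0.03) with a
#' critical-reaction partition: any channel whose reactants could be exhausted
#' within `n_critical` firings is excluded from the leap and fired one event
#' at a time, exact steps replace leaps that would advance fewer than a
#' handful of events, and a leap that would drive a count negative is rolled
#' back and redrawn with a halved step — no trajectory ever contains a
#' negative count.
#'
#' The state is recorded every `record_dt` hours (zero-order hold on the
#' sampling grid), plus at termination and at the instant each strain's
#' sensitive population first hits exact zero. The run stops early when every
#' phage count is zero or every bacterial count is zero: with no phage decay
#' in the model, a phage population without hosts is frozen, so in both cases
#' no further dynamics of interest remain.
#'
#' @param net A [build_reaction_network()].
#' @param init Initial [model_state()].
#' @param t_max End time in hours (default 150).
#' @param seed Integer seed; identical seed, method and inputs give an
#'   identical trajectory.
#' @param method `"tau_leap"` or `"exact"`.
#' @param record_dt Sampling interval (hours).
#' @param eps Tau-leap relative error-control parameter.
#' @param n_critical Criticality threshold (firings to reactant exhaustion).
#' @param stop_on_phage_extinction If `TRUE` (default) the run ends as soon
#'   as every phage count is zero. Set to `FALSE` when the post-clearance
#'   bacterial dynamics are the readout (e.g. competition fitness at the
#'   horizon, or no-phage controls). Bacterial extinction always stops the
#'   run: without hosts the phage population is frozen.
#'
#' @return An object of class `"trajectory"`: `$times`, `$states` (species x
#'   samples matrix), `$termination` (one of `"time_limit"`,
#'   `"phage_extinct"`, `"bacteria_extinct"`, `"all_extinct"`),
#'   `$final_state`, `$peak_phage` (running maximum of total free phage),
#'   `$s_extinction` (per strain: time and state snapshot when S first hit 0,
#'   or NULL).
#' @examples
#' net <- build_reaction_network(crispr_params(alpha = 0.05, mu = 0, n_s = 5,
#'                                             K = 1e4, beta = 1e-3,
#'                                             b_wt = 10, b_m = 8))
#' tr <- simulate_outbreak(net, model_state(S = 500, P_wt = 50, n_s = 5),
#'                         t_max = 20, seed = 1, method = "exact")
#' tr$termination
#' @export
simulate_outbreak <- function(net, init, t_max = 150, seed = NULL,
                              method = c("tau_leap", "exact"),
                              record_dt = 0.5, eps = 0.03, n_critical = 10,
                              stop_on_phage_extinction = TRUE) {
  method <- match.arg(method)
  if (!inherits(init, "model_state")) stop("init must be a model_state")
  if (init$n_strains != net$n_strains || init$n_s != net$n_s)
    stop("initial state does not match the network dimensions")
  if (t_max <= 0) stop("t_max must be positive")
  if (!is.null(seed)) set.seed(seed)

  if (method == "tau_leap") {
    raw <- .cpp_simulate(net$compact, pack_state(init), init$t, t_max,
                         record_dt, eps, n_critical,
                         isTRUE(stop_on_phage_extinction))
    x <- raw$x
    t <- raw$t
    rec_t <- raw$times
    rec_x <- raw$states
    s_ext <- lapply(raw$s_extinction, function(sn) {
      if (is.null(sn)) NULL
      else list(t = sn$t, state = unpack_state(sn$x, net$n_strains, net$n_s,
                                               t = sn$t))
    })
    peak_phage <- raw$peak_phage
  } else {
    raw <- ssa_exact(net, pack_state(init), init$t, t_max, record_dt,
                     isTRUE(stop_on_phage_extinction))
    x <- raw$x
    t <- raw$t
    rec_t <- raw$times
    rec_x <- raw$states
    s_ext <- raw$s_extinction
    peak_phage <- raw$peak_phage
  }

  bact_idx <- c(net$iS, as.vector(net$iR))
  phage_idx <- c(net$iP, net$iE)
  phage_left <- sum(x[phage_idx]) > 0
  bact_left <- sum(x[bact_idx]) > 0
  termination <- if (!phage_left && !bact_left) "all_extinct"
  else if (!phage_left) "phage_extinct"
  else if (!bact_left) "bacteria_extinct"
  else "time_limit"

  out <- list(times = rec_t,
              states = rec_x,
              species = net$species,
              n_strains = net$n_strains, n_s = net$n_s,
              termination = termination,
              final_state = unpack_state(x, net$n_strains, net$n_s, t = t),
              peak_phage = peak_phage,
              s_extinction = s_ext)
  class(out) <- "trajectory"
  out
}

# exact Gillespie loop in plain R; the independent counterpart of the
# compiled tau-leap path (shares only the network structure with it)
ssa_exact <- function(net, x, t, t_max, record_dt, stop_on_phage_extinction) {
  n_sp <- net$n_species
  bact_idx <- c(net$iS, as.vector(net$iR))
  phage_idx <- c(net$iP, net$iE)
  # per-channel dense update lists for fast application
  upd <- net$compact
  rec_t <- numeric(512); rec_x <- matrix(0, n_sp, 512); n_rec <- 0L
  push <- function(tt, xx) {
    if (n_rec == length(rec_t)) {
      rec_t <<- c(rec_t, numeric(length(rec_t)))
      rec_x <<- cbind(rec_x, matrix(0, n_sp, ncol(rec_x)))
    }
    n_rec <<- n_rec + 1L
    rec_t[n_rec] <<- tt
    rec_x[, n_rec] <<- xx
  }
  push(t, x)
  next_rec <- t + record_dt
  peak_phage <- sum(x[phage_idx])
  s_ext <- vector("list", net$n_strains)
  s_alive <- x[net$iS] > 0

  repeat {
    a <- rates_vec(net, x)
    if (any(!is.finite(a))) stop("non-finite channel rate at t = ", t)
    a0 <- sum(a)
    if (a0 <= 0 || t >= t_max) { t <- t_max; break }
    dt <- stats::rexp(1L, a0)
    if (t + dt > t_max) { t <- t_max; break }
    t <- t + dt
    while (next_rec <= t && next_rec <= t_max) {
      push(next_rec, x)   # hold the pre-event state on the grid
      next_rec <- next_rec + record_dt
    }
    j <- sample.int(net$n_channels, 1L, prob = a)
    span <- (upd$up_start[j] + 1L):upd$up_start[j + 1L]
    idx <- upd$up_idx[span] + 1L
    x[idx] <- x[idx] + upd$up_val[span]

    peak_phage <- max(peak_phage, sum(x[phage_idx]))
    hit <- which(s_alive & x[net$iS] == 0)
    for (s in hit) {
      s_alive[s] <- FALSE
      s_ext[[s]] <- list(t = t, state = unpack_state(x, net$n_strains,
                                                     net$n_s, t = t))
    }
    if ((all(x[phage_idx] == 0) && stop_on_phage_extinction) ||
        all(x[bact_idx] == 0)) break
  }

  while (next_rec <= t && next_rec <= t_max) {
    push(next_rec, x)
    next_rec <- next_rec + record_dt
  }
  if (t > rec_t[n_rec]) push(t, x)
  list(times = rec_t[seq_len(n_rec)],
       states = rec_x[, seq_len(n_rec), drop = FALSE],
       t = t, x = x, peak_phage = peak_phage, s_extinction = s_ext)
}

#' Deterministic mean-field reference trajectory
#'
#' Integrates the mean-field ordinary differential equations implied by the
#' reaction network (the stoichiometry matrix applied to the rate laws,
#' evaluated on a continuous state). Used as a validation oracle for the
#' stochastic engine at large population sizes, not as a production path.
#'
#' @param net A [build_reaction_network()].
#' @param init Initial [model_state()].
#' @param times Numeric vector of output times (hours).
#' @param ... Passed to [deSolve::ode()] (e.g. `rtol`, `atol`).
#' @return A `deSolve` matrix: first column time, then one column per species.
#' @export
ode_reference <- function(net, init, times, ...) {
  x0 <- pack_state(init)
  names(x0) <- net$species
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    list(as.numeric(net$stoich %*% rates_vec(net, y)))
  }
  out <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL, ...)
  if (attr(out, "istate")[1L] < 0) {
    out <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-8, ...)
    if (attr(out, "istate")[1L] < 0)
      stop("mean-field integration failed even at tightened tolerances")
  }
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$times), "samples to t =",
      max(x$times), "h; termination:", x$termination,
      "; peak free phage:", format(x$peak_phage, big.mark = ","), "\n")
  invisible(x)
}

#' Tidy view of a trajectory
#'
#' @param x A `"trajectory"`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `strain` (NA for phage species),
#'   `species`, `count`.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  n_s <- x$n_s
  strain_of <- c(rep(seq_len(x$n_strains), each = 1L + n_s),
                 rep(NA_integer_, 1L + n_s))
  tibble::tibble(
    time = rep(x$times, each = length(x$species)),
    strain = rep(strain_of, times = length(x$times)),
    species = rep(x$species, times = length(x$times)),
    count = as.vector(x$states))
}
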