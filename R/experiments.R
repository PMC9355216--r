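#' Deterministic per-replicate seeds
#'
#' Derives the seed of replicate `rep` of grid cell `cell` from a master seed,
#' so experiment grids are reproducible and embarrassingly parallel. A simple
#' multiplicative hash folded into the 32-bit signed range.
#'
#' @param master Master seed (integer).
#' @param cell Grid-cell index (integer, >= 1).
#' @param rep Replicate index (integer, >= 1).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
replicate_seed <- function(master, cell, rep) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- (as.numeric(master) %% m) + 1
  h <- (h * 48271 + as.numeric(cell) * 16807) %% m
  h <- (h * 48271 + as.numeric(rep) * 69621) %% m
  as.integer(h %% (m - 1)) + 1L
}

run_replicates <- function(params, init, reps, seed, cell = 1L, t_max = 150,
                           method = "tau_leap", stop_on_phage_extinction = TRUE,
                           ...) {
  net <- build_reaction_network(params, ...)
  lapply(seq_len(reps), function(r) {
    simulate_outbreak(net, init, t_max = t_max,
                      seed = replicate_seed(seed, cell, r), method = method,
                      stop_on_phage_extinction = stop_on_phage_extinction)
  })
}

replicate_record <- function(traj, strain = 1L) {
  fs <- traj$final_state
  snap <- traj$s_extinction[[strain]]
  tibble::tibble(
    termination = traj$termination,
    phage_extinct = phage_extinct(fs),
    bacteria_extinct = total_bacteria(fs) == 0,
    peak_phage = traj$peak_phage,
    final_bacteria = total_bacteria(fs),
    resistant_at_s_extinction =
      if (is.null(snap)) NA_real_ else resistant_cells(snap$state, strain),
    diversity_at_s_extinction = as.numeric(diversity_at_s_extinction(traj,
                                                                     strain)))
}

binom_se <- function(p, n) sqrt(p * (1 - p) / n)

#' Probability of phage extinction under a parameter set
#'
#' Runs `reps` seeded outbreak simulations (default initial conditions: 6e6
#' sensitive cells, 1e5 wild-type phage) and reports the fraction in which
#' every phage genotype is extinct at termination, with its binomial standard
#' error and the per-replicate records.
#'
#' @param params A [crispr_params()] object.
#' @param reps Number of replicates (>= 1).
#' @param seed Master seed.
#' @param init Initial state (default [outbreak_init()] with the network's
#'   `n_s`).
#' @param t_max Simulation horizon (hours).
#' @param ... Passed to [build_reaction_network()] (variant switches).
#' @return A list with `fraction`, `se`, `reps` and a tibble `records`.
#' @export
extinction_probability <- function(params, reps = 100, seed = 1,
                                   init = NULL, t_max = 150, ...) {
  if (reps < 1) stop("reps must be >= 1")
  if (is.null(init)) init <- outbreak_init(n_s = params$n_s)
  trajs <- run_replicates(params, init, reps, seed, t_max = t_max, ...)
  records <- do.call(rbind, lapply(trajs, replicate_record))
  records$seed <- vapply(seq_len(reps), function(r) replicate_seed(seed, 1L, r),
                         0L)
  frac <- mean(records$phage_extinct)
  list(fraction = frac, se = binom_se(frac, reps), reps = reps,
       records = records)
}

#' Probability that resistance emerges before the sensitive cells are gone
#'
#' Fraction of replicates with at least one resistant cell present at the
#' instant the sensitive population first hits zero (replicates in which S
#' never reaches zero count as emergence if resistant cells exist at the end).
#'
#' @inheritParams extinction_probability
#' @return A list with `fraction`, `se`, `reps`, `records`.
#' @export
resistant_emergence_probability <- function(params, reps = 100, seed = 1,
                                            init = NULL, t_max = 150, ...) {
  if (reps < 1) stop("reps must be >= 1")
  if (is.null(init)) init <- outbreak_init(n_s = params$n_s)
  trajs <- run_replicates(params, init, reps, seed, t_max = t_max, ...)
  emerged <- vapply(trajs, function(tr) {
    snap <- tr$s_extinction[[1L]]
    st <- if (is.null(snap)) tr$final_state else snap$state
    resistant_cells(st, 1L) > 0
  }, TRUE)
  records <- do.call(rbind, lapply(trajs, replicate_record))
  records$emerged <- emerged
  frac <- mean(emerged)
  list(fraction = frac, se = binom_se(frac, reps), reps = reps,
       records = records)
}

#' Extinction-probability grid over acquisition and mutation probabilities
#'
#' Monte-Carlo sweep over a grid of spacer-acquisition probabilities `alpha`
#' (and optionally escape probabilities `mu`), reporting the phage-extinction
#' fraction per cell.
#'
#' @param alphas Numeric vector of acquisition probabilities.
#' @param mus Numeric vector of per-protospacer escape probabilities.
#' @param reps Replicates per grid cell.
#' @param seed Master seed.
#' @param base Base parameter set whose other fields are kept (default
#'   [default_params()]); `beta` and burst-size overrides (infectivity
#'   sensitivity, escape-cost variants) can be set here.
#' @param t_max Horizon (hours).
#' @param init Initial state (default [outbreak_init()] at the reference
#'   scale).
#' @param ... Passed to [build_reaction_network()] (e.g.
#'   `all_mutant_progeny = TRUE`).
#' @return A tibble with one row per grid cell: `alpha`, `mu`, `extinct`
#'   (fraction), `se`, `mean_peak_phage`, `reps`.
#' @export
acquisition_sweep <- function(alphas, mus = 3.4e-7, reps = 100, seed = 1,
                              base = default_params(), t_max = 150,
                              init = NULL, ...) {
  grid <- expand.grid(alpha = alphas, mu = mus, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(cell) {
    p <- crispr_params(alpha = grid$alpha[cell], mu = grid$mu[cell],
                       g = base$g, K = base$K, n_s = base$n_s,
                       beta = base$beta, b_wt = base$b_wt, b_m = base$b_m,
                       propensity = base$propensity)
    init_c <- if (is.null(init)) outbreak_init(n_s = p$n_s) else init
    trajs <- run_replicates(p, init_c, reps, seed, cell = cell, t_max = t_max,
                            ...)
    ext <- vapply(trajs, function(tr) phage_extinct(tr$final_state), TRUE)
    pk <- vapply(trajs, function(tr) tr$peak_phage, 0)
    tibble::tibble(alpha = p$alpha, mu = p$mu, extinct = mean(ext),
                   se = binom_se(mean(ext), reps),
                   mean_peak_phage = mean(pk), reps = reps)
  })
  do.call(rbind, rows)
}

#' Epidemiological threshold of the acquisition probability
#'
#' Smallest acquisition probability on a geometric grid whose phage-extinction
#' fraction reaches `target` (default 0.5), located by bisection on the grid:
#' cells are only simulated while they bracket the threshold.
#'
#' @param mu Escape probability per protospacer.
#' @param alphas Sorted grid of candidate acquisition probabilities.
#' @param reps Replicates per evaluated grid point.
#' @param seed Master seed.
#' @param target Extinction fraction defining the threshold.
#' @param base Base parameter set.
#' @param t_max Horizon (hours).
#' @param init Initial state (default [outbreak_init()] at the reference
#'   scale).
#' @return A list with `threshold` (NA if no grid point reaches the target),
#'   and a tibble `evaluated` of the grid points actually simulated.
#' @export
threshold_estimate <- function(mu = 3.4e-7,
                               alphas = 10^seq(-6.5, -4, by = 0.25),
                               reps = 20, seed = 1, target = 0.5,
                               base = default_params(), t_max = 150,
                               init = NULL) {
  alphas <- sort(alphas)
  frac <- rep(NA_real_, length(alphas))
  eval_cell <- function(k) {
    p <- crispr_params(alpha = alphas[k], mu = mu, g = base$g, K = base$K,
                       n_s = base$n_s, beta = base$beta, b_wt = base$b_wt,
                       b_m = base$b_m, propensity = base$propensity)
    init_c <- if (is.null(init)) outbreak_init(n_s = p$n_s) else init
    trajs <- run_replicates(p, init_c, reps, seed, cell = k, t_max = t_max)
    mean(vapply(trajs, function(tr) phage_extinct(tr$final_state), TRUE))
  }
  lo <- 1L; hi <- length(alphas)
  frac[lo] <- eval_cell(lo)
  frac[hi] <- eval_cell(hi)
  if (frac[lo] >= target) {
    threshold <- alphas[lo]
  } else if (frac[hi] < target) {
    threshold <- NA_real_
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      frac[mid] <- eval_cell(mid)
      if (frac[mid] >= target) hi <- mid else lo <- mid
    }
    threshold <- alphas[hi]
  }
  ev <- !is.na(frac)
  list(threshold = threshold,
       evaluated = tibble::tibble(alpha = alphas[ev], extinct = frac[ev],
                                  reps = reps))
}

#' Phage extinction under pre-existing spacer diversity
#'
#' Seeds the population with 50% naive cells and 50% resistant cells split
#' equally over `n_genotypes` spacers (`alpha = 0`, so no new spacers arise)
#' and measures the phage-extinction fraction.
#'
#' @param n_genotypes Number of distinct pre-existing resistant genotypes
#'   (0 seeds an all-sensitive population).
#' @param reps Replicates.
#' @param seed Master seed.
#' @param mu Escape probability (default the type I/II value).
#' @param base Base parameter set.
#' @param t_max Horizon (hours).
#' @param S0,P0 Total initial bacteria and phage inoculum.
#' @return A list with `fraction`, `se`, `reps`, `records`.
#' @export
initial_diversity_experiment <- function(n_genotypes, reps = 100, seed = 1,
                                         mu = 3.4e-7, base = default_params(),
                                         t_max = 150, S0 = 6e6, P0 = 1e5) {
  p <- crispr_params(alpha = 0, mu = mu, g = base$g, K = base$K,
                     n_s = base$n_s, beta = base$beta, b_wt = base$b_wt,
                     b_m = base$b_m, propensity = base$propensity,
                     type_iii = FALSE)
  init <- diversity_init(n_genotypes, S0 = S0, P0 = P0, n_s = p$n_s)
  trajs <- run_replicates(p, init, reps, seed, t_max = t_max)
  records <- do.call(rbind, lapply(trajs, replicate_record))
  frac <- mean(records$phage_extinct)
  list(fraction = frac, se = binom_se(frac, reps), reps = reps,
       records = records, n_genotypes = n_genotypes)
}

competition_fitness <- function(traj) {
  fs <- traj$final_state
  n_a <- fs$S[1L] + sum(fs$R[1L, ])
  n_b <- fs$S[2L] + sum(fs$R[2L, ])
  if (n_a == 0 && n_b == 0) return(relative_fitness(0, both_extinct = TRUE))
  relative_fitness(n_b / (n_a + n_b))
}

#' Two-strain competition experiment
#'
#' Mixes two sensitive strains (3e6 cells each) differing in their parameters,
#' optionally infects them with 1e5 wild-type phage, and computes the relative
#' fitness of strain B from its initial (0.5) and final frequency, counting
#' sensitive plus resistant cells of each strain. Both strains extinct gives
#' fitness 0; strain A extinct gives `Inf`.
#'
#' @param strain_a,strain_b [crispr_params()] of the control (A) and focal (B)
#'   strain.
#' @param reps Replicates.
#' @param seed Master seed.
#' @param with_phage If `FALSE`, no phage is added (autoimmunity-cost control).
#' @param t_max Horizon (hours).
#' @param cell Grid-cell index for the seed scheme.
#' @param init Initial two-strain state; defaults to [competition_init()]
#'   (3e6 cells per strain) with or without the phage inoculum.
#' @return A list with `fitness` (per replicate), `median_fitness`, `records`.
#' @export
competition <- function(strain_a, strain_b, reps = 100, seed = 1,
                        with_phage = TRUE, t_max = 150, cell = 1L,
                        init = NULL) {
  if (is.null(init))
    init <- competition_init(P0 = if (with_phage) 1e5 else 0,
                             n_s = strain_a$n_s)
  # fitness is read at the horizon, so bacterial dynamics continue after
  # the phage clears
  trajs <- run_replicates(list(strain_a, strain_b), init, reps, seed,
                          cell = cell, t_max = t_max,
                          stop_on_phage_extinction = FALSE)
  fit <- vapply(trajs, competition_fitness, 0)
  records <- tibble::tibble(
    rep = seq_len(reps),
    seed = vapply(seq_len(reps), function(r) replicate_seed(seed, cell, r), 0L),
    fitness = fit,
    termination = vapply(trajs, function(tr) tr$termination, ""))
  list(fitness = fit,
       median_fitness = stats::median(fit[is.finite(fit) | fit == Inf]),
       records = records)
}

#' Optimal acquisition probability across autoimmunity propensities
#'
#' For each propensity, competes a control strain (`alpha = 1e-5`) against
#' focal strains over a grid of acquisition probabilities (both type I/II,
#' `mu = 3.4e-7`, sharing the propensity) and reports the acquisition
#' probability with the highest median relative fitness.
#'
#' @param propensities Numeric vector of autoimmunity propensities.
#' @param alphas Acquisition-probability grid for the focal strain.
#' @param reps Replicates per competition.
#' @param seed Master seed.
#' @param mu Escape probability for both strains.
#' @param alpha_control Control-strain acquisition probability.
#' @param base Base parameter set.
#' @param t_max Horizon (hours).
#' @param init Optional two-strain initial state passed to [competition()].
#' @return A tibble with one row per propensity: `propensity`,
#'   `optimal_alpha`, `max_median_fitness`; plus the full grid in
#'   `attr(, "grid")`.
#' @export
propensity_scan <- function(propensities = c(0.004, 0.04, 0.4, 4, 40, 400,
                                             4000),
                            alphas = 10^seq(-6, -3, by = 0.5),
                            reps = 100, seed = 1, mu = 3.4e-7,
                            alpha_control = 1e-5, base = default_params(),
                            t_max = 150, init = NULL) {
  grid <- expand.grid(propensity = propensities, alpha = alphas,
                      KEEP.OUT.ATTRS = FALSE)
  med <- vapply(seq_len(nrow(grid)), function(cell) {
    pr <- grid$propensity[cell]
    a_ctrl <- crispr_params(alpha = alpha_control, mu = mu, g = base$g,
                            K = base$K, n_s = base$n_s, beta = base$beta,
                            b_wt = base$b_wt, b_m = base$b_m, propensity = pr)
    a_foc <- crispr_params(alpha = grid$alpha[cell], mu = mu, g = base$g,
                           K = base$K, n_s = base$n_s, beta = base$beta,
                           b_wt = base$b_wt, b_m = base$b_m, propensity = pr)
    competition(a_ctrl, a_foc, reps = reps, seed = seed,
                cell = cell, t_max = t_max, init = init)$median_fitness
  }, 0)
  grid$median_fitness <- med
  out <- do.call(rbind, lapply(propensities, function(pr) {
    sub <- grid[grid$propensity == pr, ]
    best <- which.max(sub$median_fitness)
    tibble::tibble(propensity = pr, optimal_alpha = sub$alpha[best],
                   max_median_fitness = sub$median_fitness[best])
  }))
  attr(out, "grid") <- tibble::as_tibble(grid)
  out
}

#' Type I/II versus type III competition grid
#'
#' Crosses acquisition probabilities of a type I/II strain (`mu = 3.4e-7`)
#' and a type III strain (`mu = 0`, escape-proof interference) in phage-
#' infected competitions and classifies each replicate as extinction of both
#' strains, selection for type I/II (it ends more frequent) or selection for
#' type III. The most frequent outcome per cell is reported with its count;
#' ties break conservatively toward `"extinction"`.
#'
#' @param alpha_12 Acquisition-probability grid of the type I/II strain.
#' @param alpha_3 Acquisition-probability grid of the type III strain.
#' @param with_autoimmunity If `TRUE` both strains share `propensity`.
#' @param propensity Shared autoimmunity propensity when enabled (the type III
#'   strain's value can be overridden via `propensity_3`).
#' @param propensity_3 Optional override for the type III strain.
#' @param reps Replicates per cell.
#' @param seed Master seed.
#' @param mu_12 Escape probability of the type I/II strain.
#' @param base Base parameter set.
#' @param t_max Horizon (hours).
#' @param init Optional two-strain initial state (default
#'   [competition_init()] at the reference scale).
#' @return A tibble with one row per cell: `alpha_12`, `alpha_3`, `outcome`,
#'   `count`, `n_extinct`, `n_type12`, `n_type3`, `reps`.
#' @export
type_competition_grid <- function(alpha_12, alpha_3, with_autoimmunity = FALSE,
                                  propensity = 40, propensity_3 = NULL,
                                  reps = 100, seed = 1, mu_12 = 3.4e-7,
                                  base = default_params(), t_max = 150,
                                  init = NULL) {
  pr12 <- if (with_autoimmunity) propensity else 0
  pr3 <- if (!with_autoimmunity) 0
         else if (is.null(propensity_3)) propensity else propensity_3
  grid <- expand.grid(alpha_12 = alpha_12, alpha_3 = alpha_3,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(cell) {
    s12 <- crispr_params(alpha = grid$alpha_12[cell], mu = mu_12, g = base$g,
                         K = base$K, n_s = base$n_s, beta = base$beta,
                         b_wt = base$b_wt, b_m = base$b_m, propensity = pr12,
                         type_iii = FALSE)
    s3 <- crispr_params(alpha = grid$alpha_3[cell], mu = 0, g = base$g,
                        K = base$K, n_s = base$n_s, beta = base$beta,
                        b_wt = base$b_wt, b_m = base$b_m, propensity = pr3,
                        type_iii = TRUE)
    init_c <- if (is.null(init)) competition_init(n_s = base$n_s) else init
    trajs <- run_replicates(list(s12, s3), init_c, reps, seed, cell = cell,
                            t_max = t_max, stop_on_phage_extinction = FALSE)
    cls <- vapply(trajs, function(tr) {
      fs <- tr$final_state
      n12 <- fs$S[1L] + sum(fs$R[1L, ])
      n3 <- fs$S[2L] + sum(fs$R[2L, ])
      if (n12 == 0 && n3 == 0) "extinction"
      else if (n12 > n3) "type_I_II"
      else if (n3 > n12) "type_III"
      else "extinction"  # exact tie: conservative
    }, "")
    counts <- c(extinction = sum(cls == "extinction"),
                type_I_II = sum(cls == "type_I_II"),
                type_III = sum(cls == "type_III"))
    top <- max(counts)
    winners <- names(counts)[counts == top]
    outcome <- if ("extinction" %in% winners) "extinction" else winners[1L]
    tibble::tibble(alpha_12 = grid$alpha_12[cell], alpha_3 = grid$alpha_3[cell],
                   outcome = outcome, count = top,
                   n_extinct = counts[["extinction"]],
                   n_type12 = counts[["type_I_II"]],
                   n_type3 = counts[["type_III"]], reps = reps)
  })
  do.call(rbind, rows)
}
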