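#' Simpson diversity (Hill number of order 2)
#'
#' Effective number of equally abundant genotypes, `1 / sum(p_i^2)`.
#'
#' @param p Genotype frequencies (or non-negative counts, which are
#'   normalized). Must contain at least one positive entry.
#' @return A value in `[1, length(p)]`.
#' @examples
#' simpson_diversity(c(3, 1))   # 1.6
#' simpson_diversity(rep(1, 4)) # 4
#' @export
simpson_diversity <- function(p) {
  if (length(p) == 0L || any(!is.finite(p)) || any(p < 0))
    stop("frequencies must be non-negative finite numbers")
  tot <- sum(p)
  if (tot == 0) stop("Simpson diversity is undefined for an all-zero vector")
  p <- p / tot
  1 / sum(p^2)
}

#' Relative fitness from initial and final frequencies
#'
#' `p_f (1 - p_i) / (p_i (1 - p_f))`; with `p_i = 0.5` this reduces to
#' `p_f / (1 - p_f)`. If both strains are extinct the relative fitness is set
#' to 0; if the control strain is extinct (`p_f = 1`) it is `Inf`.
#'
#' @param p_final Final frequency of the focal strain in `[0, 1]`.
#' @param p_initial Initial frequency (default 0.5, the standard competition
#'   seeding).
#' @param both_extinct Logical; set to `TRUE` when both strains died out.
#' @return The fitness ratio (possibly `Inf`).
#' @examples
#' relative_fitness(0.8)        # 4
#' relative_fitness(0.5)        # 1
#' @export
relative_fitness <- function(p_final, p_initial = 0.5, both_extinct = FALSE) {
  if (both_extinct) return(0)
  for (p in c(p_final, p_initial))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("frequencies must lie in [0, 1], got ", p)
  if (p_final == 1) return(Inf)
  p_final * (1 - p_initial) / (p_initial * (1 - p_final))
}

#' Growth rate from two optical-density readings
#'
#' `ln(od2 / od1) / (t2 - t1)`, the exponential-phase growth rate.
#'
#' @param od1,od2 Optical densities (> 0) at times `t1` and `t2`.
#' @param t1,t2 Times in hours, `t2 > t1`.
#' @return Growth rate per hour.
#' @examples
#' growth_rate_from_od(0.4, 5.5, 0.5, 6)  # ~0.446
#' @export
growth_rate_from_od <- function(od1, t1, od2, t2) {
  if (od1 <= 0 || od2 <= 0) stop("optical densities must be positive")
  if (t2 <= t1) stop("t2 must be later than t1")
  log(od2 / od1) / (t2 - t1)
}

#' Outbreak outcome predicates and summaries
#'
#' `phage_extinct()` is `TRUE` iff the wild-type and every escape phage count
#' is zero. `outbreak_size()` is the running peak of total free phage over the
#' trajectory (the cumulative count of virions produced is a coarser
#' alternative, not computed here). `diversity_at_s_extinction()` is the
#' Simpson diversity of the resistant genotypes (newly generated spacers,
#' excluding sensitive cells) at the snapshot taken when the sensitive
#' population first hit zero; it is 0 when the whole bacterial population is
#' extinct at that snapshot, and falls back to the final state (with a
#' warning attribute) when S never hit zero.
#'
#' @param state A [model_state()] (for `phage_extinct`).
#' @param traj A `"trajectory"` from [simulate_outbreak()].
#' @param strain Strain whose S-extinction snapshot to use (default 1).
#' @return See details.
#' @export
phage_extinct <- function(state) {
  state$P_wt == 0 && all(state$P_esc == 0)
}

#' @rdname phage_extinct
#' @export
outbreak_size <- function(traj) traj$peak_phage

#' @rdname phage_extinct
#' @export
diversity_at_s_extinction <- function(traj, strain = 1L) {
  snap <- traj$s_extinction[[strain]]
  flagged <- is.null(snap)
  st <- if (flagged) traj$final_state else snap$state
  r <- st$R[strain, ]
  # 0 covers both an extinct bacterial population and a spacer-free one
  d <- if (sum(r) == 0) 0 else simpson_diversity(r)
  if (flagged) attr(d, "flag") <- "S never reached zero; final state used"
  d
}

#' Number of resistant cells of a strain in a state
#' @param state A [model_state()].
#' @param strain Strain index.
#' @return Total resistant-cell count.
#' @export
resistant_cells <- function(state, strain = 1L) sum(state$R[strain, ])
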