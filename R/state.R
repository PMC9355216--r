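#' Population state of the outbreak model
#'
#' Integer counts of every bacterial and phage genotype at one instant.
#' Bacterial counts are per strain: sensitive cells `S` and a vector `R` of
#' resistant cells carrying spacer i (i = 1..n_s). Phage counts are shared by
#' all strains: wild-type `P_wt` and escape mutants `P_esc[i]` mutated in
#' protospacer i (spacers are defined by the phage sequence, so competing
#' strains share one protospacer coordinate system).
#'
#' Counts may exceed `.Machine$integer.max` (the default carrying capacity is
#' 1e11), so they are stored as whole-valued doubles.
#'
#' @param S Numeric vector of sensitive-cell counts, one per strain.
#' @param R Matrix of resistant-cell counts, `n_strains` rows and `n_s`
#'   columns (or a vector of length `n_s` for a single strain).
#' @param P_wt Wild-type phage count.
#' @param P_esc Numeric vector of length `n_s` of escape-phage counts.
#' @param n_s Number of protospacers; defaults to `ncol(R)` or `length(P_esc)`.
#' @param t Time (hours).
#'
#' @return An object of class `"model_state"`.
#' @examples
#' model_state(S = 6e6, P_wt = 1e5, n_s = 100)
#' @export
model_state <- function(S, R = NULL, P_wt = 0, P_esc = NULL, n_s = NULL,
                        t = 0) {
  n_strains <- length(S)
  if (is.null(n_s)) {
    n_s <- if (!is.null(P_esc)) length(P_esc)
           else if (is.matrix(R)) ncol(R)
           else if (!is.null(R) && n_strains == 1L) length(R)
           else 0L
    if (n_s == 0L)
      stop("n_s must be given when neither R nor P_esc determines it")
  }
  n_s <- as.integer(n_s)
  if (is.null(R)) R <- matrix(0, n_strains, n_s)
  if (is.vector(R)) R <- matrix(R, nrow = n_strains, byrow = n_strains == 1L)
  if (is.null(P_esc)) P_esc <- numeric(n_s)
  if (nrow(R) != n_strains || ncol(R) != n_s)
    stop("R must be a ", n_strains, " x ", n_s, " matrix")
  if (length(P_esc) != n_s) stop("P_esc must have length n_s = ", n_s)
  counts <- c(S, R, P_wt, P_esc)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts)))
    stop("all counts must be non-negative integers")
  st <- list(S = as.numeric(S), R = matrix(as.numeric(R), n_strains, n_s),
             P_wt = as.numeric(P_wt), P_esc = as.numeric(P_esc),
             n_strains = n_strains, n_s = n_s, t = t)
  class(st) <- "model_state"
  st
}

#' Total bacterial population of a state
#'
#' Recomputed from the counts, never cached.
#' @param state A [model_state()].
#' @return Total number of bacterial cells across strains and genotypes.
#' @export
total_bacteria <- function(state) sum(state$S) + sum(state$R)

#' Total free phage of a state
#' @param state A [model_state()].
#' @return Wild-type plus escape phage count.
#' @export
total_phage <- function(state) state$P_wt + sum(state$P_esc)

#' @export
print.model_state <- function(x, ...) {
  cat("model_state at t =", x$t, "h:",
      x$n_strains, "strain(s),", x$n_s, "protospacers\n")
  cat("  S     =", paste(format(x$S, big.mark = ","), collapse = ", "), "\n")
  cat("  R     =", paste(format(rowSums(x$R), big.mark = ","), collapse = ", "),
      "(cells, summed over spacers)\n")
  cat("  P_wt  =", format(x$P_wt, big.mark = ","), "\n")
  cat("  P_esc =", format(sum(x$P_esc), big.mark = ","),
      "(virions, summed over protospacers)\n")
  invisible(x)
}

# -- packing between the list form and the flat species vector used by the
#    engine.  Layout: for each strain s: S_s, R_s[1..n_s]; then P_wt,
#    P_esc[1..n_s].

species_names <- function(n_strains, n_s) {
  per_strain <- function(s) c(sprintf("S%d", s), sprintf("R%d_%d", s, seq_len(n_s)))
  c(unlist(lapply(seq_len(n_strains), per_strain)),
    "P_wt", sprintf("P_esc_%d", seq_len(n_s)))
}

pack_state <- function(state) {
  x <- numeric(state$n_strains * (1L + state$n_s) + 1L + state$n_s)
  off <- 0L
  for (s in seq_len(state$n_strains)) {
    x[off + 1L] <- state$S[s]
    x[off + 1L + seq_len(state$n_s)] <- state$R[s, ]
    off <- off + 1L + state$n_s
  }
  x[off + 1L] <- state$P_wt
  x[off + 1L + seq_len(state$n_s)] <- state$P_esc
  x
}

unpack_state <- function(x, n_strains, n_s, t = 0) {
  S <- numeric(n_strains)
  R <- matrix(0, n_strains, n_s)
  off <- 0L
  for (s in seq_len(n_strains)) {
    S[s] <- x[off + 1L]
    R[s, ] <- x[off + 1L + seq_len(n_s)]
    off <- off + 1L + n_s
  }
  st <- list(S = S, R = R, P_wt = x[off + 1L],
             P_esc = x[off + 1L + seq_len(n_s)],
             n_strains = n_strains, n_s = n_s, t = t)
  class(st) <- "model_state"
  st
}

#' Standard initial conditions
#'
#' `outbreak_init()` is the single-strain default (6e6 sensitive cells, 1e5
#' wild-type phage); `competition_init()` the two-strain competition default
#' (3e6 sensitive cells of each strain, 1e5 wild-type phage);
#' `diversity_init()` a population of 50% naive cells and 50% resistant cells
#' split equally over `n_genotypes` distinct spacers.
#'
#' @param S0 Initial sensitive cells (total for `diversity_init`).
#' @param P0 Initial wild-type phage.
#' @param n_s Number of protospacers.
#' @param n_genotypes Number of distinct resistant genotypes to seed
#'   (0 gives an all-sensitive population).
#' @return A [model_state()].
#' @export
outbreak_init <- function(S0 = 6e6, P0 = 1e5, n_s = 100L) {
  model_state(S = S0, P_wt = P0, n_s = n_s)
}

#' @rdname outbreak_init
#' @export
competition_init <- function(S0 = c(3e6, 3e6), P0 = 1e5, n_s = 100L) {
  model_state(S = S0, P_wt = P0, n_s = n_s)
}

#' @rdname outbreak_init
#' @export
diversity_init <- function(n_genotypes, S0 = 6e6, P0 = 1e5, n_s = 100L) {
  n_genotypes <- as.integer(n_genotypes)
  if (n_genotypes < 0L || n_genotypes > n_s)
    stop("n_genotypes must be between 0 and n_s")
  R <- numeric(n_s)
  if (n_genotypes == 0L) {
    S <- S0
  } else {
    S <- round(S0 / 2)
    R[seq_len(n_genotypes)] <- floor(S0 / 2 / n_genotypes)
  }
  model_state(S = S, R = R, P_wt = P0, n_s = n_s)
}
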