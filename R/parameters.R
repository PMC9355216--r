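#' Model parameters for one bacterial strain
#'
#' Bundles the rate constants and probabilities governing the interaction of a
#' bacterial strain carrying a naive CRISPR-Cas system with a virulent phage.
#' Defaults are the values measured or derived for *Streptococcus thermophilus*
#' DGCC7710 and its virulent phage 2972, the reference experimental system for
#' type II CRISPR-Cas studies.
#'
#' @param alpha Probability per infection that the cell acquires one spacer
#'   (dimensionless, in `[0, 1]`).
#' @param mu Escape-mutation probability per protospacer per replication
#'   (dimensionless). `mu = 0` encodes a type III system, whose interference
#'   cannot be escaped by point mutation; `mu = 3.4e-7` is the measured type
#'   I/II value.
#' @param g Bacterial growth rate (per hour).
#' @param K Carrying capacity of the bacterial population (cells).
#' @param n_s Number of protospacers on the phage genome (integer count).
#' @param beta Infectivity rate constant (per hour per phage per cell).
#' @param b_wt Burst size of the wild-type phage (virions per burst).
#' @param b_m Burst size of escape phage (virions per burst). `b_m < b_wt`
#'   encodes the fitness cost of escaping a spacer; equality (no-cost variant)
#'   is allowed.
#' @param propensity Autoimmunity propensity multiplier (dimensionless).
#'   The per-capita autoimmune death rate of every bacterial cell of the strain
#'   is `alpha * propensity`. `0` disables autoimmunity.
#' @param type_iii Logical; if `TRUE` the strain's resistant cells degrade
#'   every phage genotype, including matching escape mutants (escape-proof
#'   type III interference). Defaults to `mu == 0`.
#'
#' @return An object of class `"crispr_params"` (a named list).
#' @examples
#' p <- crispr_params(alpha = 1e-5, mu = 0)
#' p$g
#' @export
crispr_params <- function(alpha = 1e-5, mu = 3.4e-7, g = 0.44, K = 1e11,
                          n_s = 100L, beta = 1e-6, b_wt = 190, b_m = 179,
                          propensity = 0, type_iii = (mu == 0)) {
  p <- list(alpha = alpha, mu = mu, g = g, K = K, n_s = as.integer(n_s),
            beta = beta, b_wt = b_wt, b_m = b_m, propensity = propensity,
            type_iii = isTRUE(type_iii))
  validate_params(p)
  class(p) <- "crispr_params"
  p
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("alpha", "mu", "g", "K", "beta", "b_wt", "b_m", "propensity")) {
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a single finite number")
    if (p[[f]] < 0) stop("parameter '", f, "' must be non-negative, got ", p[[f]])
  }
  if (p$alpha > 1) stop("alpha is a probability and must be <= 1, got ", p$alpha)
  if (length(p$n_s) != 1L || is.na(p$n_s) || p$n_s < 1L)
    stop("n_s must be a positive integer, got ", p$n_s)
  if (p$n_s * p$mu > 1)
    stop("n_s * mu = ", p$n_s * p$mu,
         " exceeds 1; the per-infection mutation probability is ill-defined")
  if (p$K <= 0) stop("carrying capacity K must be positive")
  invisible(p)
}

#' @export
print.crispr_params <- function(x, ...) {
  cat("CRISPR-Cas strain parameters",
      if (x$type_iii) "(type III interference)" else "(type I/II interference)",
      "\n")
  for (f in setdiff(names(x), "type_iii"))
    cat(sprintf("  %-10s %g\n", f, x[[f]]))
  invisible(x)
}

#' Reference parameter set
#'
#' The default parameterization of the model (the *S. thermophilus* /
#' phage 2972 system): `g = 0.44` per hour, `K = 1e11`, `n_s = 100`,
#' `beta = 1e-6`, `b_wt = 190`, `b_m = 179`, no autoimmunity.
#'
#' @param alpha,mu Acquisition and per-protospacer escape probabilities.
#' @param ... Overrides passed on to [crispr_params()].
#' @return A `"crispr_params"` object.
#' @export
default_params <- function(alpha = 1e-5, mu = 3.4e-7, ...) {
  crispr_params(alpha = alpha, mu = mu, ...)
}
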