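#' Build the stochastic reaction network of the outbreak model
#'
#' Enumerates every transition channel of the phage/CRISPR outbreak model for
#' one or two competing bacterial strains: logistic growth and
#' density-dependent death of every bacterial genotype, wild-type bursts on
#' sensitive cells, mutation bursts placing an escape mutation on one of the
#' `n_s` protospacers, spacer acquisition, adsorption of wild-type phage on
#' resistant cells, escape-phage bursts on sensitive cells and on matching
#' resistant hosts, cross adsorption of escape phage on non-matching resistant
#' hosts, and autoimmune death at per-capita rate `alpha * propensity`.
#'
#' Successful bursts do not remove the infecting virion (the loss of the
#' infecting phage is neglected relative to the burst size). A mutation burst
#' splits the progeny between the parental and the mutant genotype:
#' `half_wt` wild-type plus `half_m` escape virions, each half-burst rounded to
#' the nearest integer by default. Strains flagged `type_iii` have no
#' escape-phage burst on their resistant cells: every phage genotype entering
#' such a cell is degraded.
#'
#' Channels with identical state change are aggregated over the index that
#' does not affect it (wild-type adsorption over the resistant genotype;
#' cross adsorption of `P_esc[i]` over the non-matching hosts), which leaves
#' every per-term rate sum identical to the mean-field equations.
#'
#' @param params A `"crispr_params"` object, or a list of one or two of them
#'   (one per competing strain). All strains must share `n_s`, `K`, `beta`.
#' @param all_mutant_progeny Logical; if `TRUE`, a mutation burst yields
#'   exclusively escape virions (`b_m` of them) instead of a half/half split.
#' @param half_wt,half_m Integer overrides for the half-burst sizes of a
#'   mutation burst; default `round(b_wt / 2)` and `round(b_m / 2)`.
#'
#' @return An object of class `"reaction_network"` with the channel table
#'   (`$channels`: label, class, strain, spacer), the stoichiometry matrix
#'   (`$stoich`, species x channels, sparse) and a vectorized rate evaluator
#'   (used by [reaction_rates()]).
#' @examples
#' net <- build_reaction_network(crispr_params(alpha = 1e-5, mu = 0, n_s = 5))
#' net
#' @export
build_reaction_network <- function(params, all_mutant_progeny = FALSE,
                                   half_wt = NULL, half_m = NULL) {
  if (inherits(params, "crispr_params")) params <- list(params)
  if (!is.list(params) || !all(vapply(params, inherits, TRUE, "crispr_params")))
    stop("params must be a crispr_params object or a list of them")
  n_strains <- length(params)
  if (!n_strains %in% 1:2)
    stop("n_strains must be 1 or 2, got ", n_strains)
  lapply(params, validate_params)
  n_s <- params[[1L]]$n_s
  if (!all(vapply(params, function(p) p$n_s, 0L) == n_s))
    stop("competing strains must share n_s (spacers are phage-sequence-defined)")
  K <- params[[1L]]$K
  if (!all(vapply(params, function(p) p$K, 0) == K))
    stop("competing strains must share the carrying capacity K")

  n_sp <- n_strains * (1L + n_s) + 1L + n_s
  iS <- integer(n_strains)            # index of S per strain
  iR <- matrix(0L, n_strains, n_s)    # indices of R per strain
  off <- 0L
  for (s in seq_len(n_strains)) {
    iS[s] <- off + 1L
    iR[s, ] <- off + 1L + seq_len(n_s)
    off <- off + 1L + n_s
  }
  iP <- off + 1L
  iE <- off + 1L + seq_len(n_s)       # indices of P_esc

  # channel bookkeeping, built strain by strain
  lab <- character(0); cls <- character(0)
  strain <- integer(0); spacer <- integer(0)
  trip <- list()   # list of (species index, delta) pairs per channel

  add <- function(label, class, s, i, ij, dv) {
    lab <<- c(lab, label); cls <<- c(cls, class)
    strain <<- c(strain, s); spacer <<- c(spacer, i)
    trip[[length(trip) + 1L]] <<- cbind(ij, dv)
  }

  for (s in seq_len(n_strains)) {
    p <- params[[s]]
    hw <- if (is.null(half_wt)) round(p$b_wt / 2) else half_wt
    hm <- if (is.null(half_m)) round(p$b_m / 2) else half_m
    add(sprintf("grow_S.%d", s), "grow_S", s, NA_integer_, iS[s], +1)
    for (i in seq_len(n_s))
      add(sprintf("grow_R.%d.%d", s, i), "grow_R", s, i, iR[s, i], +1)
    add(sprintf("death_S.%d", s), "death_S", s, NA_integer_, iS[s], -1)
    for (i in seq_len(n_s))
      add(sprintf("death_R.%d.%d", s, i), "death_R", s, i, iR[s, i], -1)
    add(sprintf("burst_wt.%d", s), "burst_wt", s, NA_integer_,
        c(iS[s], iP), c(-1, p$b_wt))
    for (i in seq_len(n_s)) {
      if (all_mutant_progeny) {
        add(sprintf("mut_burst.%d.%d", s, i), "mut_burst", s, i,
            c(iS[s], iE[i]), c(-1, p$b_m))
      } else {
        add(sprintf("mut_burst.%d.%d", s, i), "mut_burst", s, i,
            c(iS[s], iP, iE[i]), c(-1, hw, hm))
      }
    }
    for (i in seq_len(n_s))
      add(sprintf("acquisition.%d.%d", s, i), "acquisition", s, i,
          c(iS[s], iR[s, i], iP), c(-1, +1, -1))
    add(sprintf("adsorb_wt.%d", s), "adsorb_wt", s, NA_integer_, iP, -1)
    for (i in seq_len(n_s))
      add(sprintf("esc_burst_S.%d.%d", s, i), "esc_burst_S", s, i,
          c(iS[s], iE[i]), c(-1, p$b_m))
    for (i in seq_len(n_s)) {
      if (p$type_iii) next  # type III resistant cells degrade every genotype
      add(sprintf("esc_burst_R.%d.%d", s, i), "esc_burst_R", s, i,
          c(iR[s, i], iE[i]), c(-1, p$b_m))
    }
    for (i in seq_len(n_s))
      add(sprintf("cross_adsorb.%d.%d", s, i), "cross_adsorb", s, i, iE[i], -1)
    add(sprintf("auto_S.%d", s), "auto_S", s, NA_integer_, iS[s], -1)
    for (i in seq_len(n_s))
      add(sprintf("auto_R.%d.%d", s, i), "auto_R", s, i, iR[s, i], -1)
  }

  n_ch <- length(lab)
  tr <- do.call(rbind, trip)
  reps <- vapply(trip, nrow, 0L)
  stoich <- Matrix::sparseMatrix(i = tr[, 1L], j = rep(seq_len(n_ch), reps),
                                 x = tr[, 2L], dims = c(n_sp, n_ch))

  # consumed-species lookup (every consuming entry is -1): up to two reactants
  cons1 <- rep(NA_integer_, n_ch); cons2 <- rep(NA_integer_, n_ch)
  for (j in seq_len(n_ch)) {
    neg <- trip[[j]][trip[[j]][, 2L] < 0, 1L]
    if (length(neg) >= 1L) cons1[j] <- neg[1L]
    if (length(neg) >= 2L) cons2[j] <- neg[2L]
  }

  # channel-class index table per strain, for the vectorized rate evaluator
  slots <- lapply(seq_len(n_strains), function(s) {
    f <- function(cl) which(cls == cl & strain == s)
    list(grow_S = f("grow_S"), grow_R = f("grow_R"), death_S = f("death_S"),
         death_R = f("death_R"), burst_wt = f("burst_wt"),
         mut_burst = f("mut_burst"), acquisition = f("acquisition"),
         adsorb_wt = f("adsorb_wt"), esc_burst_S = f("esc_burst_S"),
         esc_burst_R = f("esc_burst_R"), cross_adsorb = f("cross_adsorb"),
         auto_S = f("auto_S"), auto_R = f("auto_R"))
  })

  # compact form consumed by the compiled tau-leap core
  class_code <- c(grow_S = 1L, grow_R = 2L, death_S = 3L, death_R = 4L,
                  burst_wt = 5L, mut_burst = 6L, acquisition = 7L,
                  adsorb_wt = 8L, esc_burst_S = 9L, esc_burst_R = 10L,
                  cross_adsorb = 11L, auto_S = 12L, auto_R = 13L)
  param_matrix <- do.call(rbind, lapply(params, function(p)
    c(p$alpha, p$mu, p$g, p$K, p$beta, p$b_wt, p$b_m, p$propensity,
      as.numeric(p$type_iii))))
  compact <- list(
    n_strains = n_strains, n_s = n_s, n_species = n_sp, n_channels = n_ch,
    param_matrix = param_matrix,
    iS = iS, iR = iR, iP = iP, iE = iE,
    cls = unname(class_code[cls]), strain = strain, spacer = spacer,
    cons1 = cons1, cons2 = cons2,
    up_start = c(0L, cumsum(reps)),
    up_idx = as.integer(tr[, 1L] - 1L),
    up_val = as.numeric(tr[, 2L]))

  net <- list(
    n_strains = n_strains, n_s = n_s, params = params, K = K,
    n_species = n_sp, n_channels = n_ch,
    species = species_names(n_strains, n_s),
    channels = data.frame(label = lab, class = cls, strain = strain,
                          spacer = spacer, stringsAsFactors = FALSE),
    stoich = stoich, stoich_sq = stoich^2,
    cons1 = cons1, cons2 = cons2,
    iS = iS, iR = iR, iP = iP, iE = iE, slots = slots,
    compact = compact,
    all_mutant_progeny = isTRUE(all_mutant_progeny)
  )
  class(net) <- "reaction_network"
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", x$n_strains, "strain(s),", x$n_s, "protospacers,",
      x$n_channels, "channels,", x$n_species, "species\n")
  invisible(x)
}

#' Evaluate all channel rates at a state
#'
#' @param net A [build_reaction_network()] object.
#' @param state A [model_state()] or a packed species vector.
#' @return Named numeric vector of channel rates (per hour), one per channel.
#' @examples
#' net <- build_reaction_network(crispr_params(alpha = 0, mu = 0, n_s = 2))
#' reaction_rates(net, model_state(S = 10, P_wt = 3, n_s = 2))
#' @export
reaction_rates <- function(net, state) {
  x <- if (inherits(state, "model_state")) pack_state(state) else state
  a <- rates_vec(net, x)
  names(a) <- net$channels$label
  a
}

# fast unnamed rate evaluator used in the simulation loops
rates_vec <- function(net, x) {
  n_s <- net$n_s
  Tt <- 0
  for (s in seq_len(net$n_strains))
    Tt <- Tt + x[net$iS[s]] + sum(x[net$iR[s, ]])
  P <- x[net$iP]
  E <- x[net$iE]
  a <- numeric(net$n_channels)
  for (s in seq_len(net$n_strains)) {
    p <- net$params[[s]]
    sl <- net$slots[[s]]
    S <- x[net$iS[s]]
    R <- x[net$iR[s, ]]
    Rtot <- sum(R)
    dd <- p$g * Tt / p$K
    inf <- p$beta * S * P
    a[sl$grow_S] <- p$g * S
    a[sl$grow_R] <- p$g * R
    a[sl$death_S] <- dd * S
    a[sl$death_R] <- dd * R
    a[sl$burst_wt] <- (1 - p$alpha) * (1 - n_s * p$mu) * inf
    a[sl$mut_burst] <- (1 - p$alpha) * p$mu * inf
    a[sl$acquisition] <- (p$alpha / n_s) * inf
    a[sl$adsorb_wt] <- p$beta * P * Rtot
    a[sl$esc_burst_S] <- p$beta * S * E
    if (!p$type_iii) a[sl$esc_burst_R] <- p$beta * E * R
    a[sl$cross_adsorb] <- p$beta * E * (if (p$type_iii) Rtot else Rtot - R)
    au <- p$alpha * p$propensity
    a[sl$auto_S] <- au * S
    a[sl$auto_R] <- au * R
  }
  a
}

#' Apply a channel to a state
#'
#' Adds the channel's integer state-change vector to the state `times` times.
#' If any count would become negative the firing is infeasible and an error is
#' raised (the stochastic engine instead reduces its leap).
#'
#' @param state A [model_state()].
#' @param net The [build_reaction_network()] the channel belongs to.
#' @param channel Channel label or index.
#' @param times Number of firings (>= 1).
#' @return The updated [model_state()].
#' @examples
#' net <- build_reaction_network(crispr_params(alpha = 1, mu = 0, n_s = 2))
#' st <- model_state(S = 5, P_wt = 3, n_s = 2)
#' apply_reaction(st, net, "acquisition.1.1")
#' @export
apply_reaction <- function(state, net, channel, times = 1) {
  if (times < 1 || times != floor(times)) stop("times must be an integer >= 1")
  j <- if (is.character(channel)) match(channel, net$channels$label)
       else as.integer(channel)
  if (is.na(j) || j < 1L || j > net$n_channels)
    stop("unknown channel: ", channel)
  x <- pack_state(state)
  x2 <- x + as.numeric(net$stoich[, j]) * times
  if (any(x2 < 0))
    stop("infeasible firing: channel '", net$channels$label[j], "' fired ",
         times, " time(s) would drive a count negative")
  unpack_state(x2, net$n_strains, net$n_s, t = state$t)
}
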