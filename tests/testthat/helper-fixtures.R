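# shared miniature systems: small carrying capacity and amplified
# infectivity so both simulation methods are practical in tests

mini_params <- function(alpha = 0.02, mu = 0.004, K = 1e4, beta = 1e-3,
                        b_wt = 10, b_m = 8, g = 0.44, n_s = 5L, ...) {
  crispr_params(alpha = alpha, mu = mu, g = g, K = K, n_s = n_s, beta = beta,
                b_wt = b_wt, b_m = b_m, ...)
}

mini_init <- function(S = 500, P = 50, n_s = 5L) {
  model_state(S = S, P_wt = P, n_s = n_s)
}

# random valid parameter set for property-style loops
random_params <- function() {
  crispr_params(alpha = stats::runif(1, 0, 1),
                mu = stats::runif(1, 0, 1e-3),
                g = stats::runif(1, 0.1, 2),
                K = 10^stats::runif(1, 3, 11),
                n_s = sample(2:50, 1),
                beta = 10^stats::runif(1, -8, -3),
                b_wt = sample(10:300, 1),
                b_m = sample(5:200, 1),
                propensity = sample(c(0, 10^stats::runif(1, -2, 3)), 1),
                type_iii = FALSE)
}

random_state <- function(n_s, n_strains = 1L) {
  model_state(S = sample(0:5000, n_strains),
              R = matrix(sample(0:200, n_strains * n_s, replace = TRUE),
                         n_strains, n_s),
              P_wt = sample(0:1e5, 1),
              P_esc = sample(0:500, n_s, replace = TRUE))
}

# direct per-class rate sums of a single-strain network, written straight
# from the mean-field equations; the independent oracle for the rate laws
eq_term_rates <- function(p, st) {
  S <- st$S[1]; R <- st$R[1, ]; P <- st$P_wt; E <- st$P_esc
  T <- S + sum(R)
  list(
    grow_S = p$g * S,
    grow_R = p$g * R,
    death_S = p$g * S * T / p$K,
    death_R = p$g * R * T / p$K,
    predation_wt_on_S = (1 - p$alpha) * (1 - p$n_s * p$mu) * p$beta * S * P,
    mutation = (1 - p$alpha) * p$n_s * p$mu * p$beta * S * P,
    acquisition = p$alpha * p$beta * S * P,
    failed_wt_on_R = p$beta * P * sum(R),
    predation_esc_on_S = p$beta * S * sum(E),
    predation_esc_on_R = p$beta * sum(E * R),
    failed_esc_on_R = p$beta * sum(E * (sum(R) - R)),
    autoimmunity = p$alpha * p$propensity * T)
}

class_sum <- function(net, st, cls) {
  a <- reaction_rates(net, st)
  sum(a[net$channels$class == cls])
}
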