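test_that("with no phage the bacterial population settles at the carrying
           capacity", {
  p <- mini_params(alpha = 0, mu = 0, type_iii = FALSE)
  net <- build_reaction_network(p)
  init <- model_state(S = 500, P_wt = 0, n_s = 5)
  for (m in c("tau_leap", "exact")) {
    tr <- simulate_outbreak(net, init, t_max = 40, seed = 11, method = m,
                            stop_on_phage_extinction = FALSE)
    final <- total_bacteria(tr$final_state)
    # fluctuations around the logistic fixed point are O(sqrt(K))
    expect_lt(abs(final - p$K), 6 * sqrt(p$K))
    expect_equal(tr$termination, "phage_extinct")  # no phage were ever there
    expect_equal(max(tr$times), 40)
  }
})

test_that("identical seeds give bit-identical trajectories and different
           seeds differ", {
  net <- build_reaction_network(mini_params())
  for (m in c("tau_leap", "exact")) {
    t1 <- simulate_outbreak(net, mini_init(), t_max = 10, seed = 5, method = m)
    t2 <- simulate_outbreak(net, mini_init(), t_max = 10, seed = 5, method = m)
    expect_identical(t1$states, t2$states)
    expect_identical(t1$times, t2$times)
    expect_identical(t1$termination, t2$termination)
    expect_identical(t1$peak_phage, t2$peak_phage)
    t3 <- simulate_outbreak(net, mini_init(), t_max = 10, seed = 6, method = m)
    expect_false(identical(t1$states, t3$states))
  }
})

test_that("no recorded state ever contains a negative count", {
  set.seed(20)
  net <- build_reaction_network(mini_params(alpha = 0.1, mu = 0.01,
                                            propensity = 5))
  for (s in 1:6) {
    tr <- simulate_outbreak(net, mini_init(), t_max = 25, seed = s)
    expect_true(all(tr$states >= 0))
    expect_true(all(diff(tr$times) > 0))
    expect_lte(max(tr$times), 25)
  }
})

test_that("mu = 0 keeps escape phage at zero and alpha = 0 keeps resistance
           at zero along whole trajectories", {
  net_mu0 <- build_reaction_network(mini_params(alpha = 0.1, mu = 0,
                                                type_iii = FALSE))
  net_a0 <- build_reaction_network(mini_params(alpha = 0, mu = 0.01))
  for (s in 1:4) {
    tr <- simulate_outbreak(net_mu0, mini_init(), t_max = 30, seed = s)
    esc_rows <- grep("^P_esc", tr$species)
    expect_true(all(tr$states[esc_rows, ] == 0))

    tr2 <- simulate_outbreak(net_a0, mini_init(), t_max = 30, seed = s)
    r_rows <- grep("^R", tr2$species)
    expect_true(all(tr2$states[r_rows, ] == 0))
  }
})

test_that("exact SSA and tau-leaping agree in distribution on the miniature
           system", {
  # the two methods are independent implementations (interpreted R vs the
  # compiled leap core), so this is also a cross-implementation check
  net <- build_reaction_network(mini_params())
  init <- mini_init()
  n_runs <- 120
  run <- function(method, off) vapply(seq_len(n_runs), function(r) {
    tr <- simulate_outbreak(net, init, t_max = 8, seed = 1000 * off + r,
                            method = method)
    c(extinct = as.numeric(phage_extinct(tr$final_state)),
      phage = total_phage(tr$final_state),
      bact = total_bacteria(tr$final_state))
  }, c(extinct = 0, phage = 0, bact = 0))
  ex <- run("exact", 1)
  tl <- run("tau_leap", 2)

  # extinction outcome: two-sample proportion test, 1% level (skipped when
  # neither arm has any extinction, where the test statistic is undefined)
  n_ext <- c(sum(ex["extinct", ]), sum(tl["extinct", ]))
  if (sum(n_ext) > 0) {
    pt <- suppressWarnings(stats::prop.test(n_ext, c(n_runs, n_runs)))
    expect_gt(pt$p.value, 0.01)
  } else {
    expect_equal(n_ext[1], n_ext[2])
  }
  # final population sizes: rank test, 1% level
  expect_gt(stats::wilcox.test(ex["phage", ], tl["phage", ])$p.value, 0.01)
  expect_gt(stats::wilcox.test(ex["bact", ], tl["bact", ])$p.value, 0.01)
})

test_that("the mean-field oracle reproduces logistic growth without phage", {
  p <- mini_params(alpha = 0, mu = 0, type_iii = FALSE)
  net <- build_reaction_network(p)
  init <- model_state(S = 500, P_wt = 0, n_s = 5)
  tgrid <- seq(0, 20, by = 1)
  out <- ode_reference(net, init, tgrid)
  S0 <- 500
  closed <- p$K * S0 * exp(p$g * tgrid) / (p$K + S0 * (exp(p$g * tgrid) - 1))
  expect_equal(unname(out[, "S1"]), closed, tolerance = 1e-5)
})

test_that("the stochastic ensemble mean tracks the mean-field solution at
           large counts", {
  # system-size scaling: counts x100, infectivity /100 leaves the mean-field
  # dynamics unchanged while shrinking relative fluctuations
  p <- mini_params(alpha = 0.02, mu = 0, K = 1e6, beta = 1e-5,
                   type_iii = FALSE)
  net <- build_reaction_network(p)
  init <- model_state(S = 5e4, P_wt = 5e3, n_s = 5)
  ode <- ode_reference(net, init, c(0, 5), rtol = 1e-10, atol = 1e-8)
  n_runs <- 50
  # a tight leap tolerance removes the O(eps) bias so the comparison is
  # dominated by Monte-Carlo error
  finals <- vapply(seq_len(n_runs), function(r) {
    tr <- simulate_outbreak(net, init, t_max = 5, seed = 300 + r,
                            eps = 0.005)
    c(S = tr$final_state$S[1], P = tr$final_state$P_wt)
  }, c(S = 0, P = 0))
  for (sp in c("S", "P")) {
    m <- mean(finals[sp, ])
    se <- stats::sd(finals[sp, ]) / sqrt(n_runs)
    target <- if (sp == "S") ode[2, "S1"] else ode[2, "P_wt"]
    expect_lt(abs(m - target), 3 * se + 1e-3)
  }
})

test_that("termination causes are classified from the final counts", {
  # phage win: no resistance possible, bacteria collapse
  net <- build_reaction_network(mini_params(alpha = 0, mu = 0,
                                            type_iii = FALSE))
  tr <- simulate_outbreak(net, mini_init(), t_max = 80, seed = 2)
  expect_equal(tr$termination, "bacteria_extinct")
  expect_false(is.null(tr$s_extinction[[1]]))
  expect_equal(tr$s_extinction[[1]]$state$S[1], 0)

  # bacteria win: acquisition certain and no escape possible
  net2 <- build_reaction_network(mini_params(alpha = 0.5, mu = 0))
  tr2 <- simulate_outbreak(net2, mini_init(), t_max = 150, seed = 2)
  expect_equal(tr2$termination, "phage_extinct")
  expect_true(phage_extinct(tr2$final_state))
})

test_that("trajectories export to a tidy table", {
  net <- build_reaction_network(mini_params())
  tr <- simulate_outbreak(net, mini_init(), t_max = 5, seed = 3)
  df <- as.data.frame(tr)
  expect_s3_class(df, "tbl_df")
  expect_named(df, c("time", "strain", "species", "count"))
  expect_equal(nrow(df), length(tr$times) * length(tr$species))
  expect_true(all(df$count >= 0))
})

test_that("engine input validation rejects mismatched dimensions", {
  net <- build_reaction_network(mini_params())
  expect_error(simulate_outbreak(net, model_state(S = 10, P_wt = 1, n_s = 3),
                                 seed = 1), "dimensions")
  expect_error(simulate_outbreak(net, mini_init(), t_max = -1, seed = 1),
               "t_max")
})
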