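test_that("parameter invariants are enforced", {
  expect_s3_class(crispr_params(alpha = 0, mu = 0), "crispr_params")
  expect_error(crispr_params(alpha = 1.5), "alpha")
  expect_error(crispr_params(alpha = -0.1), "non-negative")
  expect_error(crispr_params(mu = 0.5, n_s = 100), "n_s \\* mu")
  expect_error(crispr_params(n_s = 0), "n_s")
  expect_error(crispr_params(K = 0), "K")
  expect_error(crispr_params(beta = NA), "finite")
  # the no-cost escape variant is allowed
  expect_s3_class(crispr_params(b_m = 190, b_wt = 190), "crispr_params")
})

test_that("network channel rates equal the printed equation terms at the
           reference parameters", {
  # direct symbolic evaluation of every equation term with the reference
  # numbers is the oracle; the network must match term by term
  p <- crispr_params(alpha = 1e-5, mu = 3.4e-7, type_iii = FALSE)
  net <- build_reaction_network(p)
  st <- model_state(S = 6e6, P_wt = 1e5, n_s = 100)
  terms <- eq_term_rates(p, st)

  expect_equal(class_sum(net, st, "grow_S"), terms$grow_S)
  expect_equal(class_sum(net, st, "death_S"), terms$death_S)
  expect_equal(class_sum(net, st, "burst_wt"), terms$predation_wt_on_S)
  expect_equal(class_sum(net, st, "mut_burst"), terms$mutation)
  expect_equal(class_sum(net, st, "acquisition"), terms$acquisition)
  expect_equal(class_sum(net, st, "auto_S"), 0)  # propensity 0

  # frozen values of the direct evaluation (infection flux 0.6 per hour
  # splits as (1 - alpha)(1 - n_s mu) : (1 - alpha) n_s mu : alpha)
  expect_equal(terms$predation_wt_on_S, 599973.600204, tolerance = 1e-12)
  expect_equal(terms$mutation, 20.399796, tolerance = 1e-10)
  expect_equal(terms$acquisition, 6, tolerance = 1e-12)
  expect_equal(terms$grow_S, 0.44 * 6e6)
  expect_equal(terms$death_S, 0.44 * 6e6 * 6e6 / 1e11)
})

test_that("rates match the equation terms on states with resistance and
           escape phage present", {
  set.seed(101)
  for (rep in 1:20) {
    p <- random_params()
    net <- build_reaction_network(p)
    st <- random_state(p$n_s)
    terms <- eq_term_rates(p, st)
    expect_equal(class_sum(net, st, "grow_R"), sum(terms$grow_R))
    expect_equal(class_sum(net, st, "death_R"), sum(terms$death_R))
    expect_equal(class_sum(net, st, "adsorb_wt"), terms$failed_wt_on_R)
    expect_equal(class_sum(net, st, "esc_burst_S"), terms$predation_esc_on_S)
    expect_equal(class_sum(net, st, "esc_burst_R"), terms$predation_esc_on_R)
    expect_equal(class_sum(net, st, "cross_adsorb"), terms$failed_esc_on_R)
    expect_equal(class_sum(net, st, "auto_S") + class_sum(net, st, "auto_R"),
                 terms$autoimmunity)
  }
})

test_that("infection branches sum to the total infection flux", {
  # (1-a)(1-n_s mu) + (1-a) n_s mu + a = 1 for every parameter set
  set.seed(7)
  for (rep in 1:25) {
    p <- random_params()
    net <- build_reaction_network(p)
    st <- random_state(p$n_s)
    flux <- p$beta * st$S[1] * st$P_wt
    branch <- class_sum(net, st, "burst_wt") +
      class_sum(net, st, "mut_burst") + class_sum(net, st, "acquisition")
    expect_equal(branch, flux, tolerance = 1e-12)
  }
})

test_that("alpha = 1 routes the whole infection flux into acquisition and
           alpha = 0 disables it", {
  st <- model_state(S = 1, P_wt = 1, n_s = 4)
  net1 <- build_reaction_network(crispr_params(alpha = 1, mu = 1e-3, n_s = 4,
                                               beta = 1e-6))
  expect_equal(class_sum(net1, st, "acquisition"), 1e-6)
  expect_equal(class_sum(net1, st, "burst_wt"), 0)
  expect_equal(class_sum(net1, st, "mut_burst"), 0)

  net0 <- build_reaction_network(crispr_params(alpha = 0, mu = 0, n_s = 4,
                                               beta = 1e-6, type_iii = FALSE))
  a <- reaction_rates(net0, st)
  expect_equal(unname(a[net0$channels$class == "burst_wt"]), 1e-6)
  expect_equal(class_sum(net0, st, "acquisition"), 0)
})

test_that("mutation bursts split the progeny into rounded half-bursts", {
  net <- build_reaction_network(crispr_params())  # b_wt 190, b_m 179
  j <- which(net$channels$class == "mut_burst")[1]
  col <- net$stoich[, j]
  expect_equal(unname(col[net$iP]), 95)
  expect_equal(unname(col[net$iE[1]]), 90)  # round(89.5) = 90
  expect_equal(unname(col[net$iS[1]]), -1)

  # all-mutant-progeny variant: the burst is entirely escape virions
  netv <- build_reaction_network(crispr_params(), all_mutant_progeny = TRUE)
  jv <- which(netv$channels$class == "mut_burst")[1]
  expect_equal(unname(netv$stoich[netv$iE[1], jv]), 179)
  expect_equal(unname(netv$stoich[netv$iP, jv]), 0)
})

test_that("compiled and interpreted rate evaluators agree everywhere", {
  set.seed(42)
  for (rep in 1:15) {
    p <- random_params()
    net <- build_reaction_network(p)
    st <- random_state(p$n_s)
    x <- crisprout:::pack_state(st)
    expect_equal(crisprout:::.cpp_rates(net$compact, x),
                 unname(reaction_rates(net, st)))
  }
  # and for a two-strain network with a type III competitor
  p1 <- crispr_params(alpha = 1e-3, mu = 1e-4, n_s = 8, K = 1e6,
                      propensity = 40, type_iii = FALSE)
  p2 <- crispr_params(alpha = 5e-4, mu = 0, n_s = 8, K = 1e6,
                      propensity = 40, type_iii = TRUE)
  net2 <- build_reaction_network(list(p1, p2))
  st2 <- random_state(8L, n_strains = 2L)
  expect_equal(crisprout:::.cpp_rates(net2$compact,
                                      crisprout:::pack_state(st2)),
               unname(reaction_rates(net2, st2)))
})

test_that("type III strains have no escape burst on their resistant cells", {
  p3 <- crispr_params(alpha = 1e-4, mu = 0, n_s = 3, type_iii = TRUE)
  net <- build_reaction_network(p3)
  expect_false(any(net$channels$class == "esc_burst_R"))
  # every phage genotype is degraded: cross adsorption covers the matching
  # spacer too
  st <- model_state(S = 0, R = c(10, 0, 0), P_wt = 0, P_esc = c(7, 0, 0))
  a <- reaction_rates(net, st)
  expect_equal(unname(a["cross_adsorb.1.1"]), p3$beta * 7 * 10)
})

test_that("apply_reaction applies the state change and rejects infeasible
           firings", {
  net <- build_reaction_network(crispr_params(alpha = 1, mu = 0, n_s = 2,
                                              b_wt = 190))
  st <- model_state(S = 5, R = c(0, 0), P_wt = 3, n_s = 2)
  st2 <- apply_reaction(st, net, "acquisition.1.1")
  expect_equal(st2$S, 4)
  expect_equal(st2$R[1, 1], 1)
  expect_equal(st2$P_wt, 2)

  st3 <- apply_reaction(model_state(S = 1, P_wt = 1, n_s = 2), net,
                        "burst_wt.1")
  expect_equal(st3$S, 0)
  expect_equal(st3$P_wt, 191)

  expect_error(apply_reaction(model_state(S = 1, P_wt = 1, n_s = 2), net,
                              "burst_wt.1", times = 2), "infeasible")
  expect_error(apply_reaction(st, net, "no_such_channel"), "unknown channel")
})

test_that("two competing strains share the protospacer coordinate system", {
  pa <- crispr_params(alpha = 1e-4, mu = 1e-4, n_s = 4, type_iii = FALSE)
  pb <- crispr_params(alpha = 1e-5, mu = 1e-4, n_s = 4, type_iii = FALSE)
  net <- build_reaction_network(list(pa, pb))
  # an escape phage in protospacer 2 can burst on either strain's R_2
  st <- model_state(S = c(0, 0), R = rbind(c(0, 5, 0, 0), c(0, 3, 0, 0)),
                    P_wt = 0, P_esc = c(0, 11, 0, 0))
  a <- reaction_rates(net, st)
  expect_equal(unname(a["esc_burst_R.1.2"]), pa$beta * 11 * 5)
  expect_equal(unname(a["esc_burst_R.2.2"]), pb$beta * 11 * 3)
  expect_error(build_reaction_network(list(pa, crispr_params(n_s = 5))),
               "share n_s")
  expect_error(build_reaction_network(rep(list(pa), 3)), "n_strains")
})
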