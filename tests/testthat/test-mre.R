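test_that("fitness is total: empty chromosome, hand case, nonnegativity", {
  net <- toy_te_network()
  expect_identical(fitness(net, 0L, c(T = "1"), "E"), 1)
  # chromosome binding E to its second state ("1"): the GBF of the
  # explanation {E=1} for the evidence {T=1}, i.e. 0.3077 / 0.0270
  expect_equal(fitness(net, 2L, c(T = "1"), "E"),
               (0.08 / 0.26) / (0.02 / 0.74), tolerance = 1e-12)
  # and it equals gbf() with the same roles
  expect_equal(fitness(net, 2L, c(T = "1"), "E"),
               gbf(net, c(E = "1"), c(T = "1")), tolerance = 1e-12)
  for (seed in 1:3) {
    net2 <- random_net(6L, seed * 23L)
    cands <- setdiff(bn_vars(net2), bn_target(net2))[1:4]
    hyp <- stats::setNames(bn_states(net2, bn_target(net2))[1L], bn_target(net2))
    withr::with_seed(seed, {
      for (i in 1:10) {
        ch <- vapply(cands, function(v) sample(0:bn_card(net2, v), 1L), integer(1))
        expect_gte(fitness(net2, ch, hyp, cands), 0)
      }
    })
  }
})

test_that("exhaustive search: hand case, independence, cap", {
  net <- toy_te_network()
  ex <- exhaustive_mre(net, c(T = "1"), "E")
  expect_identical(ex$explanation, c(E = "1"))
  expect_equal(ex$gbf, (0.08 / 0.26) / (0.02 / 0.74), tolerance = 1e-12)

  # candidates independent of the hypothesis: nothing beats staying silent
  s <- bn_structure(list(bn_variable("t", c("0", "1"), role = "target"),
                         bn_variable("a", c("0", "1")), bn_variable("b", c("0", "1"))))
  ind <- bayesian_network(s, list(
    bn_cpt("t", character(0), matrix(c(0.7, 0.3), 1)),
    bn_cpt("a", character(0), matrix(c(0.4, 0.6), 1)),
    bn_cpt("b", character(0), matrix(c(0.2, 0.8), 1))
  ))
  ex2 <- exhaustive_mre(ind, c(t = "1"), c("a", "b"))
  expect_length(ex2$explanation, 0L)
  expect_equal(ex2$gbf, 1)

  expect_error(exhaustive_mre(net, c(T = "1"), "E", cap = 1),
               class = "ssbn_too_large")
})

test_that("the GA is seeded, elitist, and matches the oracle on small spaces", {
  # single binary candidate: a two-point search space
  net <- toy_te_network()
  res <- run_ga(net, c(T = "1"), "E", ga_config(seed = 3, generations = 5))
  expect_identical(res$results[[1L]]$explanation, c(E = "1"))
  expect_equal(res$results[[1L]]$gbf, exhaustive_mre(net, c(T = "1"), "E")$gbf,
               tolerance = 1e-12)

  net2 <- random_net(9L, 301L, max_card = 2L, target_idx = 5L)
  tg <- bn_target(net2)
  cands <- setdiff(bn_vars(net2), tg)
  hyp <- stats::setNames(bn_states(net2, tg)[2L], tg)
  cfg <- ga_config(seed = 11, generations = 25)
  r1 <- run_ga(net2, hyp, cands, cfg)
  r2 <- run_ga(net2, hyp, cands, cfg)
  expect_identical(r1$results, r2$results)
  # best fitness per generation is non-decreasing (elitism)
  b <- r1$best_per_generation
  expect_true(all(signif(b[-1L], 10) >= signif(b[-length(b)], 10)))
  # the reported optimum dominates the rest of the ranked list
  gbfs <- vapply(r1$results, `[[`, numeric(1), "gbf")
  expect_true(all(gbfs[1L] >= gbfs - 1e-9))

  ex <- exhaustive_mre(net2, hyp, cands)
  expect_lte(r1$results[[1L]]$gbf, ex$gbf * (1 + 1e-9))

  expect_error(run_ga(net2, hyp, character(0)), class = "ssbn_configuration")
  expect_error(run_ga(net2, hyp, c(cands, tg)), class = "ssbn_configuration")
  expect_error(ga_config(population_size = 1), class = "ssbn_configuration")
  expect_error(ga_config(elite_count = 100, population_size = 10),
               class = "ssbn_configuration")
})

test_that("full-profile mode binds every candidate", {
  net <- random_net(7L, 90L, target_idx = 4L)
  tg <- bn_target(net)
  cands <- setdiff(bn_vars(net), tg)
  hyp <- stats::setNames(bn_states(net, tg)[1L], tg)
  res <- run_ga(net, hyp, cands, ga_config(seed = 8, generations = 20,
                                           allow_unset = FALSE))
  for (r in res$results) expect_length(r$explanation, length(cands))
  ex <- exhaustive_mre(net, hyp, cands, allow_unset = FALSE)
  expect_length(ex$explanation, length(cands))
})

test_that("what-if queries report the posterior shift of the target", {
  spec <- cohort_spec(n_sons = 3, n_spouses = 1, n_noise = 1)
  gt <- build_ground_truth(spec)
  # empty evidence: posterior equals prior
  w0 <- whatif(gt, NULL)
  expect_equal(w0$posterior, w0$prior, tolerance = 1e-12)
  expect_equal(w0$delta, 0, tolerance = 1e-12)
  expect_equal(w0$prior, 0.055, tolerance = 1e-9)
  # the stored high-risk profile raises the risk above the prior,
  # checked against the independent enumeration oracle
  prof <- attr(gt, "high_risk_profile")
  w1 <- whatif(gt, prof)
  expect_gt(w1$posterior, w1$prior)
  tab <- oracle_joint_table(gt)
  expect_equal(w1$posterior,
               oracle_posterior(tab, "depression", prof, c("no", "yes"))[["yes"]],
               tolerance = 1e-9)
  expect_error(whatif(gt, c(depression = "yes")), class = "ssbn_configuration")
})
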