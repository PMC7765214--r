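test_that("joint probability is the product of CPT entries", {
  # single uniform binary variable
  s1 <- bn_structure(list(bn_variable("X", c("0", "1"))))
  uni <- bayesian_network(s1, list(bn_cpt("X", character(0), matrix(c(0.5, 0.5), 1))))
  expect_identical(joint_probability(uni, c(X = "0")), 0.5)

  net <- toy_te_network()
  expect_equal(joint_probability(net, c(T = "1", E = "1")), 0.1 * 0.8)
  expect_equal(joint_probability(net, c(E = "0", T = "0")), 0.9 * 0.8)

  expect_error(joint_probability(net, c(T = "1")), class = "ssbn_incomplete_assignment")
  expect_error(joint_probability(net, c(T = "1", E = "2")), class = "ssbn_domain")
  expect_error(joint_probability(net, c(T = "1", E = "1", Z = "0")), class = "ssbn_domain")
})

test_that("joint probability matches the full-joint-table oracle on random nets", {
  for (seed in 1:5) {
    net <- random_net(5L, seed)
    tab <- oracle_joint_table(net)
    for (i in c(1L, 7L, nrow(tab))) {
      a <- unlist(tab[i, bn_vars(net)])
      expect_equal(joint_probability(net, a), tab$.p[i], tolerance = 1e-12)
    }
    # total probability over all full assignments
    expect_equal(sum(tab$.p), 1, tolerance = 1e-9)
  }
})

test_that("marginal likelihood sums completions and handles edge cases", {
  net <- toy_te_network()
  expect_identical(marginal_likelihood(net, NULL), 1)
  expect_identical(marginal_likelihood(net, character(0)), 1)
  expect_equal(marginal_likelihood(net, c(E = "1")), 0.26, tolerance = 1e-12)
  # full assignment degenerates to the joint
  expect_equal(marginal_likelihood(net, c(T = "1", E = "1")),
               joint_probability(net, c(T = "1", E = "1")), tolerance = 1e-15)
  expect_error(marginal_likelihood(net, c(Q = "1")), class = "ssbn_domain")
})

test_that("posterior matches Bayes rule on the tutorial net", {
  net <- toy_te_network()
  post <- posterior(net, "T", c(E = "1"))
  expect_equal(as.numeric(post), c(0.18 / 0.26, 0.08 / 0.26), tolerance = 1e-12)
  expect_equal(round(post[["1"]], 4), 0.3077)
  # empty evidence on a parentless query recovers the prior CPT row
  expect_equal(as.numeric(posterior(net, "T", NULL)), c(0.9, 0.1), tolerance = 1e-15)
})

test_that("variable elimination equals enumeration on random networks", {
  for (seed in 1:20) {
    net <- random_net(sample(4:8, 1) + 0L, seed * 11L)
    vars <- bn_vars(net)
    a <- random_full_assignment(net, seed)
    tab <- oracle_joint_table(net)
    q <- vars[1L]
    e <- a[vars[3:min(4, length(vars))]]
    ve <- posterior(net, q, e)
    br <- oracle_posterior(tab, q, e, bn_states(net, q))
    expect_lt(max(abs(as.numeric(ve) - br)), 1e-10)
    # in-package enumeration fallback agrees too
    en <- posterior_enumerate(net, q, e)
    expect_lt(max(abs(as.numeric(ve) - as.numeric(en))), 1e-10)
  }
})

test_that("evidence from a disconnected component leaves the prior untouched", {
  # two independent blocks: A -> B and C
  s <- bn_structure(
    list(bn_variable("A", c("0", "1")), bn_variable("B", c("0", "1")),
         bn_variable("C", c("0", "1"))),
    list(c("A", "B"))
  )
  net <- bayesian_network(s, list(
    bn_cpt("A", character(0), matrix(c(0.3, 0.7), 1)),
    bn_cpt("B", "A", matrix(c(0.9, 0.1, 0.4, 0.6), 2, byrow = TRUE)),
    bn_cpt("C", character(0), matrix(c(0.25, 0.75), 1))
  ))
  expect_equal(as.numeric(posterior(net, "A", c(C = "1"))),
               as.numeric(posterior(net, "A", NULL)), tolerance = 1e-12)
})

test_that("impossible evidence raises its own condition class", {
  s <- bn_structure(list(bn_variable("A", c("0", "1")), bn_variable("B", c("0", "1"))),
                    list(c("A", "B")))
  net <- bayesian_network(s, list(
    bn_cpt("A", character(0), matrix(c(1, 0), 1)),
    bn_cpt("B", "A", matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  ))
  # A = 1 has probability zero
  expect_error(posterior(net, "B", c(A = "1")), class = "ssbn_impossible_evidence")
  expect_error(posterior(net, "B", c(A = "x")), class = "ssbn_domain")
})

test_that("forward sampling is seeded, exact for degenerate CPTs, calibrated", {
  net <- toy_te_network()
  d1 <- forward_sample(net, 500, 42)
  d2 <- forward_sample(net, 500, 42)
  expect_identical(d1, d2)
  expect_false(identical(d1, forward_sample(net, 500, 43)))

  # deterministic CPTs force a single configuration
  s <- bn_structure(list(bn_variable("A", c("0", "1")), bn_variable("B", c("0", "1"))),
                    list(c("A", "B")))
  det <- bayesian_network(s, list(
    bn_cpt("A", character(0), matrix(c(0, 1), 1)),
    bn_cpt("B", "A", matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  ))
  dd <- forward_sample(det, 50, 1)
  expect_true(all(dd$A == "1" & dd$B == "1"))

  # empirical frequency within 3 binomial standard errors of the CPT value
  big <- forward_sample(net, 100000, 7)
  expect_lt(abs(mean(big$T == "1") - 0.1), 3 * sqrt(0.1 * 0.9 / 100000) + 1e-9)
  expect_lt(abs(mean(big$E == "1") - 0.26), 3 * sqrt(0.26 * 0.74 / 100000) + 1e-9)
})
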