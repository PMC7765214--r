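test_that("KL divergence handles identity, hand values and the infinite sentinel", {
  expect_identical(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)
  expect_equal(kl_divergence(c(0.75, 0.25), c(0.5, 0.5)),
               0.75 * log2(1.5) + 0.25 * log2(0.5), tolerance = 1e-12)
  expect_equal(round(kl_divergence(c(0.75, 0.25), c(0.5, 0.5)), 5), 0.18872)
  expect_identical(kl_divergence(c(0.5, 0.5), c(1, 0)), Inf)
  expect_error(kl_divergence(c(1, 0), c(0.5, 0.25, 0.25)), class = "ssbn_domain")
})

make_joint_data <- function(counts) {
  # exact empirical joint from a 2x2 count matrix
  data.frame(
    x = factor(rep(rep(c("0", "1"), each = 2), as.vector(t(counts)))),
    y = factor(rep(c("0", "1", "0", "1"), as.vector(t(counts))))
  )
}

test_that("mutual information matches direct evaluation of the empirical joint", {
  ind <- make_joint_data(matrix(c(250, 250, 250, 250), 2))
  expect_equal(mutual_information(ind, "x", "y"), 0, tolerance = 1e-12)

  det <- make_joint_data(matrix(c(500, 0, 0, 500), 2))
  expect_equal(mutual_information(det, "x", "y"), 1, tolerance = 1e-12)

  d <- make_joint_data(matrix(c(400, 100, 100, 400), 2))
  expect_equal(mutual_information(d, "x", "y"), 0.2780719, tolerance = 1e-6)

  const <- data.frame(x = factor(rep("0", 10), levels = c("0", "1")),
                      y = factor(rep(c("0", "1"), 5)))
  expect_warning(mi <- mutual_information(const, "x", "y"), "constant")
  expect_identical(mi, 0)
})

test_that("conditional MI: degenerate conditioning and closed-form recovery", {
  d <- make_joint_data(matrix(c(400, 100, 100, 400), 2))
  d$z <- factor(rep("a", nrow(d)))
  levels(d$z) <- c("a", "b")
  expect_warning(cmi <- conditional_mutual_information(d, "x", "y", "z"), NA)
  expect_equal(cmi, mutual_information(d, "x", "y"), tolerance = 1e-12)

  # x independent of y given z by construction: x,y both children of z only
  s <- bn_structure(list(bn_variable("z", c("0", "1")), bn_variable("x", c("0", "1")),
                         bn_variable("y", c("0", "1"))),
                    list(c("z", "x"), c("z", "y")))
  net <- bayesian_network(s, list(
    bn_cpt("z", character(0), matrix(c(0.5, 0.5), 1)),
    bn_cpt("x", "z", matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)),
    bn_cpt("y", "z", matrix(c(0.1, 0.9, 0.6, 0.4), 2, byrow = TRUE))
  ))
  big <- forward_sample(net, 100000, 11)
  expect_lt(conditional_mutual_information(big, "x", "y", "z"), 0.001)

  # closed-form CMI of a generating v-structure net, from its CPTs
  s2 <- bn_structure(list(bn_variable("z", c("0", "1")), bn_variable("x", c("0", "1")),
                          bn_variable("y", c("0", "1"))),
                     list(c("z", "x"), c("z", "y"), c("x", "y")))
  net2 <- bayesian_network(s2, list(
    bn_cpt("z", character(0), matrix(c(0.4, 0.6), 1)),
    bn_cpt("x", "z", matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)),
    bn_cpt("y", c("x", "z"), matrix(c(0.9, 0.1, 0.5, 0.5, 0.2, 0.8, 0.6, 0.4),
                                    4, byrow = TRUE))
  ))
  tab <- oracle_joint_table(net2)
  closed <- 0
  for (z in c("0", "1")) {
    pz <- sum(tab$.p[tab$z == z])
    for (x in c("0", "1")) for (y in c("0", "1")) {
      pxyz <- sum(tab$.p[tab$x == x & tab$y == y & tab$z == z]) / pz
      px <- sum(tab$.p[tab$x == x & tab$z == z]) / pz
      py <- sum(tab$.p[tab$y == y & tab$z == z]) / pz
      if (pxyz > 0) closed <- closed + pz * pxyz * log2(pxyz / (px * py))
    }
  }
  big2 <- forward_sample(net2, 100000, 13)
  expect_lt(abs(conditional_mutual_information(big2, "x", "y", "z") - closed), 0.01)
})

test_that("relative binary MI normalises by the target entropy", {
  d <- make_joint_data(matrix(c(400, 100, 100, 400), 2))
  expect_equal(relative_binary_mi(d, "x", "y"), 27.80719, tolerance = 1e-4)
  expect_equal(relative_binary_mi(make_joint_data(matrix(c(250, 250, 250, 250), 2)),
                                  "x", "y"), 0, tolerance = 1e-9)
  det <- make_joint_data(matrix(c(500, 0, 0, 500), 2))
  expect_equal(relative_binary_mi(det, "x", "y"), 100, tolerance = 1e-9)
  const <- data.frame(x = factor(c("0", "1")), y = factor(c("1", "1"), levels = c("0", "1")))
  expect_error(relative_binary_mi(const, "x", "y"), class = "ssbn_undefined_measure")
})

test_that("arc force equals empirical MI for a fitted two-node net and is never negative", {
  d <- make_joint_data(matrix(c(400, 100, 100, 400), 2))
  s <- bn_structure(list(bn_variable("x", c("0", "1")), bn_variable("y", c("0", "1"))),
                    list(c("x", "y")))
  net <- fit_parameters(s, d, smoothing = 0)
  af <- arc_force(net, d, c("x", "y"))
  expect_lt(abs(af$force - mutual_information(d, "x", "y")), 1e-9)

  # vacuous arc: identical child rows across the parent states
  net0 <- bayesian_network(s, list(
    bn_cpt("x", character(0), matrix(c(0.5, 0.5), 1)),
    bn_cpt("y", "x", matrix(c(0.3, 0.7, 0.3, 0.7), 2, byrow = TRUE))
  ))
  d0 <- forward_sample(net0, 5000, 3)
  expect_lt(arc_force(net0, d0, c("x", "y"))$force, 0.005)

  for (seed in 1:5) {
    net <- random_net(5L, seed * 7L)
    a <- bn_arcs(net)
    dd <- forward_sample(net, 2000, seed)
    af <- arc_force(net, dd, a[1L, ], smoothing = 1)
    expect_gte(af$force, 0)
  }
  expect_error(arc_force(net, dd, c("nope", "x")), class = "ssbn_domain")
})

test_that("state Bayes factors: hand value, independence, reciprocity", {
  net <- toy_te_network()
  expect_equal(state_bayes_factor(net, "E", "1", "1"), 4, tolerance = 1e-12)
  expect_equal(state_bayes_factor(net, "E", "1", "1") *
                 state_bayes_factor(net, "E", "1", "0"), 1, tolerance = 1e-12)

  s <- bn_structure(list(bn_variable("t", c("0", "1"), role = "target"),
                         bn_variable("x", c("0", "1"))))
  ind <- bayesian_network(s, list(
    bn_cpt("t", character(0), matrix(c(0.6, 0.4), 1)),
    bn_cpt("x", character(0), matrix(c(0.3, 0.7), 1))
  ))
  expect_equal(state_bayes_factor(ind, "x", "1", "1"), 1, tolerance = 1e-12)
})

test_that("target report mirrors the relevance table layout", {
  net <- build_ground_truth(cohort_spec(n_sons = 3, n_spouses = 1, n_noise = 1))
  d <- generate_cohort(net, 4000, 0, 21)
  rep <- target_report(net, d)
  expect_s3_class(rep, "data.frame")
  expect_setequal(rep$node, setdiff(bn_vars(net), "depression"))
  expect_true(all(rep$relative_binary_mi_pct >= 0 & rep$relative_binary_mi_pct <= 100))
  expect_true(all(rep$max_bf_neg >= rep$min_bf_neg))
  # the two target directions are explicit and reciprocal at the extremes:
  # the largest factor for "no" is the reciprocal of the smallest for "yes"
  expect_equal(rep$max_bf_neg, 1 / rep$min_bf_pos, tolerance = 1e-9)
  p <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, p)
  expect_identical(nrow(utils::read.csv(p)), nrow(rep))
})
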