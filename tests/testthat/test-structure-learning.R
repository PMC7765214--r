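test_that("parameter fitting follows Laplace arithmetic and its error contract", {
  s1 <- bn_structure(list(bn_variable("b", c("0", "1"))))
  even <- data.frame(b = factor(rep(c("0", "1"), 25)))
  expect_equal(as.numeric(fit_parameters(s1, even, smoothing = 0)$cpts$b$prob),
               c(0.5, 0.5))
  nine <- data.frame(b = factor(rep("0", 9), levels = c("0", "1")))
  expect_equal(as.numeric(fit_parameters(s1, nine, smoothing = 1)$cpts$b$prob),
               c(10 / 11, 1 / 11), tolerance = 1e-12)
  allna <- data.frame(b = factor(rep(NA_character_, 5), levels = c("0", "1")))
  expect_error(fit_parameters(s1, allna, smoothing = 0), class = "ssbn_estimation")
  expect_error(fit_parameters(s1, even[0, , drop = FALSE], smoothing = -1),
               class = "ssbn_configuration")
})

test_that("refitting on forward samples recovers the generating CPTs", {
  net <- random_net(6L, 31L)
  d <- forward_sample(net, 100000, 5)
  refit <- fit_parameters(net$structure, d, smoothing = 1)
  err <- max(vapply(bn_vars(net), function(v) {
    max(abs(refit$cpts[[v]]$prob - net$cpts[[v]]$prob))
  }, numeric(1)))
  expect_lte(err, 0.02)
})

test_that("naive Bayes topology and closed-form posterior", {
  spec <- cohort_spec(n_sons = 3, n_spouses = 0, n_noise = 0)
  gt <- build_ground_truth(spec)
  d <- generate_cohort(gt, 4000, 0, 2)
  nb <- learn_naive_bayes(d, "depression")
  a <- bn_arcs(nb)
  expect_identical(nrow(a), 3L)
  expect_true(all(a[, 1L] == "depression"))
  # posterior equals the hand product rule on an arbitrary record
  rec <- vapply(d[101L, setdiff(names(d), "depression")], as.character, character(1))
  odds <- as.numeric(nb$cpts$depression$prob)
  for (f in names(rec)) {
    si <- match(rec[[f]], bn_states(nb, f))
    odds <- odds * nb$cpts[[f]]$prob[, si]
  }
  expect_equal(as.numeric(posterior(nb, "depression", rec)),
               odds / sum(odds), tolerance = 1e-12)
  expect_error(learn_naive_bayes(d, "not_a_column"), class = "ssbn_configuration")
  # no features at all: target-only network
  solo <- learn_naive_bayes(d["depression"], "depression")
  expect_identical(bn_vars(solo), "depression")
})

test_that("TAN topology contract holds on sampled cohorts", {
  gt <- build_tan_ground_truth(5L, seed = 9L)
  d <- forward_sample(gt, 5000, 10)
  tan <- learn_tan(d, "class")
  feats <- setdiff(bn_vars(tan), "class")
  for (f in feats) {
    pa <- bn_parents(tan, f)
    expect_true("class" %in% pa)
    expect_lte(length(setdiff(pa, "class")), 1L)
  }
  # tree: exactly one feature (the root) has only the class as parent
  roots <- sum(vapply(feats, function(f) length(bn_parents(tan, f)) == 1L, logical(1)))
  expect_identical(roots, 1L)
  expect_error(learn_tan(d[c("class", "f01")], "class"), class = "ssbn_configuration")
})

test_that("TAN recovers a known generating tree skeleton", {
  gt <- build_tan_ground_truth(8L, seed = 41L)
  d <- forward_sample(gt, 20000, 42)
  tan <- learn_tan(d, "class")
  a <- bn_arcs(tan)
  fe <- a[a[, 1L] != "class", , drop = FALSE]
  skel <- sort(apply(fe, 1L, function(r) paste(sort(r), collapse = "-")))
  truth <- sort(apply(attr(gt, "tree"), 2L, paste, collapse = "-"))
  expect_identical(skel, truth)
})

test_that("independent features give TAN the naive Bayes fallback", {
  withr::with_seed(77, {
    d <- data.frame(t = factor(sample(c("0", "1"), 800, replace = TRUE)),
                    a = factor(sample(c("0", "1"), 800, replace = TRUE)),
                    b = factor(sample(c("0", "1"), 800, replace = TRUE)))
  })
  # weights are small but not exactly zero on finite data; the fallback
  # fires only for exact zeros, so the tree must still connect all features
  tan <- learn_tan(d, "t")
  feats <- setdiff(bn_vars(tan), "t")
  n_tree_arcs <- sum(bn_arcs(tan)[, 1L] != "t")
  expect_identical(n_tree_arcs, length(feats) - 1L)
})

test_that("sons-and-spouses recovery: sons in, noise out, spouses attached", {
  spec <- cohort_spec()
  gt <- build_ground_truth(spec)
  d <- generate_cohort(gt, 20000, 0, 71)
  ss <- learn_sons_and_spouses(d, "depression")
  sel <- select_features(ss)
  expect_true(all(attr(gt, "sons") %in% bn_children(ss, "depression")))
  expect_length(intersect(attr(gt, "noise"), sel), 0L)
  # the target never gains parents and spouses never touch the target
  expect_length(bn_parents(ss, "depression"), 0L)
  for (sp in intersect(attr(gt, "spouses"), bn_vars(ss))) {
    expect_false("depression" %in% bn_parents(ss, sp))
    expect_false(sp %in% bn_children(ss, "depression"))
  }
})

test_that("missing cells do not corrupt the greedy score", {
  # candidate arcs must be scored on a common record set: if the two
  # likelihoods were counted on different available-case subsets, merely
  # dropping incomplete rows would masquerade as a score improvement and
  # pull in noise variables
  gt <- build_ground_truth(cohort_spec())
  d <- generate_cohort(gt, 12000, 0.05, seed = 14)
  ss <- learn_sons_and_spouses(exclude_incomplete(d, 0.2)$data, "depression")
  sel <- select_features(ss)
  expect_length(intersect(attr(gt, "noise"), sel), 0L)
  expect_true(all(attr(gt, "sons") %in% bn_children(ss, "depression")))
})

test_that("sons are never dropped as the sample grows", {
  spec <- cohort_spec()
  gt <- build_ground_truth(spec)
  d <- generate_cohort(gt, 20000, 0, 99)
  sons_at <- lapply(c(2000L, 10000L, 20000L), function(n) {
    ss <- learn_sons_and_spouses(d[seq_len(n), , drop = FALSE], "depression")
    bn_children(ss, "depression")
  })
  expect_true(all(sons_at[[1L]] %in% sons_at[[2L]]))
  expect_true(all(sons_at[[2L]] %in% sons_at[[3L]]))
})

test_that("no-signal data yields the target-only network", {
  withr::with_seed(5, {
    d <- data.frame(t = factor(rep(c("0", "1"), each = 500)),
                    a = factor(sample(c("0", "1"), 1000, replace = TRUE)),
                    b = factor(sample(c("x", "y", "z"), 1000, replace = TRUE)))
  })
  ss <- learn_sons_and_spouses(d, "t")
  expect_identical(bn_vars(ss), "t")
  expect_identical(select_features(ss), character(0))
})

test_that("select_features returns children plus their other parents", {
  # star of 7 children, each first-6 with one dedicated extra parent pair:
  # 7 sons + 6 spouses = 13 selected, echoing the cohort topology
  sons <- sprintf("son%d", 1:7)
  spouses <- sprintf("spouse%d", 1:6)
  vars <- c(list(bn_variable("t", c("0", "1"), role = "target")),
            lapply(c(sons, spouses), function(v) bn_variable(v, c("0", "1"))))
  arcs <- c(lapply(sons, function(s) c("t", s)),
            lapply(1:6, function(i) c(spouses[i], sons[i])))
  s <- bn_structure(vars, arcs)
  expect_setequal(select_features(s), c(sons, spouses))
  expect_length(select_features(s), 13L)

  nb_like <- bn_structure(vars[1:4], lapply(sons[1:3], function(x) c("t", x)))
  expect_setequal(select_features(nb_like), sons[1:3])
  expect_error(select_features(bn_structure(list(bn_variable("a", c("0", "1"))))),
               class = "ssbn_configuration")
})

test_that("all learners return acyclic structures satisfying their contracts", {
  spec <- cohort_spec(n_sons = 3, n_spouses = 2, n_noise = 2)
  gt <- build_ground_truth(spec)
  d <- generate_cohort(gt, 6000, 0, 55)
  for (m in c("nb", "tan", "ss")) {
    net <- learn_network(d, "depression", m)
    expect_s3_class(net, "bayesian_network")   # construction validates acyclicity
    expect_identical(bn_target(net), "depression")
    expect_length(bn_parents(net, "depression"), 0L)
  }
})
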