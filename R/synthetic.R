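# Synthetic-cohort module: a ground-truth supervised network with known
# sons/spouses/noise partition, and a sampler that emulates the structure of
# a categorical health-survey extract (rare binary outcome, dependent
# categorical covariates, distractor variables, missing entries).

son_pool <- list(
  subjective_health = c("very_good", "good", "not_bad", "bad", "very_bad"),
  income_quartile   = c("low", "mid_low", "mid_high", "high"),
  marital_status    = c("married_together", "married_separated", "divorced",
                        "widowed", "unmarried"),
  economic_status   = c("yes", "no"),
  arthritis         = c("no", "yes"),
  gender            = c("male", "female"),
  diabetes          = c("no", "yes")
)
spouse_pool <- list(
  age                 = c("30s", "40s", "50s"),
  hypertension        = c("no", "yes"),
  glycated_hemoglobin = c("le6", "6_to_8", "gt8"),
  hemoglobin          = c("low", "normal", "high"),
  oral_examination    = c("no", "yes"),
  smoking             = c("non_smoker", "under_5_packs", "over_5_packs")
)
noise_pool <- list(
  bmi             = c("underweight", "normal", "overweight", "obese"),
  drinking        = c("never", "monthly", "weekly"),
  job_status      = c("no", "yes"),
  stroke          = c("no", "yes"),
  asthma          = c("no", "yes"),
  thyroid_disease = c("no", "yes")
)

pool_take <- function(pool, n, prefix, cards) {
  if (n <= length(pool)) return(pool[seq_len(n)])
  extra <- n - length(pool)
  more <- lapply(seq_len(extra), function(i) {
    k <- cards[(i - 1L) %% length(cards) + 1L]
    paste0("s", seq_len(k))
  })
  names(more) <- paste0(prefix, seq_len(extra))
  c(pool, more)
}

#' Specification of the synthetic cohort
#'
#' Defaults emulate a middle-aged health-survey extract: a rare binary
#' depression indicator (prevalence 5.5%), 7 direct risk factors ("sons",
#' children of the target), 6 co-parents of those risk factors ("spouses",
#' with no arc to the target), and 6 isolated distractor variables, with
#' cardinalities between 2 and 5.
#'
#' @param prevalence Target positive-state probability, in (0, 1)
#'   (default 0.055).
#' @param n_sons,n_spouses,n_noise Variable counts (defaults 7, 6, 6).
#' @param effect Minimum contrast between the target-positive and
#'   target-negative rows of every son CPT (default 0.3).
#' @param spouse_effect Contrast of a son's risk-state probability across
#'   its spouse's states, carried in the target-negative rows
#'   (default 0.25).
#' @param risk_lo Risk-state probability of a son in the target-negative
#'   baseline row (default 0.15).
#' @param risk_hi Risk-state probability of a son in the target-positive
#'   rows (default 0.93). Kept high because with a rare target those CPT
#'   rows are informed by few records; weak positive-row signal would make
#'   the cohort's parameters unestimable at realistic sample sizes, and the
#'   strong separation matches the large explanation Bayes factors this
#'   kind of risk model is built to surface.
#' @param missing_rate Default cell-level missingness for
#'   [generate_cohort()] (completely at random).
#' @param seed Seed fixing the randomly drawn CPT entries of the ground
#'   truth.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(prevalence = 0.055, n_sons = 7L, n_spouses = 6L,
                        n_noise = 6L, effect = 0.3, spouse_effect = 0.25,
                        risk_lo = 0.15, risk_hi = 0.93, missing_rate = 0,
                        seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) {
    ssbn_stop("specification", "prevalence must lie in (0, 1)")
  }
  if (effect < 0 || spouse_effect < 0) {
    ssbn_stop("specification", "effect sizes must be >= 0")
  }
  if (min(n_sons, n_spouses, n_noise) < 0) {
    ssbn_stop("specification", "variable counts must be >= 0")
  }
  if (n_spouses > 0L && n_sons == 0L) {
    ssbn_stop("specification", "spouses need at least one son to attach to")
  }
  if (risk_hi - (risk_lo + spouse_effect) < effect) {
    ssbn_stop("specification",
              "infeasible effect sizes: risk_hi - (risk_lo + spouse_effect) = %.3f < effect = %.3f",
              risk_hi - (risk_lo + spouse_effect), effect)
  }
  if (risk_hi >= 1 || risk_lo + spouse_effect >= 1) {
    ssbn_stop("specification", "risk-state probabilities must stay below 1")
  }
  structure(list(prevalence = prevalence, n_sons = as.integer(n_sons),
                 n_spouses = as.integer(n_spouses), n_noise = as.integer(n_noise),
                 effect = effect, spouse_effect = spouse_effect,
                 risk_lo = risk_lo, risk_hi = risk_hi,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Build the ground-truth cohort network
#'
#' Constructs the known generating network for the synthetic cohort:
#' `depression` (binary, states no/yes, role target) with the configured
#' prevalence; sons as children of the target whose CPTs concentrate
#' `risk_hi` mass on a randomly chosen risk state in the target-positive
#' rows; spouses as additional parents of distinct sons (no arc to the
#' target) modulating the target-negative rows; and isolated noise
#' variables. The attribute `high_risk_profile` stores the
#' single-state-per-son assignment with the maximal target posterior
#' (exact, since sons have disjoint spouse sets given the target).
#'
#' @param spec A [cohort_spec()].
#' @return A [bayesian_network()] with attributes `high_risk_profile`,
#'   `sons`, `spouses`, `noise`.
#' @export
build_ground_truth <- function(spec = cohort_spec()) {
  sons <- pool_take(son_pool, spec$n_sons, "son", 2:5)
  spouses <- pool_take(spouse_pool, spec$n_spouses, "spouse", 2:3)
  noise <- pool_take(noise_pool, spec$n_noise, "noise", 2:5)
  target <- "depression"

  vars <- c(list(bn_variable(target, c("no", "yes"), role = "target")),
            lapply(names(sons), function(v) bn_variable(v, sons[[v]])),
            lapply(names(spouses), function(v) bn_variable(v, spouses[[v]])),
            lapply(names(noise), function(v) bn_variable(v, noise[[v]])))

  # spouse i modulates son ((i - 1) mod n_sons) + 1: disjoint spouse sets
  spouse_of <- if (spec$n_spouses > 0L) {
    split(names(spouses), ((seq_len(spec$n_spouses) - 1L) %% spec$n_sons) + 1L)
  } else list()

  arcs <- list()
  for (s in names(sons)) arcs[[length(arcs) + 1L]] <- c(target, s)
  for (j in seq_along(spouse_of)) {
    son <- names(sons)[as.integer(names(spouse_of)[j])]
    for (sp in spouse_of[[j]]) arcs[[length(arcs) + 1L]] <- c(sp, son)
  }
  s <- bn_structure(vars, arcs)

  with_seed(spec$seed, {
    cpts <- list(bn_cpt(target, character(0),
                        matrix(c(1 - spec$prevalence, spec$prevalence), 1L)))
    rand_simplex <- function(k) { g <- stats::runif(k, 0.5, 1.5); g / sum(g) }
    for (sp in names(spouses)) {
      cpts[[length(cpts) + 1L]] <- bn_cpt(sp, character(0),
                                          matrix(rand_simplex(length(spouses[[sp]])), 1L))
    }
    for (nv in names(noise)) {
      cpts[[length(cpts) + 1L]] <- bn_cpt(nv, character(0),
                                          matrix(rand_simplex(length(noise[[nv]])), 1L))
    }
    for (i in seq_along(sons)) {
      son <- names(sons)[i]
      k <- length(sons[[son]])
      pa <- structure_parents(s, son)           # (target, spouses...) sorted by bn_structure? no: declared order
      # bn_structure canonicalises arcs by (child, parent); recover parent order:
      pa <- pa                                   # order as stored
      sp_pa <- setdiff(pa, target)
      cardp <- vapply(pa, function(p) length(if (p == target) c("no", "yes") else spouses[[p]]), integer(1))
      nr <- prod(cardp)
      r <- sample.int(k, 1L)                     # risk state
      w <- rand_simplex(k - 1L)                  # shape of the non-risk mass
      pm <- arrayInd(seq_len(nr), rev(cardp))[, rev(seq_along(pa)), drop = FALSE]
      prob <- matrix(0, nr, k)
      for (row in seq_len(nr)) {
        t_yes <- pm[row, match(target, pa)] == 2L
        z <- 0
        if (length(sp_pa) > 0L) {
          zs <- vapply(sp_pa, function(p) {
            cs <- cardp[[match(p, pa)]]
            if (cs > 1L) (pm[row, match(p, pa)] - 1L) / (cs - 1L) else 0
          }, numeric(1))
          z <- mean(zs)
        }
        p_r <- if (t_yes) spec$risk_hi else spec$risk_lo + spec$spouse_effect * z
        prob[row, r] <- p_r
        prob[row, -r] <- (1 - p_r) * w
      }
      cpts[[length(cpts) + 1L]] <- bn_cpt(son, pa, prob)
    }
  })
  net <- bayesian_network(s, cpts)

  # exact high-risk profile: sons are conditionally independent given the
  # target (disjoint spouse sets), so the per-son likelihood-ratio argmax is
  # the joint argmax
  profile <- vapply(names(sons), function(son) {
    states <- bn_states(net, son)
    ratios <- vapply(states, function(st) {
      num <- posterior(net, son, c(depression = "yes"))[[st]]
      den <- posterior(net, son, c(depression = "no"))[[st]]
      if (den == 0) Inf else num / den
    }, numeric(1))
    states[which.max(ratios)]
  }, character(1))

  attr(net, "high_risk_profile") <- profile
  attr(net, "sons") <- names(sons)
  attr(net, "spouses") <- names(spouses)
  attr(net, "noise") <- names(noise)
  net
}

#' Sample a synthetic cohort
#'
#' Forward-samples `n` records from the network and masks each cell
#' independently (missing completely at random) with probability
#' `missing_rate`.
#'
#' @param net A [bayesian_network()], typically [build_ground_truth()].
#' @param n Number of records.
#' @param missing_rate Cell-level masking probability in \[0, 1).
#' @param seed Integer seed.
#' @param eq5d If `TRUE`, the target column is emitted on a three-level
#'   scale (`none`/`some`/`extreme`): positive records are split between
#'   `some` and `extreme`, emulating the instrument level from which a
#'   binary indicator is merged. Use [merge_states()] to binarize.
#' @return A `data.frame` of factor columns with `NA` for masked cells.
#' @export
generate_cohort <- function(net, n, missing_rate = 0, seed = 1L, eq5d = FALSE) {
  if (missing_rate < 0 || missing_rate >= 1) {
    ssbn_stop("specification", "missing_rate must lie in [0, 1)")
  }
  seeds <- derive_seeds(seed, 3L)
  data <- forward_sample(net, n, seeds[1L])
  if (eq5d) {
    target <- bn_target(net)
    if (is.null(target)) ssbn_stop("configuration", "eq5d = TRUE needs a target")
    pos <- bn_states(net, target)[2L]
    lev3 <- c("none", "some", "extreme")
    raw <- ifelse(as.character(data[[target]]) == pos, "some", "none")
    with_seed(seeds[2L], {
      ispos <- raw == "some"
      raw[ispos][stats::runif(sum(ispos)) < 0.2] <- "extreme"
    })
    data[[target]] <- factor(raw, levels = lev3)
  }
  if (missing_rate > 0) {
    with_seed(seeds[3L], {
      for (v in names(data)) {
        data[[v]][stats::runif(n) < missing_rate] <- NA
      }
    })
  }
  data
}

#' Merge several states of a column into one
#'
#' Collapses the given states to a single label, e.g. merging the
#' `some`/`extreme` levels of a three-level instrument item into a binary
#' present/absent indicator.
#'
#' @param data A data frame.
#' @param column Column to collapse.
#' @param states States to merge.
#' @param into Replacement label for the merged states.
#' @param rest Optional label replacing all remaining states.
#' @return `data` with the column recoded (factor; `into` is the last
#'   level).
#' @export
merge_states <- function(data, column, states, into, rest = NULL) {
  check_columns(data, column)
  x <- as.character(data[[column]])
  out <- x
  out[x %in% states] <- into
  if (!is.null(rest)) out[!(x %in% states) & !is.na(x)] <- rest
  lev <- c(setdiff(unique(stats::na.omit(out)), into), into)
  data[[column]] <- factor(out, levels = lev)
  data
}

#' Exclude records with too many missing values
#'
#' Drops every record whose fraction of missing columns strictly exceeds
#' `max_missing_fraction`, reporting how many records were kept and
#' excluded.
#'
#' @param data A data frame.
#' @param max_missing_fraction Threshold in \[0, 1\] (default 0.2).
#' @return List: `data` (retained records), `retained`, `excluded`.
#' @export
exclude_incomplete <- function(data, max_missing_fraction = 0.2) {
  frac <- rowMeans(is.na(data))
  keep <- frac <= max_missing_fraction
  list(data = data[keep, , drop = FALSE],
       retained = sum(keep), excluded = sum(!keep))
}

#' Build a ground-truth TAN network
#'
#' A tree-augmented classifier with known structure for recovery
#' experiments: a binary class, `n_features` categorical features each
#' having the class plus (root excepted) one feature parent along a random
#' spanning tree, and CPT row contrasts of at least `effect` across both
#' the class and the feature parent.
#'
#' @param n_features Number of features (>= 2).
#' @param cards Cardinalities recycled over the features (default 2:3).
#' @param effect Minimum row contrast (default 0.35).
#' @param seed Seed for the tree shape, risk states and CPT entries.
#' @return A [bayesian_network()] with attribute `tree` (undirected feature
#'   edges of the generating spanning tree, each column-sorted).
#' @export
build_tan_ground_truth <- function(n_features = 8L, cards = 2:3,
                                   effect = 0.35, seed = 1L) {
  if (n_features < 2L) ssbn_stop("specification", "need at least 2 features")
  feats <- sprintf("f%02d", seq_len(n_features))
  kk <- rep_len(cards, n_features)
  vars <- c(list(bn_variable("class", c("neg", "pos"), role = "target")),
            lapply(seq_len(n_features), function(i) {
              bn_variable(feats[i], paste0("s", seq_len(kk[i])))
            }))
  with_seed(seed, {
    # random tree: each non-root attaches to a uniformly drawn earlier node
    parent_feat <- c(NA_integer_,
                     vapply(2:n_features, function(i) sample.int(i - 1L, 1L), integer(1)))
    arcs <- lapply(feats, function(f) c("class", f))
    for (i in 2:n_features) {
      arcs[[length(arcs) + 1L]] <- c(feats[parent_feat[i]], feats[i])
    }
    s <- bn_structure(vars, arcs)
    cpts <- list(bn_cpt("class", character(0), matrix(c(0.5, 0.5), 1L)))
    for (i in seq_len(n_features)) {
      f <- feats[i]
      pa <- structure_parents(s, f)
      cardp <- vapply(pa, function(p) length(s$variables[[p]]$states), integer(1))
      nr <- prod(cardp)
      k <- kk[i]
      r <- sample.int(k, 1L)
      w <- if (k > 1L) { g <- stats::runif(k - 1L, 0.5, 1.5); g / sum(g) } else numeric(0)
      pm <- arrayInd(seq_len(nr), rev(cardp))[, rev(seq_along(pa)), drop = FALSE]
      prob <- matrix(0, nr, k)
      for (row in seq_len(nr)) {
        cls_pos <- pm[row, match("class", pa)] == 2L
        z <- 0
        fp <- setdiff(pa, "class")
        if (length(fp) == 1L) {
          cs <- cardp[[match(fp, pa)]]
          z <- if (cs > 1L) (pm[row, match(fp, pa)] - 1L) / (cs - 1L) else 0
        }
        p_r <- 0.1 + effect * as.numeric(cls_pos) + effect * z
        prob[row, r] <- p_r
        prob[row, -r] <- (1 - p_r) * w
      }
      cpts[[length(cpts) + 1L]] <- bn_cpt(f, pa, prob)
    }
    net <- bayesian_network(s, cpts)
    tree <- vapply(2:n_features, function(i) {
      sort(c(feats[parent_feat[i]], feats[i]))
    }, character(2))
    attr(net, "tree") <- tree
    net
  })
}
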