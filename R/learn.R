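#' Learner configuration
#'
#' @param smoothing Pseudo-count added to every CPT cell (Laplace; default 1).
#' @param max_parents Maximum number of parents per node, the target
#'   included (default 3).
#' @param score Structure score for the Sons-and-Spouses greedy search; only
#'   `"BIC"` is implemented.
#' @param mi_threshold Minimum relative binary mutual information with the
#'   target (percent) for a feature to be admitted as a candidate child in
#'   the Sons-and-Spouses search (default 0.1).
#' @param max_missing Records whose fraction of missing columns exceeds this
#'   are excluded before learning (default 0.2).
#' @param seed Integer seed (reserved; the learners themselves are
#'   deterministic).
#' @return A list of class `learner_config`.
#' @export
learner_config <- function(smoothing = 1, max_parents = 3L, score = "BIC",
                           mi_threshold = 0.1, max_missing = 0.2, seed = 1L) {
  if (smoothing < 0) ssbn_stop("configuration", "smoothing must be >= 0")
  if (max_parents < 1L) ssbn_stop("configuration", "max_parents must be >= 1")
  score <- match.arg(score, "BIC")
  structure(list(smoothing = smoothing, max_parents = as.integer(max_parents),
                 score = score, mi_threshold = mi_threshold,
                 max_missing = max_missing, seed = as.integer(seed)),
            class = "learner_config")
}

# variables implied by a data frame's factor columns
data_variables <- function(data, target = NULL) {
  lapply(names(data), function(v) {
    col <- data[[v]]
    states <- if (is.factor(col)) levels(col) else sort(unique(stats::na.omit(as.character(col))))
    bn_variable(v, states, role = if (identical(v, target)) "target" else "feature")
  })
}

as_declared_factors <- function(data, structure) {
  for (v in intersect(names(data), names(structure$variables))) {
    data[[v]] <- factor(data[[v]], levels = structure$variables[[v]]$states)
  }
  data
}

# family counts in CPT layout; returns list(counts matrix [config x state], n)
family_counts <- function(data, structure, child) {
  pa <- structure_parents(structure, child)
  cols <- c(child, pa)
  sub <- data[cols]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  cc <- length(structure$variables[[child]]$states)
  cardp <- vapply(pa, function(p) length(structure$variables[[p]]$states), integer(1))
  nr <- max(1L, prod(cardp))
  cnt_vec <- as.vector(table(sub))  # column-major over (child, parents...)
  if (length(pa) == 0L) {
    m <- matrix(cnt_vec, nrow = 1L)
  } else {
    pm <- arrayInd(seq_len(nr), rev(cardp))[, rev(seq_along(pa)), drop = FALSE]
    off <- integer(nr)
    stride <- 1L
    for (j in seq_along(pa)) {
      off <- off + (pm[, j] - 1L) * stride * cc
      stride <- stride * cardp[j]
    }
    m <- matrix(cnt_vec[as.vector(outer(seq_len(cc), off, "+"))],
                nrow = nr, byrow = TRUE)
  }
  list(counts = m, n = nrow(sub))
}

#' Estimate CPT parameters for a fixed structure
#'
#' Maximum a-posteriori estimation with a symmetric Dirichlet prior
#' (pseudo-count `smoothing` per cell): each CPT entry is
#' (count + smoothing) / (row total + smoothing * cardinality). Counting is
#' available-case: a record is used for a family if it is complete for that
#' family's child and parents, regardless of other columns.
#'
#' @param structure A [bn_structure()] whose variables are covered by
#'   `data`'s columns.
#' @param data Data frame of factor columns (`NA` = missing).
#' @param smoothing Pseudo-count >= 0.
#' @return A [bayesian_network()].
#' @export
fit_parameters <- function(structure, data, smoothing = 1) {
  if (smoothing < 0) ssbn_stop("configuration", "smoothing must be >= 0")
  vars <- names(structure$variables)
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0L) {
    ssbn_stop("configuration", "data lacks column(s): %s", paste(miss, collapse = ", "))
  }
  data <- as_declared_factors(data, structure)
  cpts <- lapply(vars, function(v) {
    fc <- family_counts(data, structure, v)
    m <- fc$counts
    cc <- ncol(m)
    if (fc$n == 0L && smoothing == 0) {
      ssbn_stop("estimation",
                "no complete records for family of '%s' and smoothing is 0", v)
    }
    num <- m + smoothing
    den <- rowSums(m) + smoothing * cc
    empty <- den == 0
    if (any(empty)) {
      # unseen parent configuration with smoothing 0: fall back to uniform
      warning(sprintf("family of '%s': %d unseen parent configuration(s) set to uniform",
                      v, sum(empty)))
      num[empty, ] <- 1
      den[empty] <- cc
    }
    bn_cpt(v, structure_parents(structure, v), num / den)
  })
  bayesian_network(structure, cpts)
}

prepare_training_data <- function(data, target, config) {
  if (!target %in% names(data)) {
    ssbn_stop("configuration", "target column '%s' not present in data", target)
  }
  excl <- exclude_incomplete(data, config$max_missing)
  excl$data
}

#' Learn a Naive Bayes network
#'
#' Every feature column becomes a child of the target with no other parents;
#' parameters are estimated with [fit_parameters()].
#'
#' @param data Data frame of factor columns, one being the target.
#' @param target Target column name.
#' @param config A [learner_config()].
#' @return A [bayesian_network()] with the target marked as such.
#' @export
learn_naive_bayes <- function(data, target, config = learner_config()) {
  data <- prepare_training_data(data, target, config)
  feats <- setdiff(names(data), target)
  arcs <- if (length(feats) > 0L) lapply(feats, function(f) c(target, f)) else NULL
  s <- bn_structure(data_variables(data, target), arcs)
  fit_parameters(s, data, config$smoothing)
}

# deterministic Kruskal maximum spanning tree; edges: data.frame(a, b, w)
# with a < b; ties broken by (a, b) lexicographically
max_spanning_tree <- function(nodes, edges) {
  edges <- edges[order(-edges$w, edges$a, edges$b), , drop = FALSE]
  comp <- stats::setNames(seq_along(nodes), nodes)
  picked <- list()
  for (i in seq_len(nrow(edges))) {
    ca <- comp[[edges$a[i]]]; cb <- comp[[edges$b[i]]]
    if (ca != cb) {
      comp[comp == cb] <- ca
      picked[[length(picked) + 1L]] <- c(edges$a[i], edges$b[i])
    }
  }
  picked
}

#' Learn a Tree-Augmented Naive Bayes (TAN) network
#'
#' Builds the maximum-weight spanning tree over the features with edge
#' weights I(x; y | target) (conditional mutual information, bits), directs
#' the tree outward from the feature with the highest mutual information
#' with the target, and adds the target as a parent of every feature. Every
#' feature therefore has the target plus at most one feature parent.
#'
#' Spanning-tree and root ties are broken lexicographically by variable
#' name, so the learned structure is a deterministic function of the data.
#' If all pairwise weights are (numerically) zero the Naive Bayes structure
#' is returned with a warning.
#'
#' @inheritParams learn_naive_bayes
#' @return A [bayesian_network()].
#' @export
learn_tan <- function(data, target, config = learner_config()) {
  data <- prepare_training_data(data, target, config)
  feats <- sort(setdiff(names(data), target))
  if (length(feats) < 2L) {
    ssbn_stop("configuration", "TAN needs at least 2 features")
  }
  pairs <- utils::combn(feats, 2L)
  edges <- data.frame(a = pairs[1L, ], b = pairs[2L, ],
                      w = apply(pairs, 2L, function(p) {
                        conditional_mutual_information(data, p[1L], p[2L], target)
                      }), stringsAsFactors = FALSE)
  if (all(edges$w < 1e-12)) {
    warning("all conditional MI weights are zero; returning the Naive Bayes structure")
    return(learn_naive_bayes(data, target, config))
  }
  tree <- max_spanning_tree(feats, edges)
  mi_t <- vapply(feats, function(f) mutual_information(data, f, target), numeric(1))
  root <- sort(feats[mi_t == max(mi_t)])[1L]
  # orient edges outward from the root (BFS)
  adj <- lapply(stats::setNames(feats, feats), function(...) character(0))
  for (e in tree) {
    adj[[e[1L]]] <- c(adj[[e[1L]]], e[2L])
    adj[[e[2L]]] <- c(adj[[e[2L]]], e[1L])
  }
  arcs <- lapply(feats, function(f) c(target, f))
  visited <- root
  queue <- root
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in sort(adj[[v]])) {
      if (!u %in% visited) {
        arcs[[length(arcs) + 1L]] <- c(v, u)
        visited <- c(visited, u)
        queue <- c(queue, u)
      }
    }
  }
  s <- bn_structure(data_variables(data, target), arcs)
  fit_parameters(s, data, config$smoothing)
}

# BIC log-likelihood of child | parents from a joint count table whose
# first dimension is the child
ll_from_counts <- function(tab, child_dim = 1L) {
  d <- dim(tab)
  if (length(d) <= 1L) {
    tot <- sum(tab)
    pos <- tab > 0
    return(sum(tab[pos] * log(tab[pos] / tot)))
  }
  totals <- apply(tab, seq_along(d)[-child_dim], sum)
  tot_exp <- array(rep(as.vector(totals), each = d[child_dim]), dim = d)
  pos <- tab > 0
  sum(tab[pos] * log(tab[pos] / tot_exp[pos]))
}

# BIC improvement of adding parent u to child's family, with both models
# counted on the same records (complete for child, current parents and u);
# available-case deltas computed on differing row sets would reward the
# mere loss of incomplete rows
family_bic_delta <- function(data, child, pa, u, cards) {
  cols <- c(child, pa, u)
  sub <- data[cols]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  n <- nrow(sub)
  if (n == 0L) return(-Inf)
  tab <- table(sub)                      # dims: child, pa..., u
  ll_with <- ll_from_counts(tab)
  tab_wo <- if (length(dim(tab)) > 2L) {
    apply(tab, seq_along(dim(tab))[-length(dim(tab))], sum)
  } else {
    apply(tab, 1L, sum)
  }
  ll_without <- ll_from_counts(tab_wo)
  cc <- cards[[child]]
  k_pa <- if (length(pa) == 0L) 1L else prod(unlist(cards[pa]))
  extra_params <- k_pa * (cards[[u]] - 1L) * (cc - 1L)
  (ll_with - ll_without) - 0.5 * log(n) * extra_params
}

#' Learn a Sons-and-Spouses network
#'
#' Supervised structure learning around a binary target: the learned network
#' consists of the target, a subset of features as its children ("sons"),
#' and further parents of those children ("spouses", which may themselves be
#' sons or plain co-parents but never have an arc to or from the target).
#' Features connected to nothing are dropped, so the method doubles as
#' feature selection.
#'
#' The search is a deterministic greedy BIC forward selection: features
#' whose relative binary mutual information with the target exceeds
#' `config$mi_threshold` are candidate sons; arcs are added one at a time
#' from the legal set \{target -> candidate son, feature -> son\} picking
#' the largest BIC improvement (ties broken lexicographically by child then
#' parent) until no arc improves the score, subject to `max_parents` and
#' acyclicity.
#'
#' @inheritParams learn_naive_bayes
#' @return A [bayesian_network()] over the selected variables only.
#' @export
learn_sons_and_spouses <- function(data, target, config = learner_config()) {
  data <- prepare_training_data(data, target, config)
  tcol <- data[[target]]
  if (!is.factor(tcol)) tcol <- factor(tcol)
  if (nlevels(tcol) != 2L) {
    ssbn_stop("configuration", "Sons-and-Spouses requires a binary target")
  }
  feats <- sort(setdiff(names(data), target))
  allvars <- data_variables(data, target)
  names(allvars) <- vapply(allvars, function(v) v$name, character(1))
  data <- as_declared_factors(data, bn_structure(allvars))

  rbmi <- vapply(feats, function(f) relative_binary_mi(data, f, target), numeric(1))
  cand_sons <- feats[rbmi > config$mi_threshold]

  parents <- lapply(stats::setNames(feats, feats), function(...) character(0))
  cards <- lapply(stats::setNames(c(feats, target), c(feats, target)),
                  function(v) length(allvars[[v]]$states))
  cache <- new.env(parent = emptyenv())
  arc_delta <- function(child, pa, u) {
    key <- paste(child, paste(sort(pa), collapse = "|"), u, sep = "::")
    if (exists(key, envir = cache, inherits = FALSE)) {
      return(get(key, envir = cache, inherits = FALSE))
    }
    val <- family_bic_delta(data, child, pa, u, cards)
    assign(key, val, envir = cache)
    val
  }
  feature_arcs <- function() {
    out <- list()
    for (c in feats) for (p in setdiff(parents[[c]], target)) {
      out[[length(out) + 1L]] <- c(p, c)
    }
    out
  }
  creates_cycle <- function(u, c) {
    arcs <- c(feature_arcs(), list(c(u, c)))
    is.null(topological_order(feats, normalize_arcs(arcs)))
  }

  repeat {
    sons <- feats[vapply(feats, function(f) target %in% parents[[f]], logical(1))]
    moves <- list()
    for (f in setdiff(cand_sons, sons)) {
      if (length(parents[[f]]) >= config$max_parents) next
      delta <- arc_delta(f, parents[[f]], target)
      moves[[length(moves) + 1L]] <- list(parent = target, child = f, delta = delta)
    }
    for (c in sons) {
      if (length(parents[[c]]) >= config$max_parents) next
      for (u in setdiff(feats, c(c, parents[[c]]))) {
        if (creates_cycle(u, c)) next
        delta <- arc_delta(c, parents[[c]], u)
        moves[[length(moves) + 1L]] <- list(parent = u, child = c, delta = delta)
      }
    }
    if (length(moves) == 0L) break
    deltas <- vapply(moves, `[[`, numeric(1), "delta")
    if (max(deltas) <= 1e-9) break
    best <- moves[deltas == max(deltas)]
    ord <- order(vapply(best, `[[`, character(1), "child"),
                 vapply(best, `[[`, character(1), "parent"))
    mv <- best[[ord[1L]]]
    parents[[mv$child]] <- c(parents[[mv$child]], mv$parent)
  }

  connected <- unique(c(unlist(parents), names(Filter(function(p) length(p) > 0L, parents))))
  keep <- c(target, intersect(feats, connected))
  arcs <- list()
  for (c in feats) for (p in parents[[c]]) arcs[[length(arcs) + 1L]] <- c(p, c)
  s <- bn_structure(allvars[keep], arcs)
  fit_parameters(s, data[keep], config$smoothing)
}

#' Selected variable set of a supervised network
#'
#' The children of the target ("sons") together with all other parents of
#' those children ("spouses"), the target excluded.
#'
#' @param net A [bayesian_network()] or [bn_structure()].
#' @param target Target variable name (default: the declared target).
#' @return Character vector of variable names.
#' @export
select_features <- function(net, target = bn_target(net)) {
  if (is.null(target) || !target %in% bn_vars(net)) {
    ssbn_stop("configuration", "network has no target variable '%s'",
              target %||% "<none>")
  }
  sons <- bn_children(net, target)
  spouses <- unique(unlist(lapply(sons, function(s) bn_parents(net, s))))
  sort(setdiff(unique(c(sons, spouses)), target))
}

#' Dispatch a structure learner by name
#'
#' @inheritParams learn_naive_bayes
#' @param method `"nb"`, `"tan"` or `"ss"`.
#' @return A [bayesian_network()].
#' @export
learn_network <- function(data, target, method = c("ss", "tan", "nb"),
                          config = learner_config()) {
  method <- match.arg(method)
  switch(method,
         nb = learn_naive_bayes(data, target, config),
         tan = learn_tan(data, target, config),
         ss = learn_sons_and_spouses(data, target, config))
}
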