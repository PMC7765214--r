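# Information-theoretic measures. Everything is base-2: divergences, mutual
# information and entropies are reported in bits.

#' Kullback-Leibler divergence between two discrete distributions
#'
#' D(p || q) = sum_s p(s) * log2(p(s) / q(s)). Terms with p(s) = 0 contribute
#' nothing; a state with p(s) > 0 but q(s) = 0 makes the divergence infinite,
#' reported as the sentinel `Inf` rather than an error.
#'
#' @param p,q Distributions over the same ordered states: numeric vectors of
#'   equal length or [posterior()] results.
#' @return Divergence in bits (>= 0, possibly `Inf`).
#' @examples
#' kl_divergence(c(0.75, 0.25), c(0.5, 0.5))  # 0.18872 bits
#' @export
kl_divergence <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) {
    ssbn_stop("domain", "p and q must be over the same state space")
  }
  pos <- p > 0
  if (any(pos & q == 0)) return(Inf)
  sum(p[pos] * log2(p[pos] / q[pos]))
}

entropy_bits <- function(p) {
  p <- as.numeric(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# empirical joint of columns `cols` over rows complete for them, as a
# probability array; factors must carry the declared levels
empirical_joint <- function(data, cols) {
  sub <- data[cols]
  for (v in cols) {
    if (!is.factor(sub[[v]])) sub[[v]] <- factor(sub[[v]])
  }
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  if (nrow(sub) == 0L) ssbn_stop("estimation", "no complete rows for {%s}",
                                 paste(cols, collapse = ", "))
  tab <- table(sub)
  tab / sum(tab)
}

mi_from_joint <- function(joint) {
  px <- rowSums(joint)
  py <- colSums(joint)
  pos <- joint > 0
  prod_marg <- outer(px, py)
  sum(joint[pos] * log2(joint[pos] / prod_marg[pos]))
}

#' Empirical mutual information between two columns
#'
#' Base-2 mutual information of the empirical joint distribution of `x` and
#' `y`, computed on rows complete for both columns. Equal to the KL
#' divergence between the joint and the product of its marginals.
#'
#' @param data A data frame of categorical columns (factors; `NA` = missing).
#' @param x,y Column names.
#' @return Mutual information in bits (>= 0). A constant column yields 0
#'   with a warning.
#' @export
mutual_information <- function(data, x, y) {
  check_columns(data, c(x, y))
  joint <- empirical_joint(data, c(x, y))
  if (any(dim(joint) == 1L) || any(rowSums(joint) == 1) || any(colSums(joint) == 1)) {
    warning(sprintf("column '%s' or '%s' is constant on complete rows; MI = 0", x, y))
    return(0)
  }
  max(0, mi_from_joint(joint))
}

#' Conditional mutual information I(x; y | z)
#'
#' sum_z P(z) * I(x; y | Z = z) on rows complete for all three columns, in
#' bits. This is the edge weight used by the tree-augmented structure
#' learner, with z the class variable.
#'
#' @inheritParams mutual_information
#' @param z Conditioning column name.
#' @return Conditional mutual information in bits (>= 0).
#' @export
conditional_mutual_information <- function(data, x, y, z) {
  check_columns(data, c(x, y, z))
  joint <- empirical_joint(data, c(x, y, z))
  pz <- apply(joint, 3L, sum)
  cmi <- 0
  for (k in seq_along(pz)) {
    if (pz[k] == 0) next
    cmi <- cmi + pz[k] * mi_from_joint(joint[, , k] / pz[k])
  }
  max(0, cmi)
}

check_columns <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0L) {
    ssbn_stop("domain", "column(s) not in data: %s", paste(miss, collapse = ", "))
  }
}

#' Relative binary mutual information with the target (percent)
#'
#' 100 * I(x; target) / H(target): the share of the (binary) target's
#' entropy explained by `x`. This is the per-node relevance measure reported
#' alongside the learned network.
#'
#' @inheritParams mutual_information
#' @param target Binary target column name.
#' @return Percentage in \[0, 100\].
#' @export
relative_binary_mi <- function(data, x, target) {
  check_columns(data, c(x, target))
  tcol <- data[[target]]
  if (!is.factor(tcol)) tcol <- factor(tcol)
  if (nlevels(tcol) != 2L) {
    ssbn_stop("configuration", "target '%s' must be binary", target)
  }
  h <- entropy_bits(table(tcol) / sum(!is.na(tcol)))
  if (h == 0) ssbn_stop("undefined_measure", "target '%s' has zero entropy", target)
  joint <- empirical_joint(data, c(x, target))
  mi <- if (any(dim(joint) == 1L) || any(rowSums(joint) == 1) || any(colSums(joint) == 1)) 0
        else max(0, mi_from_joint(joint))
  100 * mi / h
}

# full joint of a network as a factor over sorted variable order
full_joint_factor <- function(net, cap = 1e6) {
  vars <- bn_vars(net)
  cards <- vapply(vars, function(v) bn_card(net, v), integer(1))
  if (prod(cards) > cap) {
    ssbn_stop("too_large", "joint state space %g exceeds cap %g", prod(cards), cap)
  }
  f <- Reduce(fprod, lapply(vars, function(v) cpt_factor(net, v)))
  # canonicalise cell order to sorted variable order
  svars <- sort(f$vars)
  scard <- f$card[match(svars, f$vars)]
  idx <- factor_index_map(f, svars, scard)
  new_factor(svars, scard, f$val[idx])
}

#' Arc force: divergence cost of deleting one arc
#'
#' Strength of a direct dependency, measured as the KL divergence (bits)
#' between the network's joint distribution and the joint of the same
#' network with the arc removed and its child's parameters refit on `data`.
#' Both joints are enumerated exactly.
#'
#' @inheritParams mutual_information
#' @param net A [bayesian_network()].
#' @param arc Length-2 character vector `c(parent, child)`; must be an arc
#'   of `net`.
#' @param smoothing Pseudo-count for the refit (default 0 so that, for a
#'   two-node network fit by maximum likelihood, the force equals the
#'   empirical mutual information of the pair).
#' @param cap Refuse joint state spaces larger than this.
#' @return A list of class `arc_force_report`: `arc`, `force` (bits, >= 0 or
#'   `Inf`).
#' @export
arc_force <- function(net, data, arc, smoothing = 0, cap = 1e6) {
  arc <- as.character(arc)
  a <- bn_arcs(net)
  if (!any(a[, 1L] == arc[1L] & a[, 2L] == arc[2L])) {
    ssbn_stop("domain", "arc %s -> %s not present in the network", arc[1L], arc[2L])
  }
  keep <- !(a[, 1L] == arc[1L] & a[, 2L] == arc[2L])
  reduced <- bn_structure(net$structure$variables, a[keep, , drop = FALSE])
  refit <- fit_parameters(reduced, data, smoothing = smoothing)
  p <- full_joint_factor(net, cap)
  q <- full_joint_factor(refit, cap)
  force <- {
    pos <- p$val > 0
    if (any(pos & q$val == 0)) Inf
    else max(0, sum(p$val[pos] * log2(p$val[pos] / q$val[pos])))
  }
  structure(list(arc = c(parent = arc[1L], child = arc[2L]), force = force),
            class = "arc_force_report")
}

#' @export
print.arc_force_report <- function(x, ...) {
  cat(sprintf("arc %s -> %s: force %.4f bits\n", x$arc[1L], x$arc[2L], x$force))
  invisible(x)
}

#' Single-evidence Bayes factor of a feature state for a target state
#'
#' P(x = s | target = t) / P(x = s | target = t'), with t' the other state
#' of the binary target; both conditionals by exact inference. Values above
#' 1 mean state `s` is more typical of target state `t`.
#'
#' @inheritParams arc_force
#' @param x Feature variable name.
#' @param s A state of `x`.
#' @param t A state of the (binary) target.
#' @return Non-negative ratio; `Inf` if the denominator is 0 while the
#'   numerator is positive, `NaN` if both are 0.
#' @export
state_bayes_factor <- function(net, x, s, t) {
  target <- bn_target(net)
  if (is.null(target)) ssbn_stop("configuration", "network has no target variable")
  tstates <- bn_states(net, target)
  if (length(tstates) != 2L) ssbn_stop("configuration", "target must be binary")
  if (!t %in% tstates) ssbn_stop("domain", "'%s' is not a target state", t)
  tbar <- setdiff(tstates, t)
  num <- posterior(net, x, stats::setNames(t, target))[[s]]
  den <- posterior(net, x, stats::setNames(tbar, target))[[s]]
  if (den == 0) return(if (num > 0) Inf else NaN)
  num / den
}

#' Per-node relevance report for the target
#'
#' One row per non-target variable of the network: relative binary mutual
#' information with the target (percent, from `data`), the posterior mean of
#' zero-based numeric state codes under the node's marginal, and the
#' extreme single-state Bayes factors for each target state (value and the
#' state attaining it). Both target directions are reported explicitly.
#'
#' @inheritParams arc_force
#' @return A `data.frame` of class `target_report`.
#' @export
target_report <- function(net, data) {
  target <- bn_target(net)
  if (is.null(target)) ssbn_stop("configuration", "network has no target variable")
  tstates <- bn_states(net, target)
  nodes <- setdiff(bn_vars(net), target)
  rows <- lapply(nodes, function(v) {
    marg <- posterior(net, v, NULL)
    codes <- seq_along(marg) - 1
    states <- bn_states(net, v)
    bf_neg <- vapply(states, function(s) state_bayes_factor(net, v, s, tstates[1L]),
                     numeric(1))
    bf_pos <- vapply(states, function(s) state_bayes_factor(net, v, s, tstates[2L]),
                     numeric(1))
    data.frame(
      node = v,
      relative_binary_mi_pct = relative_binary_mi(data, v, target),
      posterior_mean_value = sum(codes * as.numeric(marg)),
      max_bf_state_neg = states[which.max(bf_neg)],
      max_bf_neg = max(bf_neg),
      min_bf_state_neg = states[which.min(bf_neg)],
      min_bf_neg = min(bf_neg),
      max_bf_state_pos = states[which.max(bf_pos)],
      max_bf_pos = max(bf_pos),
      min_bf_state_pos = states[which.min(bf_pos)],
      min_bf_pos = min(bf_pos),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$relative_binary_mi_pct), ]
  rownames(out) <- NULL
  class(out) <- c("target_report", "data.frame")
  out
}

#' Write a report to CSV or JSON
#'
#' @param report A [target_report()] or [arc_force_report] result.
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default inferred from the extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path)) "json" else "csv"
  df <- if (inherits(report, "arc_force_report")) {
    data.frame(parent = report$arc[["parent"]], child = report$arc[["child"]],
               force_bits = report$force, stringsAsFactors = FALSE)
  } else {
    as.data.frame(unclass(report), stringsAsFactors = FALSE)
  }
  if (format == "json") {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
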