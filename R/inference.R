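#' Joint probability of a complete assignment
#'
#' Evaluates the chain-rule factorisation P(x_1, ..., x_n) =
#' prod_i P(x_i | pa_i): one CPT lookup per variable.
#'
#' @param net A [bayesian_network()].
#' @param a A full assignment: named character vector binding every variable
#'   of the network to one of its states.
#' @return A probability in \[0, 1\].
#' @examples
#' net <- toy_te_network()
#' joint_probability(net, c(T = "1", E = "1"))  # 0.1 * 0.8
#' @export
joint_probability <- function(net, a) {
  a <- validate_assignment(net, a, "full assignment")
  vars <- bn_vars(net)
  unbound <- setdiff(vars, names(a))
  if (length(unbound) > 0L) {
    ssbn_stop("incomplete_assignment", "unbound variable(s): %s",
              paste(unbound, collapse = ", "))
  }
  p <- 1
  for (v in vars) {
    cpt <- net$cpts[[v]]
    pa <- cpt$parents
    idx <- matrix(vapply(pa, function(q) match(a[[q]], bn_states(net, q)),
                         integer(1)), nrow = 1L)
    row <- cpt_row_index(vapply(pa, function(q) bn_card(net, q), integer(1)), idx)
    p <- p * cpt$prob[row, match(a[[v]], bn_states(net, v))]
  }
  p
}

#' Marginal likelihood of (partial) evidence
#'
#' Probability of a partial assignment under the network's joint
#' distribution, computed exactly by variable elimination. The empty
#' assignment has probability 1.
#'
#' @inheritParams joint_probability
#' @param e A partial assignment (possibly empty, `NULL` or `character(0)`).
#' @return A probability in \[0, 1\].
#' @export
marginal_likelihood <- function(net, e = NULL) {
  e <- validate_assignment(net, e %||% character(0), "evidence")
  if (length(e) == 0L) return(1)
  factors <- evidence_factors(net, e)
  res <- ve_run(factors, setdiff(bn_vars(net), names(e)))
  # all variables eliminated or fixed: scalar factor
  sum(res$val)
}

#' Posterior distribution of a query variable
#'
#' Bayes-rule update P(query = s | e) = P(query = s, e) / P(e) for every
#' state s of the query variable, computed by variable elimination with a
#' min-degree elimination order.
#'
#' @inheritParams marginal_likelihood
#' @param query Name of an unobserved variable.
#' @return An object of class `bn_distribution`: the probability of each
#'   query state in declared state order, with attributes `variable` and
#'   `states`.
#' @examples
#' net <- toy_te_network()
#' posterior(net, "T", c(E = "1"))  # (0.6923, 0.3077)
#' @export
posterior <- function(net, query, e = NULL) {
  e <- validate_assignment(net, e %||% character(0), "evidence")
  if (!query %in% bn_vars(net)) ssbn_stop("domain", "unknown variable '%s'", query)
  if (query %in% names(e)) {
    ssbn_stop("domain", "query variable '%s' is bound in the evidence", query)
  }
  factors <- evidence_factors(net, e)
  res <- ve_run(factors, setdiff(bn_vars(net), c(query, names(e))))
  # res is a factor over the query variable only
  val <- if (length(res$vars) == 1L) res$val else fmarg(res, setdiff(res$vars, query))$val
  z <- sum(val)
  if (z <= 0) {
    ssbn_stop("impossible_evidence", "evidence has probability 0 under the network")
  }
  new_distribution(query, bn_states(net, query), val / z)
}

new_distribution <- function(variable, states, prob) {
  structure(stats::setNames(as.numeric(prob), states),
            variable = variable, states = states, class = "bn_distribution")
}

#' @export
print.bn_distribution <- function(x, ...) {
  cat(sprintf("P(%s | evidence):\n", attr(x, "variable")))
  print(stats::setNames(round(as.numeric(x), 6), names(x)))
  invisible(x)
}

#' Brute-force reference inference
#'
#' Computes the same quantities as [posterior()] and [marginal_likelihood()]
#' by explicit enumeration of the full joint table. Exponential in the number
#' of variables; retained as an in-package cross-check for the variable
#' elimination engine and refused beyond `cap` joint configurations.
#'
#' @inheritParams posterior
#' @param cap Maximum number of joint configurations to enumerate.
#' @return As [posterior()].
#' @export
posterior_enumerate <- function(net, query, e = NULL, cap = 1e6) {
  e <- validate_assignment(net, e %||% character(0), "evidence")
  if (query %in% names(e)) {
    ssbn_stop("domain", "query variable '%s' is bound in the evidence", query)
  }
  vars <- bn_vars(net)
  cards <- vapply(vars, function(v) bn_card(net, v), integer(1))
  if (prod(cards) > cap) {
    ssbn_stop("too_large", "joint table of %g cells exceeds cap %g", prod(cards), cap)
  }
  grid <- expand.grid(lapply(vars, function(v) bn_states(net, v)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- vars
  p <- vapply(seq_len(nrow(grid)), function(i) {
    joint_probability(net, unlist(grid[i, , drop = FALSE]))
  }, numeric(1))
  keep <- rep(TRUE, nrow(grid))
  for (v in names(e)) keep <- keep & grid[[v]] == e[[v]]
  pe <- sum(p[keep])
  if (pe <= 0) ssbn_stop("impossible_evidence", "evidence has probability 0")
  val <- vapply(bn_states(net, query), function(s) {
    sum(p[keep & grid[[query]] == s])
  }, numeric(1))
  new_distribution(query, bn_states(net, query), val / pe)
}
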