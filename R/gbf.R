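# Generalized Bayes Factor scoring of explanations. An explanation x and
# evidence e are partial assignments over disjoint variable sets; the GBF
# compares how well x and its complement (everything that is not x) account
# for e:
#
#   GBF(x; e) = P(e | x) / P(e | not-x)
#
# The complement term is never enumerated explicitly: by total probability,
# P(e | not-x) = (P(e) - P(e, x)) / (1 - P(x)). All probabilities come from
# exact inference.

gbf_terms <- function(net, x, e) {
  px <- marginal_likelihood(net, x)
  if (px <= 0 || px >= 1) {
    ssbn_stop("ill_defined_complement",
              "P(x) = %g; the complement of the explanation is ill-defined", px)
  }
  pe <- marginal_likelihood(net, e)
  pex <- marginal_likelihood(net, c(x, e))
  num <- pex / px
  den <- max(0, pe - pex) / (1 - px)
  list(num = num, den = den)
}

ratio_or_sentinel <- function(num, den) {
  if (den <= 0) {
    if (num > 0) return(Inf)
    return(NaN)
  }
  num / den
}

#' Generalized Bayes factor of an explanation
#'
#' @param net A [bayesian_network()].
#' @param x Explanation: non-empty partial assignment (named character
#'   vector), disjoint from `e`, with 0 < P(x) < 1.
#' @param e Evidence: non-empty partial assignment.
#' @return Non-negative ratio. `Inf` is the documented sentinel for
#'   P(e | not-x) = 0 with P(e | x) > 0; P(x) in \{0, 1\} raises an
#'   ill-defined-complement error.
#' @examples
#' net <- toy_te_network()
#' gbf(net, c(T = "1"), c(E = "1"))  # 4
#' @export
gbf <- function(net, x, e) {
  x <- validate_assignment(net, x, "explanation")
  e <- validate_assignment(net, e, "evidence")
  if (length(x) == 0L || length(e) == 0L) {
    ssbn_stop("configuration", "explanation and evidence must be non-empty")
  }
  if (length(intersect(names(x), names(e))) > 0L) {
    ssbn_stop("domain", "explanation and evidence must bind disjoint variables")
  }
  t <- gbf_terms(net, x, e)
  ratio_or_sentinel(t$num, t$den)
}

#' Conditional generalized Bayes factor
#'
#' GBF(y; e | x) = P(e | y, x) / P(e | not-y, x): the complement is taken
#' over `y` only, with the context assignment `x` held fixed. With empty
#' `x` this reduces to [gbf()].
#'
#' @inheritParams gbf
#' @param y Explanation under evaluation.
#' @param x Context assignment held fixed (may be empty).
#' @return Non-negative ratio (sentinels as in [gbf()]).
#' @export
gbf_conditional <- function(net, y, e, x = NULL) {
  y <- validate_assignment(net, y, "explanation")
  e <- validate_assignment(net, e, "evidence")
  x <- validate_assignment(net, x %||% character(0), "context")
  sets <- list(names(y), names(e), names(x))
  for (i in 1:2) for (j in (i + 1):3) {
    if (length(intersect(sets[[i]], sets[[j]])) > 0L) {
      ssbn_stop("domain", "y, e and x must bind pairwise disjoint variables")
    }
  }
  if (length(x) == 0L) return(gbf(net, y, e))
  pxy <- marginal_likelihood(net, c(x, y))
  px <- marginal_likelihood(net, x)
  if (pxy <= 0 || px - pxy <= 0) {
    ssbn_stop("ill_defined_complement",
              "P(y | x) = %g; complement of y within the context is ill-defined",
              if (px > 0) pxy / px else NaN)
  }
  pexy <- marginal_likelihood(net, c(x, y, e))
  pex <- marginal_likelihood(net, c(x, e))
  num <- pexy / pxy
  den <- max(0, pex - pexy) / (px - pxy)
  ratio_or_sentinel(num, den)
}

#' Chain-rule decomposition of the generalized Bayes factor
#'
#' For evidence split into pairwise-disjoint pieces e1, ..., en:
#' GBF(x; e1, ..., en) = GBF(x; e1) * prod_i GBF(x; ei | e1, ..., e(i-1)),
#' where each conditional term fixes the earlier evidence and takes the
#' complement over `x`. Algebraically identical to [gbf()] on the union of
#' the pieces, for every ordering; the decomposition exposes how much each
#' piece of evidence contributes.
#'
#' @inheritParams gbf
#' @param evidence_sequence List of non-empty partial assignments, pairwise
#'   disjoint and disjoint from `x`.
#' @return Non-negative ratio.
#' @export
gbf_chain <- function(net, x, evidence_sequence) {
  if (!is.list(evidence_sequence) || length(evidence_sequence) == 0L) {
    ssbn_stop("configuration", "evidence_sequence must be a non-empty list")
  }
  x <- validate_assignment(net, x, "explanation")
  pieces <- lapply(evidence_sequence, validate_assignment, net = net,
                   what = "evidence piece")
  all_names <- unlist(lapply(pieces, names))
  if (anyDuplicated(all_names) || length(intersect(all_names, names(x))) > 0L) {
    ssbn_stop("domain", "evidence pieces must be pairwise disjoint and disjoint from x")
  }
  out <- gbf(net, x, pieces[[1L]])
  seen <- pieces[[1L]]
  for (i in seq_along(pieces)[-1L]) {
    out <- out * gbf_conditional(net, x, pieces[[i]], seen)
    seen <- c(seen, pieces[[i]])
  }
  out
}
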