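# Internal factor algebra for exact inference. A factor is a potential over a
# set of discrete variables: list(vars, card, val) where `val` is stored in
# column-major odometer order with the FIRST variable varying fastest (R's
# native array layout).

new_factor <- function(vars, card, val) {
  list(vars = vars, card = as.integer(card), val = as.numeric(val))
}

# state index of each union cell for variable at position j of `card`
cell_states <- function(card, j) {
  inner <- if (j > 1L) prod(card[seq_len(j - 1L)]) else 1L
  outer <- prod(card) / (inner * card[j])
  rep(rep(seq_len(card[j]), each = inner), times = outer)
}

# map each cell of a factor over `uvars`/`ucard` to the flat index of
# sub-factor f (vars subset of uvars)
factor_index_map <- function(f, uvars, ucard) {
  n <- prod(ucard)
  idx <- rep(1L, n)
  stride <- 1L
  for (v in f$vars) {
    j <- match(v, uvars)
    idx <- idx + (cell_states(ucard, j) - 1L) * stride
    stride <- stride * ucard[j]
  }
  idx
}

fprod <- function(f1, f2) {
  uvars <- union(f1$vars, f2$vars)
  ucard <- c(f1$card, f2$card)[match(uvars, c(f1$vars, f2$vars))]
  v1 <- f1$val[factor_index_map(f1, uvars, ucard)]
  v2 <- f2$val[factor_index_map(f2, uvars, ucard)]
  new_factor(uvars, ucard, v1 * v2)
}

# sum a single variable out of a factor
fmarg <- function(f, v) {
  j <- match(v, f$vars)
  if (is.na(j)) return(f)
  keep <- setdiff(seq_along(f$vars), j)
  if (length(keep) == 0L) return(new_factor(character(0), integer(0), sum(f$val)))
  arr <- array(f$val, dim = f$card)
  val <- apply(arr, keep, sum)
  new_factor(f$vars[keep], f$card[keep], val)
}

# condition on var = state index (slice; variable drops out)
freduce <- function(f, v, s) {
  j <- match(v, f$vars)
  if (is.na(j)) return(f)
  pick <- cell_states(f$card, j) == s
  keep <- setdiff(seq_along(f$vars), j)
  new_factor(f$vars[keep], f$card[keep], f$val[pick])
}

cpt_factor <- function(net, v) {
  cpt <- net$cpts[[v]]
  pa <- cpt$parents
  cc <- bn_card(net, v)
  cardp <- vapply(pa, function(p) bn_card(net, p), integer(1))
  nr <- nrow(cpt$prob)
  if (length(pa) == 0L) return(new_factor(v, cc, as.numeric(cpt$prob[1L, ])))
  # CPT rows are odometer with last parent fastest == column-major over the
  # reversed parent order; map each row to its parent indices
  pm <- arrayInd(seq_len(nr), rev(cardp))[, rev(seq_along(pa)), drop = FALSE]
  # offset of each row in the column-major layout over (v, pa...)
  off <- integer(nr)
  stride <- 1L
  for (j in seq_along(pa)) {
    off <- off + (pm[, j] - 1L) * stride * cc
    stride <- stride * cardp[j]
  }
  val <- numeric(cc * nr)
  val[as.vector(outer(seq_len(cc), off, "+"))] <- as.vector(t(cpt$prob))
  new_factor(c(v, pa), c(cc, cardp), val)
}

# variable elimination over the given factors, eliminating `elim` with a
# min-degree heuristic (lexicographic tie-break); returns a single factor
# over the remaining variables (possibly the empty scalar factor).
ve_run <- function(factors, elim) {
  factors <- Filter(function(f) TRUE, factors)
  for (step in seq_along(elim)) {
    remaining <- intersect(elim, unique(unlist(lapply(factors, `[[`, "vars"))))
    if (length(remaining) == 0L) break
    # min-degree: neighbours in the factor hypergraph
    degs <- vapply(remaining, function(v) {
      nb <- unique(unlist(lapply(factors, function(f) {
        if (v %in% f$vars) f$vars else character(0)
      })))
      length(setdiff(nb, v))
    }, integer(1))
    v <- sort(remaining[degs == min(degs)])[1L]
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(fprod, factors[touch])
    factors <- c(factors[!touch], list(fmarg(prod_f, v)))
  }
  Reduce(fprod, factors)
}

# reduce all CPT factors by evidence (named character assignment)
evidence_factors <- function(net, e) {
  lapply(bn_vars(net), function(v) {
    f <- cpt_factor(net, v)
    for (ev in intersect(names(e), f$vars)) {
      f <- freduce(f, ev, match(e[[ev]], bn_states(net, ev)))
    }
    f
  })
}
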