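# Independent brute-force oracle: builds the full joint table by explicit
# enumeration with its own CPT-row indexing (iterating parents from the
# fastest-varying last one), deliberately sharing no code path with the
# package's variable-elimination engine.

oracle_joint_table <- function(net) {
  vars <- bn_vars(net)
  grid <- expand.grid(lapply(vars, function(v) bn_states(net, v)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- vars
  p <- rep(1, nrow(grid))
  for (v in vars) {
    cpt <- net$cpts[[v]]
    ridx <- rep(1L, nrow(grid))
    mult <- 1L
    for (q in rev(cpt$parents)) {  # last declared parent varies fastest
      qi <- match(grid[[q]], bn_states(net, q))
      ridx <- ridx + (qi - 1L) * mult
      mult <- mult * bn_card(net, q)
    }
    ci <- match(grid[[v]], bn_states(net, v))
    p <- p * cpt$prob[cbind(ridx, ci)]
  }
  grid$.p <- p
  grid
}

oracle_match <- function(tab, a) {
  keep <- rep(TRUE, nrow(tab))
  for (v in names(a)) keep <- keep & tab[[v]] == a[[v]]
  keep
}

oracle_marginal <- function(tab, a) sum(tab$.p[oracle_match(tab, a)])

oracle_posterior <- function(tab, query, e, states) {
  keep <- oracle_match(tab, e)
  num <- vapply(states, function(s) sum(tab$.p[keep & tab[[query]] == s]),
                numeric(1))
  num / sum(num)
}

oracle_gbf <- function(tab, x, e) {
  px <- oracle_marginal(tab, x)
  pe <- oracle_marginal(tab, e)
  pex <- oracle_marginal(tab, c(x, e))
  (pex / px) / ((pe - pex) / (1 - px))
}
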