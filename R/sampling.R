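#' Forward (ancestral) sampling
#'
#' Draws complete records by sampling each variable from its CPT in
#' topological order, given its parents' sampled states. Vectorised over
#' records; the same seed always reproduces the same table.
#'
#' @inheritParams joint_probability
#' @param n Number of records (>= 1).
#' @param seed Integer seed; sampling never touches the caller's RNG stream.
#' @return A `data.frame` with one factor column per network variable
#'   (levels = declared states) and `n` rows.
#' @export
forward_sample <- function(net, n, seed) {
  if (!is.numeric(n) || n < 1) ssbn_stop("configuration", "n must be >= 1")
  n <- as.integer(n)
  vars <- bn_vars(net)
  topo <- net$structure$topo
  out <- vector("list", length(vars))
  names(out) <- vars
  with_seed(seed, {
    for (v in topo) {
      cpt <- net$cpts[[v]]
      pa <- cpt$parents
      if (length(pa) == 0L) {
        rows <- rep(1L, n)
      } else {
        idx <- do.call(cbind, lapply(pa, function(p) out[[p]]))
        rows <- cpt_row_index(vapply(pa, function(p) bn_card(net, p), integer(1)), idx)
      }
      cum <- t(apply(cpt$prob, 1L, cumsum))
      u <- stats::runif(n)
      out[[v]] <- rowSums(u > cum[rows, , drop = FALSE]) + 1L
    }
  })
  res <- as.data.frame(lapply(vars, function(v) {
    factor(bn_states(net, v)[out[[v]]], levels = bn_states(net, v))
  }), optional = TRUE)
  names(res) <- vars
  res
}
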