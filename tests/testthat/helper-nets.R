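# Random-network fixtures, built in code under fixed seeds.

# Random DAG with arcs from earlier to later nodes (<= 3 parents each),
# random CPTs bounded away from 0, and the target role on `target_idx` so
# the target generally has both parents and children.
random_net <- function(n_nodes, seed, max_card = 3L, target_idx = NULL) {
  stopifnot(n_nodes >= 2L)
  target_idx <- target_idx %||% ceiling(n_nodes / 2)
  withr::with_seed(seed, {
    vars <- sprintf("v%02d", seq_len(n_nodes))
    cards <- (2:max_card)[sample.int(max_card - 1L, n_nodes, replace = TRUE)]
    vl <- lapply(seq_len(n_nodes), function(i) {
      bn_variable(vars[i], paste0("s", seq_len(cards[i])),
                  role = if (i == target_idx) "target" else "feature")
    })
    arcs <- list()
    for (i in 2:n_nodes) {
      np <- sample(0:min(3L, i - 1L), 1L)
      if (np > 0L) {
        for (p in sample(seq_len(i - 1L), np)) {
          arcs[[length(arcs) + 1L]] <- c(vars[p], vars[i])
        }
      }
    }
    s <- bn_structure(vl, arcs)
    cpts <- lapply(vars, function(v) {
      pa <- bn_parents(s, v)
      nr <- if (length(pa) == 0L) 1L else
        prod(vapply(pa, function(p) bn_card(s, p), integer(1)))
      cc <- bn_card(s, v)
      m <- matrix(stats::runif(nr * cc, 0.05, 1), nr)
      bn_cpt(v, pa, m / rowSums(m))
    })
    bayesian_network(s, cpts)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random full assignment of a network
random_full_assignment <- function(net, seed) {
  withr::with_seed(seed, {
    stats::setNames(vapply(bn_vars(net), function(v) {
      sample(bn_states(net, v), 1L)
    }, character(1)), bn_vars(net))
  })
}

# all orderings of a short list
all_orderings <- function(lst) {
  n <- length(lst)
  if (n == 1L) return(list(lst))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  lapply(perms(seq_len(n)), function(ix) lst[ix])
}
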