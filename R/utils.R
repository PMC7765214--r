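# Seed hygiene: every stochastic operation takes an integer seed and restores
# the caller's RNG state on exit, so package calls never perturb a session's
# random stream.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    ssbn_stop("configuration", "seed must be a single integer, got %s",
              deparse(substitute(seed)))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stream of child seeds from one master seed, kept below 2^31
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic topological order (Kahn's algorithm, lexicographic tie-break);
# also the package's acyclicity check
topological_order <- function(nodes, arcs) {
  nodes <- sort(nodes)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(arcs) > 0L) {
    tab <- table(arcs[, 2L])
    indeg[names(tab)] <- as.integer(tab)
  }
  order <- character(0)
  avail <- names(indeg)[indeg == 0L]
  while (length(avail) > 0L) {
    v <- sort(avail)[1L]
    avail <- setdiff(avail, v)
    order <- c(order, v)
    if (nrow(arcs) > 0L) {
      ch <- arcs[arcs[, 1L] == v, 2L]
      for (c in ch) {
        indeg[[c]] <- indeg[[c]] - 1L
        if (indeg[[c]] == 0L) avail <- c(avail, c)
      }
    }
  }
  if (length(order) != length(nodes)) return(NULL)  # cycle
  order
}
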