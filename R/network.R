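#' Declare a discrete network variable
#'
#' A variable has a name, an ordered set of at least two state labels, and a
#' role: `"target"` for the single outcome variable of a supervised network,
#' `"feature"` otherwise.
#'
#' @param name Variable name (single non-empty string).
#' @param states Character vector of unique state labels, length >= 2. The
#'   order is meaningful: distributions, CPT columns and the zero-based
#'   numeric codes used by [target_report()] all follow it.
#' @param role `"feature"` (default) or `"target"`.
#' @return An object of class `bn_variable`.
#' @examples
#' bn_variable("smoking", c("never", "former", "current"))
#' @export
bn_variable <- function(name, states, role = c("feature", "target")) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    ssbn_stop("validation", "variable name must be a single non-empty string")
  }
  states <- as.character(states)
  if (length(states) < 2L) {
    ssbn_stop("validation", "variable '%s' needs at least 2 states", name)
  }
  if (anyDuplicated(states)) {
    ssbn_stop("validation", "variable '%s' has duplicated state labels", name)
  }
  structure(list(name = name, states = states, role = role),
            class = "bn_variable")
}

#' Assemble a directed acyclic network structure
#'
#' @param variables List of [bn_variable()] objects.
#' @param arcs Arcs as a two-column (parent, child) character matrix, or a
#'   list of length-2 character vectors, or `NULL` for an empty graph.
#' @return An object of class `bn_structure` with canonicalised arcs (sorted
#'   by child then parent) and a stored topological order.
#' @details The structure is validated on construction: arc endpoints must be
#'   declared variables, self-arcs and duplicate arcs are rejected, the graph
#'   must be acyclic, and at most one variable may carry the target role.
#' @export
bn_structure <- function(variables, arcs = NULL) {
  if (inherits(variables, "bn_variable")) variables <- list(variables)
  names <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(names)) {
    ssbn_stop("validation", "duplicated variable names: %s",
              paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  roles <- vapply(variables, function(v) v$role, character(1))
  if (sum(roles == "target") > 1L) {
    ssbn_stop("validation", "at most one variable may have role 'target'")
  }
  names(variables) <- names

  arcs <- normalize_arcs(arcs)
  if (nrow(arcs) > 0L) {
    unknown <- setdiff(unique(c(arcs)), names)
    if (length(unknown) > 0L) {
      ssbn_stop("domain", "arc endpoint(s) not declared: %s",
                paste(unknown, collapse = ", "))
    }
    if (any(arcs[, 1L] == arcs[, 2L])) {
      ssbn_stop("validation", "self-arcs are not allowed")
    }
    if (anyDuplicated(paste(arcs[, 1L], arcs[, 2L]))) {
      ssbn_stop("validation", "duplicate arcs are not allowed")
    }
    arcs <- arcs[order(arcs[, 2L], arcs[, 1L]), , drop = FALSE]
  }
  topo <- topological_order(names, arcs)
  if (is.null(topo)) ssbn_stop("validation", "structure contains a cycle")

  structure(list(variables = variables, arcs = arcs, topo = topo),
            class = "bn_structure")
}

normalize_arcs <- function(arcs) {
  if (is.null(arcs) || (is.list(arcs) && length(arcs) == 0L)) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child"))))
  }
  if (is.list(arcs)) arcs <- do.call(rbind, lapply(arcs, as.character))
  arcs <- as.matrix(arcs)
  if (ncol(arcs) != 2L) ssbn_stop("validation", "arcs must have two columns")
  storage.mode(arcs) <- "character"
  colnames(arcs) <- c("parent", "child")
  arcs
}

#' Conditional probability table for one variable
#'
#' @param child Child variable name.
#' @param parents Ordered character vector of parent names (may be empty).
#' @param prob Numeric matrix with one row per joint parent configuration and
#'   one column per child state. Parent configurations are enumerated in
#'   odometer order over the declared parent order with the *last* parent
#'   varying fastest; a parentless variable has a single row. Each row must
#'   sum to 1 (tolerance 1e-9) with non-negative entries.
#' @return An object of class `bn_cpt`.
#' @export
bn_cpt <- function(child, parents, prob) {
  prob <- as.matrix(prob)
  if (any(prob < 0)) ssbn_stop("validation", "CPT of '%s' has negative entries", child)
  if (any(abs(rowSums(prob) - 1) > 1e-9)) {
    ssbn_stop("validation", "CPT rows of '%s' must sum to 1", child)
  }
  structure(list(child = child, parents = as.character(parents), prob = prob),
            class = "bn_cpt")
}

#' Assemble a discrete Bayesian network
#'
#' The joint distribution of the network is the product of the per-variable
#' conditional probability tables: P(x_1, ..., x_n) = prod_i P(x_i | pa_i).
#'
#' @param structure A [bn_structure()].
#' @param cpts List of [bn_cpt()] objects, one per variable; each CPT's
#'   parent list must equal (same order) the variable's parents in the
#'   structure, and its dimensions must match the declared cardinalities.
#' @return An object of class `bayesian_network`.
#' @seealso [joint_probability()], [posterior()], [forward_sample()]
#' @examples
#' tb <- bn_variable("T", c("0", "1"), role = "target")
#' ev <- bn_variable("E", c("0", "1"))
#' s <- bn_structure(list(tb, ev), list(c("T", "E")))
#' net <- bayesian_network(s, list(
#'   bn_cpt("T", character(0), matrix(c(0.9, 0.1), 1)),
#'   bn_cpt("E", "T", matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE))
#' ))
#' joint_probability(net, c(T = "1", E = "1"))
#' @export
bayesian_network <- function(structure, cpts) {
  if (!inherits(structure, "bn_structure")) {
    ssbn_stop("validation", "'structure' must be a bn_structure")
  }
  names(cpts) <- vapply(cpts, function(x) x$child, character(1))
  vars <- names(structure$variables)
  missing <- setdiff(vars, names(cpts))
  if (length(missing) > 0L) {
    ssbn_stop("validation", "missing CPT for: %s", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(cpts), vars)
  if (length(extra) > 0L) {
    ssbn_stop("domain", "CPT for undeclared variable: %s", paste(extra, collapse = ", "))
  }
  cpts <- cpts[vars]
  for (v in vars) {
    pa <- structure_parents(structure, v)
    if (!identical(cpts[[v]]$parents, pa)) {
      ssbn_stop("validation",
                "CPT parents of '%s' (%s) do not match structure (%s)",
                v, paste(cpts[[v]]$parents, collapse = ","), paste(pa, collapse = ","))
    }
    card_c <- length(structure$variables[[v]]$states)
    card_p <- vapply(pa, function(p) length(structure$variables[[p]]$states), integer(1))
    if (ncol(cpts[[v]]$prob) != card_c || nrow(cpts[[v]]$prob) != prod(card_p)) {
      ssbn_stop("validation", "CPT of '%s' has wrong dimensions", v)
    }
  }
  structure(list(structure = structure, cpts = cpts), class = "bayesian_network")
}

structure_parents <- function(structure, v) {
  a <- structure$arcs
  as.character(a[a[, 2L] == v, 1L])
}

# ---- accessors -------------------------------------------------------------

#' Network accessors
#'
#' Small helpers shared across the package: variable names, state labels,
#' cardinalities, parents, children, arcs and the (unique) target variable.
#'
#' @param net A `bayesian_network` or `bn_structure`.
#' @param v A variable name.
#' @name accessors
NULL

as_structure <- function(net) {
  if (inherits(net, "bayesian_network")) net$structure else net
}

#' @rdname accessors
#' @export
bn_vars <- function(net) names(as_structure(net)$variables)

#' @rdname accessors
#' @export
bn_states <- function(net, v) {
  s <- as_structure(net)
  if (!v %in% names(s$variables)) ssbn_stop("domain", "unknown variable '%s'", v)
  s$variables[[v]]$states
}

#' @rdname accessors
#' @export
bn_card <- function(net, v) length(bn_states(net, v))

#' @rdname accessors
#' @export
bn_parents <- function(net, v) structure_parents(as_structure(net), v)

#' @rdname accessors
#' @export
bn_children <- function(net, v) {
  a <- as_structure(net)$arcs
  as.character(a[a[, 1L] == v, 2L])
}

#' @rdname accessors
#' @export
bn_arcs <- function(net) as_structure(net)$arcs

#' @rdname accessors
#' @export
bn_target <- function(net) {
  s <- as_structure(net)
  roles <- vapply(s$variables, function(v) v$role, character(1))
  tg <- names(roles)[roles == "target"]
  if (length(tg) == 0L) NULL else tg
}

#' @export
print.bayesian_network <- function(x, ...) {
  s <- x$structure
  cat(sprintf("Discrete Bayesian network: %d variables, %d arcs\n",
              length(s$variables), nrow(s$arcs)))
  tg <- bn_target(x)
  if (!is.null(tg)) cat(sprintf("  target: %s (%s)\n", tg,
                                paste(bn_states(x, tg), collapse = "/")))
  if (nrow(s$arcs) > 0L) {
    cat("  arcs:", paste(sprintf("%s -> %s", s$arcs[, 1], s$arcs[, 2]),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.bn_structure <- function(x, ...) {
  cat(sprintf("Network structure: %d variables, %d arcs\n",
              length(x$variables), nrow(x$arcs)))
  invisible(x)
}

# ---- assignments -----------------------------------------------------------

# assignments are named character vectors: names = variables, values = states
validate_assignment <- function(net, a, what = "assignment") {
  if (length(a) == 0L) return(stats::setNames(character(0), character(0)))
  a <- unlist(a)
  if (is.null(names(a)) || any(!nzchar(names(a)))) {
    ssbn_stop("domain", "%s must be a named variable -> state map", what)
  }
  if (anyDuplicated(names(a))) {
    ssbn_stop("domain", "%s binds a variable twice", what)
  }
  vars <- bn_vars(net)
  unknown <- setdiff(names(a), vars)
  if (length(unknown) > 0L) {
    ssbn_stop("domain", "%s binds unknown variable(s): %s", what,
              paste(unknown, collapse = ", "))
  }
  for (v in names(a)) {
    if (!a[[v]] %in% bn_states(net, v)) {
      ssbn_stop("domain", "'%s' is not a state of variable '%s'", a[[v]], v)
    }
  }
  a
}

# row index into a CPT's probability matrix: odometer over declared parent
# order, last parent fastest. idx: integer matrix (n x k) of 1-based parent
# state indices in declared parent order.
cpt_row_index <- function(card_par, idx) {
  k <- length(card_par)
  if (k == 0L) return(rep(1L, nrow(idx)))
  strides <- rev(cumprod(rev(c(card_par[-1L], 1L))))
  as.integer(1L + (idx - 1L) %*% strides)
}
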