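#' Genetic-algorithm configuration for the explanation search
#'
#' @param population_size Number of chromosomes per generation (default 100).
#' @param generations Number of generations (default 50).
#' @param crossover_rate Probability that a selected pair recombines by
#'   one-point crossover (default 0.8).
#' @param mutation_rate Per-gene mutation probability; default `NULL` means
#'   1/L with L the number of candidate variables.
#' @param elite_count Chromosomes copied unchanged into the next generation
#'   (default 2).
#' @param tournament_size Tournament selection size (default 3).
#' @param allow_unset If `TRUE` (default) a gene may be "unassigned", so the
#'   search ranges over partial explanations; if `FALSE` every candidate
#'   variable is always bound, mirroring full risk profiles.
#' @param top_k Number of ranked explanations to return (default 5).
#' @param seed Integer seed; the whole search is a deterministic function of
#'   its inputs and this seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, generations = 50L,
                      crossover_rate = 0.8, mutation_rate = NULL,
                      elite_count = 2L, tournament_size = 3L,
                      allow_unset = TRUE, top_k = 5L, seed = 1L) {
  if (population_size < 2L) ssbn_stop("configuration", "population_size must be >= 2")
  if (elite_count >= population_size) {
    ssbn_stop("configuration", "elite_count must be smaller than population_size")
  }
  for (r in c(crossover_rate, mutation_rate)) {
    if (!is.null(r) && (r < 0 || r > 1)) {
      ssbn_stop("configuration", "rates must lie in [0, 1]")
    }
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elite_count = as.integer(elite_count),
                 tournament_size = as.integer(tournament_size),
                 allow_unset = isTRUE(allow_unset),
                 top_k = as.integer(top_k),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Exact-inference engine for repeated GBF queries over a fixed candidate
# set. Up to `cap` joint configurations, one variable-elimination pass
# computes the dense joint over (candidates, hypothesis variable) and every
# explanation's probability is a slice sum of that array; beyond the cap
# each query runs its own variable elimination instead. Both routes are
# exact — the cap only trades memory for per-query time.
mre_engine <- function(net, hypothesis, candidates, cap = 2^19) {
  vars <- unique(c(candidates, names(hypothesis)))
  ocard <- vapply(vars, function(v) bn_card(net, v), integer(1))
  states <- lapply(stats::setNames(vars, vars), function(v) bn_states(net, v))
  if (prod(ocard) > cap) {
    return(list(mode = "ve", net = net, vars = vars, card = ocard,
                states = states))
  }
  f <- ve_run(evidence_factors(net, character(0)), setdiff(bn_vars(net), vars))
  idx <- factor_index_map(f, vars, ocard)
  list(mode = "dense", vars = vars, card = ocard,
       arr = array(f$val[idx], dim = ocard), states = states)
}

# probability of a partial assignment given as named 1-based state indices
engine_prob <- function(eng, a) {
  if (identical(eng$mode, "ve")) {
    if (length(a) == 0L) return(1)
    bound <- stats::setNames(vapply(names(a), function(v) {
      eng$states[[v]][a[[v]]]
    }, character(1)), names(a))
    return(marginal_likelihood(eng$net, bound))
  }
  idx <- lapply(seq_along(eng$vars), function(j) {
    v <- eng$vars[j]
    if (v %in% names(a)) a[[v]] else seq_len(eng$card[j])
  })
  sum(do.call(`[`, c(list(eng$arr), idx, list(drop = FALSE))))
}

engine_gbf <- function(eng, xidx, hidx) {
  if (length(xidx) == 0L) return(list(gbf = 1, posterior = engine_prob(eng, hidx)))
  px <- engine_prob(eng, xidx)
  if (px <= 0 || px >= 1) return(list(gbf = NA_real_, posterior = NA_real_))
  pex <- engine_prob(eng, c(xidx, hidx))
  pe <- engine_prob(eng, hidx)
  num <- pex / px
  den <- max(0, pe - pex) / (1 - px)
  g <- if (den <= 0) { if (num > 0) Inf else NaN } else num / den
  list(gbf = g, posterior = pex / px)
}

decode_chromosome <- function(chrom, candidates, states) {
  bound <- which(chrom > 0L)
  if (length(bound) == 0L) return(stats::setNames(character(0), character(0)))
  stats::setNames(
    vapply(bound, function(j) states[[candidates[j]]][chrom[j]], character(1)),
    candidates[bound]
  )
}

#' GBF fitness of a chromosome
#'
#' Decodes a chromosome (one gene per candidate variable; 0 = unassigned)
#' into a partial explanation and scores it with [gbf()] against the target
#' hypothesis. The fitness function is total: the all-unset chromosome
#' scores 1 (the empty explanation changes nothing) and an ill-defined GBF
#' (P(x) equal to 0 or 1) scores 0.
#'
#' @param net A [bayesian_network()].
#' @param chromosome Integer vector, one gene per candidate (0 = unset).
#' @param hypothesis Single-variable assignment binding the target state
#'   under explanation.
#' @param candidates Character vector of candidate variable names.
#' @return Non-negative fitness (possibly `Inf`).
#' @export
fitness <- function(net, chromosome, hypothesis, candidates) {
  hypothesis <- validate_assignment(net, hypothesis, "hypothesis")
  eng <- mre_engine(net, hypothesis, candidates)
  hidx <- stats::setNames(match(hypothesis, bn_states(net, names(hypothesis))),
                          names(hypothesis))
  xidx <- chrom_to_idx(chromosome, candidates)
  g <- engine_gbf(eng, xidx, hidx)$gbf
  if (is.na(g)) 0 else g
}

chrom_to_idx <- function(chrom, candidates) {
  bound <- which(chrom > 0L)
  stats::setNames(as.integer(chrom[bound]), candidates[bound])
}

# deterministic ranking key: GBF descending (rounded to 10 significant
# digits so fp noise does not reorder ties), then fewer bound variables,
# then the lexicographic explanation string
rank_order <- function(gbfs, chroms) {
  nb <- vapply(chroms, function(ch) sum(ch > 0L), integer(1))
  key <- vapply(chroms, paste, character(1), collapse = ",")
  g <- ifelse(is.finite(gbfs), signif(gbfs, 10L), gbfs)
  order(-g, nb, key)
}

#' Search for the most relevant explanation with a genetic algorithm
#'
#' Evolves partial assignments over the candidate variables to maximise the
#' generalized Bayes factor for the hypothesis (a single target-state
#' binding). Standard generational GA: tournament selection, one-point
#' crossover, per-gene mutation, elitism. Elitism makes the best fitness
#' per generation non-decreasing, which is asserted on every run.
#'
#' @inheritParams fitness
#' @param config A [ga_config()].
#' @return An object of class `mre_result`: list with `results` (ranked
#'   unique explanations from the final population, each with
#'   `explanation`, `gbf`, `posterior_of_target`, `generation_found`),
#'   `best_per_generation`, and `ill_defined_count` (chromosomes whose GBF
#'   was ill-defined and scored 0).
#' @export
run_ga <- function(net, hypothesis, candidates, config = ga_config()) {
  hypothesis <- validate_assignment(net, hypothesis, "hypothesis")
  if (length(hypothesis) != 1L) {
    ssbn_stop("configuration", "hypothesis must bind exactly one variable")
  }
  if (length(candidates) == 0L) {
    ssbn_stop("configuration", "candidate list is empty")
  }
  if (names(hypothesis) %in% candidates) {
    ssbn_stop("configuration", "candidates must exclude the hypothesis variable")
  }
  missing <- setdiff(candidates, bn_vars(net))
  if (length(missing) > 0L) {
    ssbn_stop("domain", "candidate(s) not in network: %s", paste(missing, collapse = ", "))
  }
  L <- length(candidates)
  cards <- vapply(candidates, function(v) bn_card(net, v), integer(1))
  mrate <- config$mutation_rate %||% (1 / L)
  eng <- mre_engine(net, hypothesis, candidates)
  hidx <- stats::setNames(match(hypothesis, bn_states(net, names(hypothesis))),
                          names(hypothesis))

  cache <- new.env(parent = emptyenv())
  ill_defined <- 0L
  eval_chrom <- function(ch) {
    key <- paste(ch, collapse = ",")
    if (exists(key, envir = cache, inherits = FALSE)) {
      return(get(key, envir = cache, inherits = FALSE))
    }
    g <- engine_gbf(eng, chrom_to_idx(ch, candidates), hidx)
    if (is.na(g$gbf)) {
      ill_defined <<- ill_defined + 1L
      g$gbf <- 0
    }
    assign(key, g, envir = cache)
    g
  }
  random_gene <- function(j, n) {
    if (config$allow_unset) sample.int(cards[j] + 1L, n, replace = TRUE) - 1L
    else sample.int(cards[j], n, replace = TRUE)
  }

  with_seed(config$seed, {
    pop <- lapply(seq_len(config$population_size), function(i) {
      vapply(seq_len(L), function(j) random_gene(j, 1L), integer(1))
    })
    fit <- vapply(pop, function(ch) eval_chrom(ch)$gbf, numeric(1))
    best_per_gen <- numeric(config$generations + 1L)
    best_per_gen[1L] <- max(fit)
    found_gen <- new.env(parent = emptyenv())
    note_found <- function(chs, gen) {
      for (ch in chs) {
        key <- paste(ch, collapse = ",")
        if (!exists(key, envir = found_gen, inherits = FALSE)) {
          assign(key, gen, envir = found_gen)
        }
      }
    }
    note_found(pop, 0L)

    tournament <- function() {
      ids <- sample.int(length(pop), config$tournament_size, replace = TRUE)
      ids[rank_order(fit[ids], pop[ids])[1L]]
    }
    for (gen in seq_len(config$generations)) {
      elite_ids <- rank_order(fit, pop)[seq_len(config$elite_count)]
      newpop <- pop[elite_ids]
      while (length(newpop) < config$population_size) {
        p1 <- pop[[tournament()]]
        p2 <- pop[[tournament()]]
        if (L >= 2L && stats::runif(1) < config$crossover_rate) {
          cut <- sample.int(L - 1L, 1L)
          c1 <- c(p1[seq_len(cut)], p2[(cut + 1L):L])
          c2 <- c(p2[seq_len(cut)], p1[(cut + 1L):L])
        } else {
          c1 <- p1; c2 <- p2
        }
        for (ch in list(c1, c2)) {
          mut <- stats::runif(L) < mrate
          for (j in which(mut)) {
            vals <- if (config$allow_unset) 0L:cards[j] else seq_len(cards[j])
            vals <- setdiff(vals, ch[j])
            ch[j] <- vals[sample.int(length(vals), 1L)]
          }
          if (length(newpop) < config$population_size) {
            newpop[[length(newpop) + 1L]] <- ch
          }
        }
      }
      pop <- newpop
      fit <- vapply(pop, function(ch) eval_chrom(ch)$gbf, numeric(1))
      note_found(pop, gen)
      best_per_gen[gen + 1L] <- max(fit)
    }
    # elitism invariant, at the ranking resolution (ties at 10 significant
    # digits are interchangeable under the deterministic tie-break)
    ngen <- length(best_per_gen)
    b <- ifelse(is.finite(best_per_gen), signif(best_per_gen, 10L), best_per_gen)
    stopifnot(all(b[-1L] >= b[-ngen]))

    keys <- vapply(pop, paste, character(1), collapse = ",")
    uniq <- !duplicated(keys)
    pop <- pop[uniq]; fit <- fit[uniq]; keys <- keys[uniq]
    ord <- rank_order(fit, pop)
    take <- ord[seq_len(min(config$top_k, length(ord)))]
    results <- lapply(take, function(i) {
      g <- eval_chrom(pop[[i]])
      list(explanation = decode_chromosome(pop[[i]], candidates, eng$states),
           gbf = g$gbf,
           posterior_of_target = g$posterior,
           generation_found = get(keys[i], envir = found_gen))
    })
    structure(list(results = results, best_per_generation = best_per_gen,
                   ill_defined_count = ill_defined,
                   hypothesis = hypothesis, candidates = candidates),
              class = "mre_result")
  })
}

#' @export
print.mre_result <- function(x, ...) {
  cat(sprintf("Most relevant explanations for %s = %s\n",
              names(x$hypothesis), x$hypothesis[[1L]]))
  for (i in seq_along(x$results)) {
    r <- x$results[[i]]
    expl <- if (length(r$explanation) == 0L) "(empty)" else
      paste(names(r$explanation), r$explanation, sep = "=", collapse = ", ")
    cat(sprintf("%2d. GBF %.4f | P(target) %.4f | %s\n",
                i, r$gbf, r$posterior_of_target, expl))
  }
  invisible(x)
}

#' Exhaustive most-relevant-explanation search
#'
#' Brute-force enumeration of every explanation over the candidate set
#' (including partial ones when `allow_unset`), under the same GBF fitness
#' and tie-break rule as [run_ga()]. Used as the optimality reference for
#' the genetic search.
#'
#' @inheritParams run_ga
#' @param allow_unset Include partial explanations (default `TRUE`).
#' @param cap Refuse search spaces larger than this many explanations.
#' @return A single explanation record as in [run_ga()]'s `results`, with
#'   `generation_found = NA`.
#' @export
exhaustive_mre <- function(net, hypothesis, candidates, allow_unset = TRUE,
                           cap = 1e6) {
  hypothesis <- validate_assignment(net, hypothesis, "hypothesis")
  if (length(candidates) == 0L) ssbn_stop("configuration", "candidate list is empty")
  cards <- vapply(candidates, function(v) bn_card(net, v), integer(1))
  size <- prod(cards + as.integer(allow_unset))
  if (size > cap) {
    ssbn_stop("too_large", "explanation space of %g exceeds cap %g", size, cap)
  }
  eng <- mre_engine(net, hypothesis, candidates, cap = Inf)
  hstate <- match(hypothesis, bn_states(net, names(hypothesis)))
  L <- length(candidates)
  # joint over candidates with / without the hypothesis state fixed
  tdim <- match(names(hypothesis), eng$vars)
  slice <- lapply(seq_along(eng$vars), function(j) {
    if (j == tdim) hstate else seq_len(eng$card[j])
  })
  t_e <- do.call(`[`, c(list(eng$arr), slice, list(drop = FALSE)))
  t_e <- array(t_e, dim = eng$card[-tdim])
  t_all <- apply(eng$arr, setdiff(seq_along(eng$vars), tdim), sum)
  t_all <- array(t_all, dim = eng$card[-tdim])
  # augment every candidate dimension with an "unset" slot holding its
  # margin: cell (i1..iL) with ij <= card = bound state, ij = card+1 = unset,
  # so each augmented cell is P(explanation) (resp. P(explanation, e))
  grow_dim <- function(A, j) {
    d <- dim(A)
    if (length(d) == 1L) return(array(c(A, sum(A)), dim = d + 1L))
    marg <- apply(A, setdiff(seq_along(d), j), sum)
    nd <- d; nd[j] <- d[j] + 1L
    out <- array(0, nd)
    idx <- lapply(nd, seq_len); idx[[j]] <- seq_len(d[j])
    out <- do.call(`[<-`, c(list(out), idx, list(A)))
    idx[[j]] <- nd[j]
    do.call(`[<-`, c(list(out), idx, list(array(marg, dim = nd[-j]))))
  }
  ccards <- eng$card[-tdim]
  for (j in seq_len(L)) { t_e <- grow_dim(t_e, j); t_all <- grow_dim(t_all, j) }
  px <- as.vector(t_all)
  pex <- as.vector(t_e)
  pe <- pex[length(pex)]  # all-unset cell of t_e = P(e)
  num <- ifelse(px > 0, pex / px, NA_real_)
  den <- ifelse(px < 1, pmax(0, pe - pex) / (1 - px), NA_real_)
  g <- ifelse(is.na(num) | is.na(den), NA_real_,
              ifelse(den > 0, num / den, ifelse(num > 0, Inf, NaN)))
  # chromosome decoding of each augmented cell
  acard <- ccards + 1L
  n_cells <- prod(acard)
  chrom_mat <- vapply(seq_len(L), function(j) {
    s <- cell_states(acard, j)
    as.integer(ifelse(s == acard[j], 0L, s))
  }, integer(n_cells))
  if (L == 1L) chrom_mat <- matrix(chrom_mat, ncol = 1L)
  nbound <- rowSums(chrom_mat > 0L)
  g[n_cells] <- 1  # empty explanation: GBF defined as 1
  ok <- !is.na(g)
  if (!allow_unset) ok <- ok & nbound == L
  if (!any(ok)) ssbn_stop("configuration", "no explanation had a defined GBF")
  key <- apply(chrom_mat, 1L, paste, collapse = ",")
  gr <- ifelse(is.finite(g), signif(g, 10L), g)
  ord <- order(-gr[ok], nbound[ok], key[ok])
  pick <- which(ok)[ord[1L]]
  ch <- as.integer(chrom_mat[pick, ])
  list(explanation = decode_chromosome(ch, candidates, eng$states),
       gbf = g[pick],
       posterior_of_target = if (nbound[pick] == 0L) pe else pex[pick] / px[pick],
       generation_found = NA_integer_)
}

#' What-if posterior query for the target
#'
#' Posterior probability of the target's positive state under a
#' hypothetical evidence profile, with the change from the unconditioned
#' prior. This is the deployment-facing query: "if a subject had this
#' profile, how would the outcome probability move?".
#'
#' @inheritParams run_ga
#' @param evidence Partial assignment over non-target variables (possibly
#'   empty).
#' @param target Target variable (default: the network's declared target).
#' @param positive_state State whose probability is reported (default: the
#'   last declared state of the target).
#' @return List of class `whatif_result`: `posterior`, `prior`, `delta`
#'   (all probabilities of the positive state).
#' @export
whatif <- function(net, evidence, target = bn_target(net),
                   positive_state = NULL) {
  if (is.null(target)) ssbn_stop("configuration", "network has no target variable")
  evidence <- validate_assignment(net, evidence %||% character(0), "evidence")
  if (target %in% names(evidence)) {
    ssbn_stop("configuration", "evidence must not bind the target")
  }
  states <- bn_states(net, target)
  positive_state <- positive_state %||% states[length(states)]
  if (!positive_state %in% states) {
    ssbn_stop("domain", "'%s' is not a state of '%s'", positive_state, target)
  }
  prior <- posterior(net, target, NULL)[[positive_state]]
  post <- posterior(net, target, evidence)[[positive_state]]
  structure(list(target = target, positive_state = positive_state,
                 posterior = post, prior = prior, delta = post - prior),
            class = "whatif_result")
}

#' @export
print.whatif_result <- function(x, ...) {
  cat(sprintf("P(%s = %s) : prior %.4f -> posterior %.4f (delta %+.4f)\n",
              x$target, x$positive_state, x$prior, x$posterior, x$delta))
  invisible(x)
}
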