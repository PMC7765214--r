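#' Two-node tutorial network
#'
#' The classic cause-effect pair used throughout the documentation and
#' unit tests: binary target T with P(T=1) = 0.1, binary effect E with
#' P(E=1 | T=1) = 0.8 and P(E=1 | T=0) = 0.2. Every hand-derivable
#' quantity of the package can be checked on it: P(E=1) = 0.26,
#' P(T=1 | E=1) = 0.08/0.26 = 0.3077, GBF({T=1}; {E=1}) = 0.8/0.2 = 4.
#'
#' @return A [bayesian_network()].
#' @export
toy_te_network <- function() {
  s <- bn_structure(
    list(bn_variable("T", c("0", "1"), role = "target"),
         bn_variable("E", c("0", "1"))),
    list(c("T", "E"))
  )
  bayesian_network(s, list(
    bn_cpt("T", character(0), matrix(c(0.9, 0.1), 1L)),
    bn_cpt("E", "T", matrix(c(0.8, 0.2, 0.2, 0.8), 2L, byrow = TRUE))
  ))
}
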