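# Condition system: every user-facing failure is a classed condition so that
# callers (and the CLI) can distinguish validation problems from infeasible
# computations without parsing messages.

ssbn_stop <- function(class, msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = NULL),
    class = c(paste0("ssbn_", class), "ssbn_error", "error", "condition")
  ))
}

# error classes used throughout:
#   incomplete_assignment  - a FullAssignment is required but a variable is unbound
#   domain                 - unknown variable or state label
#   impossible_evidence    - evidence has probability zero under the network
#   configuration          - bad learner/search configuration or missing target
#   validation             - malformed input data or file
#   estimation             - no usable data for a CPT family with smoothing 0
#   too_large              - exact enumeration beyond the configured cap
#   undefined_measure      - a metric's denominator is identically zero
#   ill_defined_complement - GBF complement with P(x) in {0, 1}
#   specification          - infeasible synthetic-cohort specification
#   stratification         - a class is smaller than the number of folds
#   parse                  - unreadable network file

is_ssbn_error <- function(e, class) inherits(e, paste0("ssbn_", class))
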