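# Internal helpers shared across modules.

#' Derive a child RNG seed from a root seed and an index
#'
#' All stochastic components of the package draw their seeds through this
#' function so that a whole experiment (many runs, many grid rows) is
#' reproducible from one root seed, and any single run can be re-executed in
#' isolation. Seeds stay below 2^31 - 1.
#'
#' @param root integer root seed.
#' @param index non-negative integer stream index.
#' @return An integer usable with [set.seed()].
#' @export
derive_seed <- function(root, index) {
  stopifnot(is.numeric(root), length(root) == 1, is.numeric(index))
  as.integer((abs(root) + 104729 * (index + 1)) %% 2147483647)
}

# Classed conditions so the CLI can map error families to exit codes.
param_error <- function(msg) {
  stop(structure(class = c("contagion_param_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

io_error <- function(msg) {
  stop(structure(class = c("contagion_io_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    param_error(sprintf("`%s` must be in [0, 1], got %s", name,
                        paste(format(x), collapse = ", ")))
  x
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x) && x >= 0
}
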