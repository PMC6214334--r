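#' Diffusion model parameters
#'
#' Bundles the model kind with its parameters. The three kinds map to the
#' passive / active / mixed contagion scenarios:
#'
#' * `"threshold"` — deterministic peer pressure: a susceptible node adopts
#'   when the fraction of its neighbors already infected is strictly greater
#'   than its threshold `tau`. `gamma` and `blocking_p` are ignored.
#' * `"profile"` — personal preference: a susceptible node with at least one
#'   infected neighbor runs one preference trial per iteration and adopts with
#'   probability `1 - gamma`; a refusing node becomes permanently blocked with
#'   probability `blocking_p`. `tau` is ignored.
#' * `"profile_threshold"` — mixed: the preference trial is run only by nodes
#'   whose infected-neighbor fraction strictly exceeds `tau`; refusers may be
#'   blocked as in the profile model.
#'
#' Any kind may additionally be driven by spontaneous (exogenous) adoption:
#' before each iteration every susceptible node independently becomes infected
#' with probability `spontaneous_a`.
#'
#' @param kind one of `"threshold"`, `"profile"`, `"profile_threshold"`.
#' @param tau adoption threshold in `[0, 1]`; a scalar applied to every node
#'   or a per-node vector (recycled to the node count at run time).
#' @param gamma node profile (reluctance) in `[0, 1]`; per-trial adoption
#'   probability is `1 - gamma`. Scalar or per-node vector.
#' @param blocking_p probability that a node refusing a preference trial
#'   becomes permanently blocked.
#' @param spontaneous_a per-iteration probability of spontaneous adoption by a
#'   susceptible node.
#' @return An object of class `model_params`.
#' @examples
#' model_params("threshold", tau = 0.2)
#' model_params("profile", gamma = 0.8, blocking_p = 0.1)
#' @export
model_params <- function(kind = c("threshold", "profile", "profile_threshold"),
                         tau = 0, gamma = 0, blocking_p = 0,
                         spontaneous_a = 0) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) param_error(
                     sprintf("unknown model kind '%s'", kind[1])))
  check_prob(tau, "tau")
  check_prob(gamma, "gamma")
  if (length(blocking_p) != 1) param_error("`blocking_p` must be a scalar")
  if (length(spontaneous_a) != 1) param_error("`spontaneous_a` must be a scalar")
  check_prob(blocking_p, "blocking_p")
  check_prob(spontaneous_a, "spontaneous_a")
  structure(list(kind = kind, tau = tau, gamma = gamma,
                 blocking_p = blocking_p, spontaneous_a = spontaneous_a),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  fmt <- function(v) if (length(v) == 1) format(v) else
    sprintf("per-node (%d values)", length(v))
  cat(sprintf("<model_params> kind=%s tau=%s gamma=%s blocking_p=%s spontaneous_a=%s\n",
              x$kind, fmt(x$tau), fmt(x$gamma),
              format(x$blocking_p), format(x$spontaneous_a)))
  invisible(x)
}
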