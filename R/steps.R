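# One-iteration step operations. All updates are synchronous: every decision
# in an iteration reads the status ledger as it stood at entry to the step.
# Random draws happen in ascending node-id order (which() returns sorted
# indices), so a run is fully determined by the RNG state on entry.

#' Minimum infected neighbors needed to pass a threshold
#'
#' Smallest integer `k` such that `k / degree` is strictly greater than `tau`,
#' i.e. the peer-pressure requirement of the threshold and profile-threshold
#' models expressed in neighbor counts. With degree 13 and `tau = 0.2` three
#' infected neighbors are needed. `NA` means the threshold is unreachable
#' (`tau = 1`, or degree 0: isolated nodes are never peer-infected).
#'
#' @param degree node degree (vectorized).
#' @param tau threshold in `[0, 1]` (vectorized, recycled).
#' @return Integer vector; `NA` where no `k <= degree` exceeds the threshold.
#' @examples
#' min_infected_neighbors(13, 0.2)  # 3
#' min_infected_neighbors(13, 1)    # NA: unreachable
#' @export
min_infected_neighbors <- function(degree, tau) {
  if (any(degree < 0)) param_error("`degree` must be non-negative")
  check_prob(tau, "tau")
  vals <- cbind(degree = degree, tau = tau)  # recycle to common length
  k <- as.integer(floor(vals[, "degree"] * vals[, "tau"])) + 1L
  # guard the float edge case where floor(d * tau) = d * tau exactly but the
  # quotient comparison disagrees; strictness must match the engine's test
  miss <- vals[, "degree"] > 0 & !(k / vals[, "degree"] > vals[, "tau"])
  k[miss] <- k[miss] + 1L
  k[k > vals[, "degree"]] <- NA_integer_
  k
}

#' Outcome of a single preference trial
#'
#' A uniform draw `v` on `[0, 1]` is compared against the deciding node's
#' profile: the node adopts iff `v >= gamma`, so the per-trial adoption
#' probability is `1 - gamma` (20% for `gamma = 0.8`).
#'
#' @param gamma node profile in `[0, 1]` (vectorized).
#' @param draw uniform variate(s) on `[0, 1]`.
#' @return Logical: `TRUE` = adopt, `FALSE` = refuse.
#' @export
profile_trial <- function(gamma, draw) {
  check_prob(gamma, "gamma")
  draw >= gamma
}

#' Spontaneous-adoption pre-step
#'
#' Before each model iteration, every susceptible node independently becomes
#' infected with probability `a` (exogenous adoption: media, advertising).
#' Blocked nodes are unaffected. Does not advance the iteration counter; the
#' adopters are folded into the next model step's record.
#'
#' @param state a `sim_state`.
#' @param a spontaneous adoption probability in `[0, 1]`.
#' @return The updated `sim_state`.
#' @export
spontaneous_step <- function(state, a) {
  check_prob(a, "a")
  if (a <= 0) return(state)
  sus <- which(state$status == STATUS_SUSCEPTIBLE)
  if (length(sus) == 0) return(state)
  new_inf <- sus[stats::runif(length(sus)) < a]
  state <- mark_infected(state, new_inf)
  state$spont_new <- c(state$spont_new, new_inf)
  state
}

# Shared epilogue: apply adoptions/blockings decided this iteration, attach
# the iteration record, advance t.
finish_step <- function(state, new_inf, new_blk) {
  state <- mark_infected(state, new_inf)
  if (length(new_blk) > 0) state$status[new_blk] <- STATUS_BLOCKED
  state$iteration <- state$iteration + 1L
  newly_infected <- sort(c(state$spont_new, new_inf))
  state$spont_new <- integer(0)
  sc <- status_counts(state)
  state$last_record <- list(
    iteration = state$iteration,
    n_susceptible = sc[["susceptible"]],
    n_infected = sc[["infected"]],
    n_blocked = sc[["blocked"]],
    newly_infected = newly_infected,
    newly_blocked = sort(new_blk))
  state
}

#' One synchronous iteration of the threshold (passive) model
#'
#' Every susceptible node whose infected-neighbor fraction, computed on the
#' statuses at entry to the step, is strictly greater than its threshold `tau`
#' becomes infected. Deterministic given the entry statuses; never produces
#' blocked nodes.
#'
#' @param state a `sim_state`.
#' @param params a [model_params()] with `kind = "threshold"`.
#' @return The updated `sim_state`; `state$last_record` holds the iteration
#'   record (status counts and newly infected/blocked node sets).
#' @export
threshold_step <- function(state, params) {
  if (params$kind != "threshold") param_error("params$kind must be 'threshold'")
  tau <- rep_len(params$tau, state$n)
  sus <- which(state$status == STATUS_SUSCEPTIBLE)
  pos <- sus[state$deg[sus] > 0]
  new_inf <- pos[state$cnt[pos] / state$deg[pos] > tau[pos]]
  finish_step(state, new_inf, integer(0))
}

#' One synchronous iteration of the profile (active) model
#'
#' Every susceptible node with at least one infected neighbor at entry runs
#' exactly one preference trial against its own `gamma` (adoption probability
#' `1 - gamma`). Adopters become infected; each refuser independently becomes
#' permanently blocked with probability `blocking_p`, otherwise it remains
#' susceptible and may try again in later iterations.
#'
#' @inheritParams threshold_step
#' @param params a [model_params()] with `kind = "profile"`.
#' @return The updated `sim_state` (see [threshold_step()]).
#' @export
profile_step <- function(state, params) {
  if (params$kind != "profile") param_error("params$kind must be 'profile'")
  gamma <- rep_len(params$gamma, state$n)
  cand <- which(state$status == STATUS_SUSCEPTIBLE & state$cnt >= 1L)
  run_trials(state, cand, gamma, params$blocking_p)
}

#' One synchronous iteration of the profile-threshold (mixed) model
#'
#' Susceptible nodes whose infected-neighbor fraction strictly exceeds `tau`
#' (peer-pressure gate) run one preference trial; adopters become infected,
#' refusers are blocked with probability `blocking_p`. Nodes failing the gate
#' are untouched — no trial, no blocking risk.
#'
#' @inheritParams threshold_step
#' @param params a [model_params()] with `kind = "profile_threshold"`.
#' @return The updated `sim_state` (see [threshold_step()]).
#' @export
profile_threshold_step <- function(state, params) {
  if (params$kind != "profile_threshold")
    param_error("params$kind must be 'profile_threshold'")
  tau <- rep_len(params$tau, state$n)
  gamma <- rep_len(params$gamma, state$n)
  sus <- which(state$status == STATUS_SUSCEPTIBLE)
  pos <- sus[state$deg[sus] > 0]
  cand <- pos[state$cnt[pos] / state$deg[pos] > tau[pos]]
  run_trials(state, cand, gamma, params$blocking_p)
}

# Preference trials for the candidate set, then blocking draws for refusers.
# Candidates arrive in ascending node-id order from which().
run_trials <- function(state, cand, gamma, blocking_p) {
  if (length(cand) == 0) return(finish_step(state, integer(0), integer(0)))
  adopt <- profile_trial(gamma[cand], stats::runif(length(cand)))
  new_inf <- cand[adopt]
  refusers <- cand[!adopt]
  new_blk <- integer(0)
  if (blocking_p > 0 && length(refusers) > 0)
    new_blk <- refusers[stats::runif(length(refusers)) < blocking_p]
  finish_step(state, new_inf, new_blk)
}

model_step <- function(state, params) {
  switch(params$kind,
         threshold = threshold_step(state, params),
         profile = profile_step(state, params),
         profile_threshold = profile_threshold_step(state, params),
         param_error(sprintf("unknown model kind '%s'", params$kind)))
}
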