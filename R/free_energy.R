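# Variational free energy and the exhaustive-enumeration evidence oracle.
#
# The generative measure used here couples policies to the current state
# through the Boltzmann factor exp(gamma * Q), normalized by a single
# constant over all (policy, state) pairs. Under this reading the sweep in
# iterate_to_convergence() is an exact coordinate descent on the free
# energy below (at fixed precision), so the bound, tightness and descent
# properties can be checked numerically against path enumeration.

obs_indices <- function(observations) {
  if (is.matrix(observations)) observations <- asplit(observations, 2)
  vapply(observations, function(o) which(o == max(o))[1], integer(1))
}

# log-weight of every configuration (s_1..s_t, policy); internal
config_log_weights <- function(model, observations, actions, policies,
                               gamma, value = NULL) {
  t <- if (is.matrix(observations)) ncol(observations) else length(observations)
  oi <- obs_indices(observations)
  if (t > 1L && length(actions) < t - 1L)
    stop("need one executed action per past transition")
  if (is.null(value))
    value <- compute_value_matrix(model, policies, t)
  Q <- value$Q
  lZ <- log(sum(exp(gamma * Q)))
  grid <- as.matrix(expand.grid(rep(list(seq_len(model$J)), t)))
  lw_states <- apply(grid, 1L, function(s) {
    lw <- log(model$d[s[1]]) + log(model$A[oi[1], s[1]])
    if (t > 1L) {
      for (i in 2:t) {
        lw <- lw + log(get_kernel(model, actions[i - 1L], i - 1L)[s[i], s[i - 1L]]) +
          log(model$A[oi[i], s[i]])
      }
    }
    lw
  })
  # rows: state configurations, cols: policies
  lw <- matrix(lw_states, nrow = nrow(grid), ncol = policies$count)
  lw <- lw + t(gamma * Q[, grid[, t], drop = FALSE]) - lZ
  list(grid = grid, lw = lw, t = t)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Model evidence by exhaustive path enumeration
#'
#' Marginalizes the generative measure over every hidden-state trajectory and
#' allowable policy, at a fixed precision. Intended as an independent oracle
#' for checking the variational free-energy bound on small models; it refuses
#' problems whose configuration count exceeds `cap`.
#'
#' @param model A [generative_model()].
#' @param observations List of one-hot observation vectors (or a matrix with
#'   one column per trial) for trials `1..t`.
#' @param actions Integer vector of executed controls for transitions
#'   `1..t-1`.
#' @param policies Policy set enumerated for trial `t`.
#' @param gamma Fixed precision at which the policy factor is evaluated.
#' @param cap Maximum number of configurations to enumerate.
#' @return List with `log_evidence` and `evidence`.
#' @export
enumerate_evidence <- function(model, observations, actions, policies,
                               gamma, cap = 1e6) {
  t <- if (is.matrix(observations)) ncol(observations) else length(observations)
  n_cfg <- model$J^t * policies$count
  if (n_cfg > cap)
    stop(sprintf("enumeration cap exceeded (%g configurations > %g)",
                 n_cfg, cap))
  cw <- config_log_weights(model, observations, actions, policies, gamma)
  le <- logsumexp(as.vector(cw$lw))
  list(log_evidence = le, evidence = exp(le))
}

#' Variational free energy of a belief state
#'
#' Gibbs energy expected under the factorized posterior minus its entropy:
#' an upper bound on surprise (negative log evidence), tight exactly when
#' the factorized posterior equals the true posterior. Evaluated by
#' enumerating all configurations, so it is restricted to small models (see
#' `cap`).
#'
#' With `gamma` supplied, precision is treated as fixed and the evaluation is
#' exact. With `gamma = NULL` the precision factor is handled within its
#' conjugate gamma family: the energy uses the posterior mean `gamma_hat`,
#' and the divergence `KL(Gamma(alpha, beta_hat) || Gamma(alpha, beta))` is
#' added.
#'
#' @param model A [generative_model()].
#' @param beliefs A [belief_state()] (its `s_hat` is the current-trial state
#'   belief).
#' @param observations,actions As in [enumerate_evidence()].
#' @param policies Policy set for the current trial.
#' @param s_hist Optional `J x t` matrix of state beliefs for trials `1..t`
#'   (columns); defaults to the single column `beliefs$s_hat` when `t = 1`.
#' @param gamma Fixed precision, or `NULL` to use the gamma posterior in
#'   `beliefs`.
#' @param cap Maximum number of configurations to enumerate.
#' @return The free energy (scalar); `Inf` if the beliefs put mass on a
#'   configuration of zero prior weight.
#' @export
free_energy <- function(model, beliefs, observations, actions, policies,
                        s_hist = NULL, gamma = NULL, cap = 1e6) {
  t <- if (is.matrix(observations)) ncol(observations) else length(observations)
  if (is.null(s_hist)) {
    if (t != 1L)
      stop("supply `s_hist` (J x t state beliefs) for multi-trial evaluation")
    s_hist <- matrix(beliefs$s_hat, ncol = 1L)
  }
  if (!all(dim(s_hist) == c(model$J, t)))
    stop("`s_hist` must be J x t")
  n_cfg <- model$J^t * policies$count
  if (n_cfg > cap)
    stop(sprintf("enumeration cap exceeded (%g configurations > %g)",
                 n_cfg, cap))
  fixed <- !is.null(gamma)
  g <- if (fixed) gamma else beliefs$gamma_hat
  cw <- config_log_weights(model, observations, actions, policies, g)
  lq_states <- apply(cw$grid, 1L, function(s)
    sum(log(s_hist[cbind(s, seq_len(t))])))
  F <- 0
  for (r in seq_len(nrow(cw$grid))) {
    for (k in seq_len(policies$count)) {
      q <- exp(lq_states[r]) * beliefs$pi_hat[k]
      if (q > 0) {
        lq <- lq_states[r] + log(beliefs$pi_hat[k])
        F <- F + q * (lq - cw$lw[r, k])
      }
    }
  }
  if (!fixed) {
    a <- model$alpha; b <- model$beta; bh <- beliefs$beta_hat
    F <- F + a * log(bh / b) + a * (b - bh) / bh
  }
  F
}
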