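# Variational updates for perception, action selection and precision,
# iterated to convergence within a trial.

#' Construct a belief state
#'
#' Sufficient statistics of the mean-field posterior: state beliefs `s_hat`
#' (current trial), policy beliefs `pi_hat`, and the rate `beta_hat` of the
#' gamma posterior over precision, whose mean `gamma_hat = alpha / beta_hat`
#' is the expected precision.
#'
#' @param s_hat Length-`J` probability vector over hidden states.
#' @param pi_hat Probability vector over allowable policies.
#' @param beta_hat Posterior rate of the gamma distribution over precision.
#' @param alpha Shape of the gamma distribution (fixed at its prior value).
#' @return An object of class `belief_state`.
#' @export
belief_state <- function(s_hat, pi_hat, beta_hat, alpha) {
  stopifnot(beta_hat > 0, alpha > 0)
  structure(list(s_hat = as.numeric(s_hat), pi_hat = as.numeric(pi_hat),
                 beta_hat = beta_hat, alpha = alpha,
                 gamma_hat = alpha / beta_hat),
            class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("<belief_state> %d states, %d policies, gamma_hat = %.4f\n",
              length(x$s_hat), length(x$pi_hat), x$gamma_hat))
  invisible(x)
}

#' Update beliefs about the current hidden state (perception)
#'
#' Softmax combination of three log-evidence terms: the observation
#' likelihood, the empirical prior propagated from the previous trial's
#' beliefs through the executed action's kernel (the initial-state prior `d`
#' at trial 1), and the precision-weighted expected value of each state under
#' current policy beliefs. The third term is an optimism bias: when precision
#' is high, perception is pulled toward states from which valuable policies
#' are available.
#'
#' @param o One-hot observation vector (length `nrow(A)`).
#' @param s_prev Previous trial's state belief, or `NULL` at trial 1.
#' @param a_prev Control executed on leaving the previous trial (ignored at
#'   trial 1).
#' @param gamma_hat Expected precision (non-negative scalar).
#' @param value A [compute_value_matrix()] for the current trial.
#' @param pi_hat Current policy beliefs.
#' @param model The [generative_model()].
#' @param t Current trial (resolves time-varying kernels).
#' @return Normalized state belief vector of length `J`.
#' @export
update_states <- function(o, s_prev, a_prev, gamma_hat, value, pi_hat,
                          model, t) {
  if (length(o) != nrow(model$A)) stop("observation has wrong length")
  if (length(pi_hat) != nrow(value$Q)) stop("pi_hat/value dimension mismatch")
  # hard evidence: a state with zero likelihood for the observed outcome is
  # vetoed outright (-Inf survives into the softmax); only the summands with
  # positive observation weight contribute, so no 0 * -Inf terms arise
  idx <- which(o > 0)
  lik <- colSums(log(model$A[idx, , drop = FALSE]) * o[idx])
  prior <- if (is.null(s_prev) || t == 1L) {
    mlog(model$d)
  } else {
    if (length(s_prev) != model$J) stop("s_prev has wrong length")
    as.vector(mlog(get_kernel(model, a_prev, t - 1L)) %*% s_prev)
  }
  bias <- gamma_hat * as.vector(crossprod(value$Q, pi_hat))
  softmax(lik + prior + bias)
}

#' Update beliefs about policies (action selection)
#'
#' The softmax choice rule: `pi_hat = softmax(gamma_hat * Q %*% s_hat)`.
#' Expected precision plays the role of the inverse temperature; at
#' `gamma_hat = 0` all policies are equiprobable, and as `gamma_hat` grows
#' the distribution concentrates on the highest-valued policy.
#'
#' @param value A [compute_value_matrix()] for the current trial.
#' @param s_hat Current state beliefs.
#' @param gamma_hat Expected precision.
#' @return Probability vector over allowable policies.
#' @export
update_policies <- function(value, s_hat, gamma_hat) {
  if (length(s_hat) != ncol(value$Q)) stop("s_hat/value dimension mismatch")
  softmax(gamma_hat * as.vector(value$Q %*% s_hat))
}

#' Update the precision of beliefs about policies (evaluation)
#'
#' The posterior rate is `beta_hat = beta - E`, where
#' `E = pi_hat' Q s_hat <= 0` is the value expected under current beliefs
#' about states and policies; expected precision is
#' `gamma_hat = alpha / beta_hat`. Precision is strictly increasing in
#' expected value and attains its upper bound `alpha / beta` when the goal
#' distribution is fully attainable (`E = 0`).
#'
#' @param value A [compute_value_matrix()] for the current trial.
#' @param s_hat Current state beliefs.
#' @param pi_hat Current policy beliefs.
#' @param model The [generative_model()] (supplies `alpha`, `beta`).
#' @return List with `beta_hat`, `gamma_hat`, and the expected value
#'   `expected_value`.
#' @export
update_precision <- function(value, s_hat, pi_hat, model) {
  E <- as.numeric(crossprod(pi_hat, value$Q %*% s_hat))
  beta_hat <- model$beta - E
  if (beta_hat <= 0)
    stop("non-positive posterior rate: goal prior is not a distribution")
  list(beta_hat = beta_hat, gamma_hat = model$alpha / beta_hat,
       expected_value = E)
}

#' Iterate the variational updates to convergence for one trial
#'
#' Repeats perception, action selection and precision evaluation (in that
#' order, starting from prior beliefs) until the largest absolute change
#' across all sufficient statistics falls below `tol`, or `max_iter` sweeps
#' have run. The per-sweep expected-precision series is recorded for
#' downstream deconvolution analyses.
#'
#' @param model The [generative_model()].
#' @param policies Policy set for the current trial.
#' @param o One-hot observation for the current trial.
#' @param t Current trial.
#' @param s_prev,a_prev Previous trial's converged state belief and executed
#'   control (`NULL` at trial 1).
#' @param init Optional `belief_state` to start from; defaults to priors
#'   (uniform policies, prior rate `beta`).
#' @param tol Convergence tolerance on the max-change norm.
#' @param max_iter Sweep cap; hitting it sets `converged = FALSE` (a warning
#'   flag in the trace, not an error).
#' @param fix_gamma If non-`NULL`, clamp expected precision at this value and
#'   skip the precision update (diagnostic use, e.g. checking posterior
#'   marginals against exact enumeration).
#' @param value Optional precomputed [compute_value_matrix()] (possibly
#'   transformed, e.g. with the entropy term removed); computed from the
#'   model if omitted.
#' @return List with `beliefs` (a [belief_state()]), `value`, and `trace`
#'   (data frame: sweep, gamma_hat, delta_s, delta_pi, delta_beta), plus
#'   `iterations` and `converged`.
#' @export
iterate_to_convergence <- function(model, policies, o, t,
                                   s_prev = NULL, a_prev = NULL,
                                   init = NULL, tol = 1e-4, max_iter = 32L,
                                   fix_gamma = NULL, value = NULL) {
  if (is.null(value)) value <- compute_value_matrix(model, policies, t)
  if (is.null(init)) {
    pi_hat <- rep(1 / policies$count, policies$count)
    beta_hat <- model$beta
    s_hat <- rep(1 / model$J, model$J)
  } else {
    pi_hat <- init$pi_hat
    beta_hat <- init$beta_hat
    s_hat <- init$s_hat
  }
  gamma_hat <- if (is.null(fix_gamma)) model$alpha / beta_hat else fix_gamma
  trace <- list()
  converged <- FALSE
  iterations <- 0L
  for (sweep in seq_len(max_iter)) {
    s_new <- update_states(o, s_prev, a_prev, gamma_hat, value, pi_hat,
                           model, t)
    pi_new <- update_policies(value, s_new, gamma_hat)
    if (is.null(fix_gamma)) {
      prec <- update_precision(value, s_new, pi_new, model)
      beta_new <- prec$beta_hat
      gamma_hat <- prec$gamma_hat
    } else {
      beta_new <- beta_hat
    }
    delta_s <- max(abs(s_new - s_hat))
    delta_pi <- max(abs(pi_new - pi_hat))
    delta_beta <- abs(beta_new - beta_hat)
    s_hat <- s_new; pi_hat <- pi_new; beta_hat <- beta_new
    iterations <- sweep
    trace[[sweep]] <- c(sweep = sweep, gamma_hat = gamma_hat,
                        delta_s = delta_s, delta_pi = delta_pi,
                        delta_beta = delta_beta)
    if (max(delta_s, delta_pi, delta_beta) < tol) {
      converged <- TRUE
      break
    }
  }
  trace <- as.data.frame(do.call(rbind, trace))
  beliefs <- belief_state(s_hat, pi_hat,
                          if (is.null(fix_gamma)) beta_hat
                          else model$alpha / fix_gamma,
                          model$alpha)
  if (!is.null(fix_gamma)) beliefs$gamma_hat <- fix_gamma
  list(beliefs = beliefs, value = value, trace = trace,
       iterations = iterations, converged = converged)
}
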