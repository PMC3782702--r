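# Analyses of the limited-offer simulations: precision-trace deconvolution,
# utility sweeps with latency distributions, entropy/expected-utility time
# courses, and marginal-utility curves.

# Forced-observation driver: the low offer stays on the table for every
# trial and the executed control is always "stay", while inference and
# choice probabilities run untouched. Internal.
run_forced_low <- function(model, use_entropy = TRUE) {
  sched <- stats::setNames(rep(1L, model$horizon),
                           as.character(seq_len(model$horizon)))
  run_game(model, generative_process(schedule = sched),
           force_stay = TRUE, use_entropy = use_entropy)
}

#' Least-squares deconvolution of a precision trace
#'
#' Models the per-iteration expected-precision series as a train of impulses
#' convolved with a causal exponentially decaying kernel
#' `k(i) = exp(-(i - 1) / tau)` and recovers the impulses by unconstrained
#' least squares. Convolving the recovered impulses with the kernel
#' reconstructs the input up to the reported residual.
#'
#' @param trace Numeric series of expected precision, one value per inner
#'   iteration (e.g. `gamma_sweeps` from [run_game()]).
#' @param tau Kernel time constant in iterations (default 8).
#' @return An object of class `deconvolved_trace`: `impulses`, `fitted`,
#'   `residual_norm`, `tau`, and the `input` series.
#' @export
deconvolve_precision <- function(trace, tau = 8) {
  n <- length(trace)
  stopifnot(n >= 1L, tau > 0)
  idx <- outer(seq_len(n), seq_len(n), "-")
  Kmat <- ifelse(idx >= 0, exp(-idx / tau), 0)
  impulses <- as.vector(qr.solve(Kmat, trace))
  fitted <- as.vector(Kmat %*% impulses)
  structure(list(impulses = impulses, fitted = fitted,
                 residual_norm = sqrt(sum((fitted - trace)^2)),
                 tau = tau, input = trace),
            class = "deconvolved_trace")
}

#' @export
print.deconvolved_trace <- function(x, ...) {
  cat(sprintf(
    "<deconvolved_trace> %d iterations, tau = %g, residual norm %.3g\n",
    length(x$input), x$tau, x$residual_norm))
  invisible(x)
}

#' Distribution over choice latencies
#'
#' Converts per-trial acceptance probabilities into the probability of the
#' first acceptance occurring at each latency:
#' `p(tau) = prod_{i < tau}(1 - a_i) * a_tau`, with the residual mass being
#' the probability of never accepting.
#'
#' @param accept_probs Per-trial probability of accepting, each in `[0, 1]`.
#' @return List with `p` (per-latency probabilities), `residual`
#'   (never-accept mass), and `mean_latency` (expected latency with the
#'   residual mass censored at one trial past the horizon).
#' @export
latency_distribution <- function(accept_probs) {
  stopifnot(all(accept_probs >= 0), all(accept_probs <= 1))
  n <- length(accept_probs)
  wait <- cumprod(c(1, 1 - accept_probs[-n]))
  p <- wait * accept_probs
  residual <- prod(1 - accept_probs)
  list(p = p, residual = residual,
       mean_latency = sum(seq_len(n) * p) + (n + 1) * residual)
}

#' Sweep the low-offer utility
#'
#' Re-runs the limited-offer game over a grid of low-offer (accepted-low)
#' utilities with offer withdrawal and action both precluded, recording
#' per-trial acceptance probabilities, the implied latency distributions and
#' expected precision -- once with the full value (entropy + expected
#' utility) and once with the entropy term removed.
#'
#' @param u_grid Utilities of the accepted-low final state (default 0..8).
#' @param params Base [limited_offer_params()]; the sweep forces
#'   `preclude_withdrawal` and `preclude_action`.
#' @return An object of class `sweep_result`: a tidy data frame with columns
#'   `u_low`, `variant` (`"with_entropy"`/`"without_entropy"`), `trial`,
#'   `p_accept`, `p_latency`, `gamma_hat`; per-group `residual` and
#'   `mean_latency` are in `attr(, "summary")`.
#' @export
sweep_low_offer_utility <- function(u_grid = 0:8,
                                    params = limited_offer_params()) {
  rows <- list(); summ <- list()
  for (u in u_grid) {
    pu <- limited_offer_params(
      horizon = params$horizon,
      utilities = replace(params$utilities, 4L, u),
      withdrawal_base = params$withdrawal_base,
      high_offer_total = params$high_offer_total,
      alpha = params$alpha, beta = params$beta,
      preclude_withdrawal = TRUE, preclude_action = TRUE)
    game <- build_limited_offer(pu)
    for (variant in c("with_entropy", "without_entropy")) {
      tr <- run_forced_low(game$model, use_entropy = variant == "with_entropy")
      df <- as.data.frame(tr)
      lat <- latency_distribution(df$p_accept)
      rows[[length(rows) + 1L]] <- data.frame(
        u_low = u, variant = variant, trial = df$trial,
        p_accept = df$p_accept, p_latency = lat$p,
        gamma_hat = df$gamma_hat)
      summ[[length(summ) + 1L]] <- data.frame(
        u_low = u, variant = variant, residual = lat$residual,
        mean_latency = lat$mean_latency)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- do.call(rbind, summ)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Utility at which the low offer becomes more attractive than waiting
#'
#' Sweeps the accepted-low utility (withdrawal and action precluded) and
#' finds the smallest grid utility at which the expected utility of
#' accepting the standing low offer immediately is at least that of every
#' policy that waits (in the hope of a high offer), read off the trial-1
#' value matrix from the low-offer state. Below the crossing every waiting
#' policy has higher expected utility and the agent tends to wait until the
#' last trial; at and above it, early acceptance dominates.
#'
#' @param u_grid Utilities of the accepted-low final state (default 0..8).
#' @param params Base [limited_offer_params()]; the sweep forces
#'   `preclude_withdrawal` and `preclude_action`.
#' @param tol Tie tolerance for the expected-utility comparison.
#' @return The crossing utility (scalar; `NA` if no grid point crosses).
#' @export
crossing_utility <- function(u_grid = 0:8, params = limited_offer_params(),
                             tol = 1e-9) {
  for (u in sort(u_grid)) {
    pu <- limited_offer_params(
      horizon = params$horizon,
      utilities = replace(params$utilities, 4L, u),
      withdrawal_base = params$withdrawal_base,
      high_offer_total = params$high_offer_total,
      alpha = params$alpha, beta = params$beta,
      preclude_withdrawal = TRUE, preclude_action = TRUE)
    game <- build_limited_offer(pu)
    policies <- enumerate_policies(2L, game$model$horizon, 1L)
    eu <- compute_value_matrix(game$model, policies, 1L)$EU[, 1L]
    if (eu[1L] >= max(eu[-1L]) - tol) return(u)
  }
  NA_real_
}

#' Entropy and expected-utility time courses
#'
#' Runs the limited-offer game with action precluded (the low offer stays on
#' the table; withdrawal hazards remain active by default) and returns, per
#' trial, the stay/accept control marginal, its Shannon entropy, and the
#' entropy and expected-utility components of the value expected under the
#' converged beliefs, together with expected precision.
#'
#' @param u_low Utility of the accepted-low final state (default 2).
#' @param preclude_withdrawal Zero the withdrawal hazard (default `FALSE`).
#' @param params Base [limited_offer_params()].
#' @return Data frame with columns `trial`, `p_stay`, `p_accept`,
#'   `choice_entropy`, `entropy_term`, `expected_utility_term`, `gamma_hat`.
#' @export
entropy_utility_timecourse <- function(u_low = 2,
                                       preclude_withdrawal = FALSE,
                                       params = limited_offer_params()) {
  pu <- limited_offer_params(
    horizon = params$horizon,
    utilities = replace(params$utilities, 4L, u_low),
    withdrawal_base = params$withdrawal_base,
    high_offer_total = params$high_offer_total,
    alpha = params$alpha, beta = params$beta,
    preclude_withdrawal = preclude_withdrawal, preclude_action = TRUE)
  game <- build_limited_offer(pu)
  tr <- run_forced_low(game$model)
  rows <- lapply(tr$trials, function(x) {
    m <- x$control_marginal
    b <- x$beliefs
    data.frame(
      trial = x$trial,
      p_stay = m[1], p_accept = sum(m[-1]),
      choice_entropy = -sum(ifelse(m > 0, m * log(m), 0)),
      entropy_term = as.numeric(crossprod(b$pi_hat, x$value$H %*% b$s_hat)),
      expected_utility_term =
        as.numeric(crossprod(b$pi_hat, x$value$EU %*% b$s_hat)),
      gamma_hat = b$gamma_hat)
  })
  do.call(rbind, rows)
}

#' Marginal (precision-weighted) utility
#'
#' The effective utility that drives choice when the entropy term is
#' negligible: expected precision times the log goal-prior probability of a
#' final state. Zero precision gives zero marginal utility for every state.
#'
#' @param gamma_hat Expected precision (non-negative scalar).
#' @param c Goal prior over final states.
#' @return Vector of marginal utilities (all `<= 0`).
#' @export
marginal_utility <- function(gamma_hat, c) {
  stopifnot(gamma_hat >= 0)
  gamma_hat * mlog(c)
}

#' Marginal-utility curves over the high-offer utility
#'
#' Sweeps the utility of the accepted-high final state with offer withdrawal
#' and action precluded, and evaluates the marginal utility of accepting the
#' low and the high offer at every trial. As the high-offer utility grows,
#' its goal-prior probability saturates while precision rises more slowly,
#' producing a convex (diminishing-returns) relationship that approaches its
#' maximum at zero.
#'
#' @param u_high_grid Utilities of the accepted-high final state
#'   (default 2..8 in steps of 0.5).
#' @param params Base [limited_offer_params()]; the sweep forces
#'   `preclude_withdrawal` and `preclude_action`.
#' @return Data frame with columns `u_high`, `trial`, `gamma_hat`,
#'   `mu_low`, `mu_high` (marginal utilities of accepting low/high).
#' @export
marginal_utility_curves <- function(u_high_grid = seq(2, 8, by = 0.5),
                                    params = limited_offer_params()) {
  rows <- list()
  for (u in u_high_grid) {
    pu <- limited_offer_params(
      horizon = params$horizon,
      utilities = replace(params$utilities, 5L, u),
      withdrawal_base = params$withdrawal_base,
      high_offer_total = params$high_offer_total,
      alpha = params$alpha, beta = params$beta,
      preclude_withdrawal = TRUE, preclude_action = TRUE)
    game <- build_limited_offer(pu)
    tr <- run_forced_low(game$model)
    mu <- vapply(tr$gamma_hat, marginal_utility, numeric(5),
                 c = game$model$c)
    rows[[length(rows) + 1L]] <- data.frame(
      u_high = u, trial = seq_len(game$model$horizon),
      gamma_hat = tr$gamma_hat,
      mu_low = mu[4L, ], mu_high = mu[5L, ])
  }
  do.call(rbind, rows)
}
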