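# Closed action-perception loop: a generative process (the true environment)
# advanced by actions selected from the agent's posterior beliefs.

#' Construct a generative process (the true environment)
#'
#' The process holds the true transition kernels (defaulting to the agent's
#' model kernels when run), an observation rule, an optional scripted
#' schedule forcing the true state at given trials (for reproducing fixed
#' experimental realizations), and the initial true state. With a schedule
#' present the process is fully deterministic: unscripted transitions take
#' the most probable next state under the executed action's kernel.
#'
#' @param B Optional true transition kernels (same layout as in
#'   [generative_model()]); `NULL` means "use the agent's model kernels".
#' @param A Optional true observation matrix; `NULL` means the model's `A`.
#' @param schedule Optional named integer vector mapping trial numbers to
#'   forced true states, e.g. `c("11" = 2)` forces state 2 at trial 11.
#' @param initial_state True state at trial 1.
#' @return An object of class `generative_process`.
#' @export
generative_process <- function(B = NULL, A = NULL, schedule = NULL,
                               initial_state = 1L) {
  if (!is.null(schedule) && is.null(names(schedule)))
    stop("schedule must be a named vector: names are trial numbers")
  structure(list(B = B, A = A, schedule = schedule,
                 initial_state = as.integer(initial_state)),
            class = "generative_process")
}

#' Select an action from posterior beliefs about policies
#'
#' Marginalizes policy beliefs onto the control prescribed at the current
#' trial (the first entry of each policy's control sequence). In
#' `deterministic` mode the most probable control is returned (ties broken
#' toward the lowest control index); in `sampled` mode the control is drawn
#' from the marginal using the session RNG.
#'
#' @param pi_hat Probability vector over allowable policies.
#' @param policies The policy set the beliefs refer to.
#' @param t Current trial (for validation).
#' @param mode `"deterministic"` or `"sampled"`.
#' @param K Number of controls (defaults to the largest control mentioned in
#'   the policy set, floor 2).
#' @return The selected control index; the control marginal is attached as
#'   attribute `"marginal"`.
#' @export
select_action <- function(pi_hat, policies, t = policies$t,
                          mode = c("deterministic", "sampled"), K = NULL) {
  mode <- match.arg(mode)
  if (abs(sum(pi_hat) - 1) > 1e-8) stop("pi_hat must be normalized")
  first <- vapply(policies$policies, `[[`, integer(1), 1L)
  if (is.null(K)) K <- max(2L, max(unlist(policies$policies)))
  marginal <- vapply(seq_len(K), function(u) sum(pi_hat[first == u]),
                     numeric(1))
  a <- if (mode == "deterministic") which.max(marginal)
       else sample.int(K, 1L, prob = marginal)
  structure(as.integer(a), marginal = marginal)
}

#' Advance the true environment by one step
#'
#' A scripted schedule entry for the arriving trial takes precedence over
#' the kernels (it is the experimenter's script; forcing a transition the
#' kernel cannot generate raises a warning but is honored). Otherwise the
#' next state follows the executed action's true kernel: its most probable
#' column entry in `deterministic` mode, or a draw in `sampled` mode. The
#' observation is emitted through the observation rule.
#'
#' @param process A [generative_process()] whose `B`/`A` have been resolved
#'   (see [run_game()]).
#' @param state Current true state index.
#' @param action Executed control index.
#' @param t Trial being left.
#' @param mode `"deterministic"` or `"sampled"`.
#' @return List with `state` (true state at trial `t + 1`) and `observation`
#'   (index emitted at the new state).
#' @export
step_environment <- function(process, state, action, t,
                             mode = c("deterministic", "sampled")) {
  mode <- match.arg(mode)
  kern <- process$B[[action]]
  kern <- if (is.list(kern)) kern[[t]] else kern
  p <- kern[, state]
  key <- as.character(t + 1L)
  if (!is.null(process$schedule) && key %in% names(process$schedule)) {
    nxt <- as.integer(process$schedule[[key]])
    if (p[nxt] == 0)
      warning(sprintf(
        "schedule forces state %d at trial %d, unreachable under control %d",
        nxt, t + 1L, action))
  } else {
    nxt <- if (mode == "deterministic" || !is.null(process$schedule))
      which.max(p) else sample.int(length(p), 1L, prob = p)
  }
  obs_p <- process$A[, nxt]
  obs <- if (mode == "deterministic" || !is.null(process$schedule))
    which.max(obs_p) else sample.int(length(obs_p), 1L, prob = obs_p)
  list(state = as.integer(nxt), observation = as.integer(obs))
}

#' Run a complete game
#'
#' Plays the closed loop for `horizon` trials: observe, enumerate the
#' allowable policies for the current trial, compute policy values, iterate
#' the variational updates to convergence, select an action, and advance the
#' environment. Trials continue to the horizon even after an absorbing state
#' is entered.
#'
#' @param model A [generative_model()].
#' @param process A [generative_process()]; `NULL` uses the model's own
#'   kernels and observation matrix with no schedule.
#' @param mode Action-selection and environment mode, `"deterministic"`
#'   (argmax; the default, for reproducible traces) or `"sampled"` (draws
#'   from the posterior control marginal and the true kernels; requires
#'   `seed`).
#' @param seed Integer seed for `sampled` mode.
#' @param force_stay If `TRUE`, action is precluded: inference runs and
#'   choice probabilities are recorded, but the executed control is always 1
#'   (stay).
#' @param tol,max_iter Convergence settings passed to
#'   [iterate_to_convergence()].
#' @param use_entropy If `FALSE`, the entropy term is removed from the value
#'   matrix (`Q` replaced by its expected-utility component) before
#'   inference.
#' @return An object of class `game_trace`: per-trial true states,
#'   observations, converged beliefs, control marginals, selected actions,
#'   expected values, and the concatenated per-sweep expected-precision
#'   series.
#' @export
run_game <- function(model, process = NULL,
                     mode = c("deterministic", "sampled"), seed = NULL,
                     force_stay = FALSE, tol = 1e-4, max_iter = 32L,
                     use_entropy = TRUE) {
  mode <- match.arg(mode)
  if (mode == "sampled") {
    if (is.null(seed)) stop("sampled mode requires a seed")
    set.seed(seed)
  }
  if (is.null(process)) process <- generative_process()
  if (is.null(process$B)) process$B <- model$B
  if (is.null(process$A)) process$A <- model$A
  horizon <- model$horizon
  J <- model$J
  state <- process$initial_state
  if (!is.null(process$schedule) && "1" %in% names(process$schedule))
    state <- as.integer(process$schedule[["1"]])
  s_prev <- NULL; a_prev <- NULL
  s_hat <- matrix(NA_real_, J, horizon)
  trials <- vector("list", horizon)
  gamma_sweeps <- numeric(0); sweep_trial <- integer(0)
  for (t in seq_len(horizon)) {
    obs <- if (mode == "sampled" && is.null(process$schedule))
      sample.int(nrow(process$A), 1L, prob = process$A[, state])
    else which.max(process$A[, state])
    o <- one_hot(obs, nrow(process$A))
    policies <- enumerate_policies(model$K, horizon, t)
    value <- compute_value_matrix(model, policies, t)
    if (!use_entropy) {
      value$Q <- value$EU
      value$H <- value$H * 0
    }
    fit <- iterate_to_convergence(model, policies, o, t,
                                  s_prev = s_prev, a_prev = a_prev,
                                  tol = tol, max_iter = max_iter,
                                  value = value)
    b <- fit$beliefs
    action <- select_action(b$pi_hat, policies, t, mode = mode, K = model$K)
    marginal <- attr(action, "marginal")
    executed <- if (force_stay) 1L else as.integer(action)
    ev <- as.numeric(crossprod(b$pi_hat, value$Q %*% b$s_hat))
    s_hat[, t] <- b$s_hat
    gamma_sweeps <- c(gamma_sweeps, fit$trace$gamma_hat)
    sweep_trial <- c(sweep_trial, rep(t, nrow(fit$trace)))
    trials[[t]] <- list(
      trial = t, state = state, observation = obs,
      beliefs = b, value = value, policies = policies,
      control_marginal = marginal, action = as.integer(action),
      executed = executed, expected_value = ev,
      iterations = fit$iterations, converged = fit$converged,
      trace = fit$trace)
    if (t < horizon) {
      stepped <- step_environment(process, state, executed, t, mode = mode)
      state <- stepped$state
    }
    s_prev <- b$s_hat; a_prev <- executed
  }
  structure(list(model = model, process = process, trials = trials,
                 s_hat = s_hat,
                 gamma_hat = vapply(trials, function(x)
                   x$beliefs$gamma_hat, numeric(1)),
                 expected_value = vapply(trials, function(x)
                   x$expected_value, numeric(1)),
                 actions = vapply(trials, function(x) x$executed, integer(1)),
                 states = vapply(trials, function(x) x$state, integer(1)),
                 observations = vapply(trials, function(x) x$observation,
                                       integer(1)),
                 gamma_sweeps = gamma_sweeps, sweep_trial = sweep_trial,
                 mode = mode, seed = seed),
            class = "game_trace")
}

#' @export
print.game_trace <- function(x, ...) {
  cat(sprintf("<game_trace> %d trials (%s mode)\n",
              length(x$trials), x$mode))
  cat("  states:  ", paste(x$states, collapse = " "), "\n")
  cat("  actions: ", paste(x$actions, collapse = " "), "\n")
  cat(sprintf("  gamma_hat: %.3f .. %.3f (final %.3f)\n",
              min(x$gamma_hat), max(x$gamma_hat),
              x$gamma_hat[length(x$gamma_hat)]))
  invisible(x)
}

#' One-row-per-trial summary of a game trace
#'
#' @param x A [run_game()] trace.
#' @param ... Unused.
#' @return Data frame with true state, observation, executed action, accept
#'   (non-stay) marginal probability, expected value, expected precision and
#'   sweep counts per trial.
#' @export
as.data.frame.game_trace <- function(x, ...) {
  data.frame(
    trial = seq_along(x$trials),
    state = x$states,
    observation = x$observations,
    action = x$actions,
    p_accept = vapply(x$trials, function(tr)
      sum(tr$control_marginal[-1]), numeric(1)),
    expected_value = x$expected_value,
    gamma_hat = x$gamma_hat,
    iterations = vapply(x$trials, function(tr) tr$iterations, integer(1)),
    converged = vapply(x$trials, function(tr) tr$converged, logical(1)))
}
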