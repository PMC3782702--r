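# Core domain types: the generative model, allowable policies and policy values.

# Probabilities are clamped at exp(-16) before any logarithm is taken:
# absorbing chains produce exact zeros and the clamp bounds the resulting
# penalties instead of propagating -Inf (mirroring softmax saturation).
PROB_FLOOR <- exp(-16)

# clamped elementwise log (internal)
mlog <- function(p) log(pmax(p, PROB_FLOOR))

#' Softmax (normalized exponential)
#'
#' Maps a real vector to a probability vector via `exp(v) / sum(exp(v))`,
#' computed after subtracting `max(v)` for numerical stability. The result is
#' invariant to adding a constant to all entries. `-Inf` entries (hard-zero
#' probabilities, e.g. states vetoed by a noiseless observation) are allowed
#' and map to 0; at least one entry must be finite.
#'
#' @param v Numeric vector of real values, possibly `-Inf`.
#' @return Probability vector of the same length as `v` (entries >= 0, sum 1).
#' @examples
#' p <- softmax(c(1, 1, 1, 2, 4))
#' p[5] / p[4]  # exp(4 - 2) = 7.39
#' @export
softmax <- function(v) {
  if (length(v) == 0L) stop("empty distribution")
  if (any(is.nan(v) | v == Inf)) stop("softmax input must not be NaN or +Inf")
  if (!any(is.finite(v))) stop("distribution has no support")
  w <- exp(v - max(v))
  w / sum(w)
}

#' One-hot probability vector
#'
#' @param i Index of the unit entry.
#' @param n Length of the vector.
#' @return Length-`n` vector with 1 at position `i`, 0 elsewhere.
#' @export
one_hot <- function(i, n) {
  stopifnot(length(i) == 1L, i >= 1L, i <= n)
  v <- numeric(n)
  v[i] <- 1
  v
}

check_stochastic_cols <- function(M, name, tol = 1e-10) {
  if (any(M < -tol)) stop(sprintf("%s has negative entries", name))
  cs <- colSums(M)
  if (any(abs(cs - 1) > tol))
    stop(sprintf("%s columns must sum to 1 (max deviation %.3g)", name,
                 max(abs(cs - 1))))
  invisible(TRUE)
}

#' Construct a generative model for a discrete Markov decision game
#'
#' The model comprises an observation likelihood `A` (column-stochastic,
#' mapping hidden states to outcomes), per-control transition kernels `B`
#' (optionally time-varying), a goal prior `c` over final states (utility of a
#' final state is its log probability under `c`), an initial-state prior `d`,
#' a gamma prior `Gamma(alpha, beta)` over the precision of beliefs about
#' policies, and a game horizon.
#'
#' @param A Observation likelihood: a `J_obs x J` column-stochastic matrix.
#' @param B Transition kernels: a list with one element per control state.
#'   Each element is either a single `J x J` column-stochastic matrix
#'   (time-invariant) or a list of `horizon` such matrices (one per trial;
#'   the kernel at position `t` governs the transition made when leaving
#'   trial `t`). Column `j` holds the distribution of the next state given
#'   the current state is `j`.
#' @param c Goal prior over final states: length-`J` probability vector.
#'   Supply either `c` or `utilities` (not both).
#' @param d Initial-state prior: length-`J` probability vector.
#' @param horizon Number of trials in the game (integer >= 1).
#' @param alpha,beta Shape and rate of the gamma prior on precision.
#' @param utilities Optional length-`J` vector of raw (unnormalized) final
#'   state utilities; the goal prior is then `softmax(utilities)`, so that it
#'   is a proper distribution and all policy values are non-positive.
#' @return An object of class `generative_model` with fields `J`, `K`,
#'   `horizon`, `A`, `B`, `c`, `d`, `alpha`, `beta`.
#' @seealso [build_limited_offer()] for the built-in worked game.
#' @export
generative_model <- function(A, B, c = NULL, d, horizon,
                             alpha = 8, beta = 1, utilities = NULL) {
  if (is.null(c) == is.null(utilities))
    stop("supply exactly one of `c` or `utilities`")
  A <- as.matrix(A)
  J <- ncol(A)
  if (!is.list(B)) stop("`B` must be a list with one element per control")
  K <- length(B)
  horizon <- as.integer(horizon)
  if (J < 2L) stop("need at least two hidden states")
  if (K < 2L) stop("need at least two control states")
  if (horizon < 1L) stop("horizon must be >= 1")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (!is.null(utilities)) {
    if (length(utilities) != J) stop("`utilities` must have length J")
    c <- softmax(utilities)
  }
  c <- as.numeric(c); d <- as.numeric(d)
  if (length(c) != J || length(d) != J) stop("`c` and `d` must have length J")
  if (any(c < 0) || abs(sum(c) - 1) > 1e-10) stop("`c` is not a distribution")
  if (any(d < 0) || abs(sum(d) - 1) > 1e-10) stop("`d` is not a distribution")
  check_stochastic_cols(A, "A")
  B <- lapply(seq_len(K), function(u) {
    b <- B[[u]]
    if (is.list(b)) {
      if (length(b) != horizon)
        stop(sprintf("time-varying B[[%d]] needs one kernel per trial", u))
      lapply(seq_len(horizon), function(t) {
        m <- as.matrix(b[[t]])
        if (!all(dim(m) == c(J, J))) stop("transition kernels must be J x J")
        check_stochastic_cols(m, sprintf("B[[%d]][[%d]]", u, t))
        m
      })
    } else {
      m <- as.matrix(b)
      if (!all(dim(m) == c(J, J))) stop("transition kernels must be J x J")
      check_stochastic_cols(m, sprintf("B[[%d]]", u))
      m
    }
  })
  structure(list(J = J, K = K, horizon = horizon, A = A, B = B,
                 c = c, d = d, alpha = alpha, beta = beta),
            class = "generative_model")
}

#' @export
print.generative_model <- function(x, ...) {
  tv <- any(vapply(x$B, is.list, logical(1)))
  cat(sprintf(
    "<generative_model> %d hidden states, %d controls, horizon %d%s\n",
    x$J, x$K, x$horizon, if (tv) " (time-varying kernels)" else ""))
  cat(sprintf("  precision prior Gamma(alpha = %g, beta = %g)\n",
              x$alpha, x$beta))
  invisible(x)
}

# kernel lookup resolving time-varying B at absolute trial t (internal)
get_kernel <- function(model, u, t) {
  b <- model$B[[u]]
  if (is.list(b)) b[[t]] else b
}

#' Enumerate the pruned "choose-once" policy set
#'
#' A policy is a control sequence covering the current trial `t` through the
#' horizon. For irreversible games with absorbing accepted states only
#' policies making exactly one choice (`u > 1` at a single trial, `u = 1`
#' elsewhere) are considered, reducing the count from `K^(T-t+1)` to
#' `(K-1) * (T-t+1)`. Policies are ordered by choice time, then by control.
#'
#' @param K Number of control states (control 1 is the "stay"/null control).
#' @param horizon Game horizon `T`.
#' @param t Current trial (1-based, `t <= horizon`).
#' @param policies Optional explicit list of control sequences (each of
#'   length `horizon - t + 1`), overriding the pruned family.
#' @return An object of class `policy_set` with fields `policies` (list of
#'   integer control sequences), `tau` and `control` (choice time and chosen
#'   control per policy, `NA` for explicit user policies), `t`, `horizon`,
#'   and `count`.
#' @export
enumerate_policies <- function(K, horizon, t = 1L, policies = NULL) {
  t <- as.integer(t); horizon <- as.integer(horizon)
  if (t > horizon) stop("current trial exceeds the horizon")
  len <- horizon - t + 1L
  if (!is.null(policies)) {
    policies <- lapply(policies, as.integer)
    if (any(vapply(policies, length, integer(1)) != len))
      stop("explicit policies must cover trials t..horizon")
    if (any(unlist(policies) < 1L) || any(unlist(policies) > K))
      stop("control indices out of range")
    return(structure(list(policies = policies,
                          tau = rep(NA_integer_, length(policies)),
                          control = rep(NA_integer_, length(policies)),
                          t = t, horizon = horizon,
                          count = length(policies)),
                     class = "policy_set"))
  }
  tau <- integer(0); control <- integer(0); pol <- list()
  for (ct in t:horizon) {
    for (u in 2:K) {
      p <- rep(1L, len)
      p[ct - t + 1L] <- as.integer(u)
      pol[[length(pol) + 1L]] <- p
      tau <- c(tau, ct); control <- c(control, as.integer(u))
    }
  }
  structure(list(policies = pol, tau = tau, control = control,
                 t = t, horizon = horizon, count = length(pol)),
            class = "policy_set")
}

#' @export
print.policy_set <- function(x, ...) {
  cat(sprintf("<policy_set> %d policies for trials %d..%d\n",
              x$count, x$t, x$horizon))
  invisible(x)
}

#' Compose transition kernels along a policy
#'
#' Returns the matrix `T(pi)` whose column `j` is the distribution over final
#' states given the current state is `j`, under the control sequence of the
#' policy. Kernels are applied in chronological order; time-varying kernels
#' are resolved at the absolute trial they are traversed.
#'
#' @param model A [generative_model()].
#' @param policy Integer control sequence covering trials `t..horizon`.
#' @param t Current trial.
#' @return A `J x J` column-stochastic matrix.
#' @export
compose_transitions <- function(model, policy, t = 1L) {
  t <- as.integer(t)
  len <- model$horizon - t + 1L
  if (length(policy) != len)
    stop(sprintf("policy length %d does not match trials %d..%d",
                 length(policy), t, model$horizon))
  M <- diag(model$J)
  for (i in seq_along(policy)) {
    M <- get_kernel(model, policy[i], t + i - 1L) %*% M
  }
  M
}

#' Policy values: negative KL divergence to the goal prior
#'
#' For each allowable policy `i` and current state `j`, the value
#' `Q[i, j]` is minus the KL divergence from the predicted final-state
#' distribution `T(pi = i)_j` to the goal prior `c`. It decomposes exactly as
#' `Q = H + EU`, where `H[i, j]` is the Shannon entropy of the predicted
#' final-state distribution (an exploration bonus) and `EU[i, j]` its
#' expected utility (expectation of `log c`). All entries of `Q` are
#' non-positive; `Q = 0` only when the predicted distribution equals `c`.
#'
#' @param model A [generative_model()].
#' @param policies A [enumerate_policies()] set for trial `t`.
#' @param t Current trial.
#' @return An object of class `value_matrix` with fields `Q`, `H`, `EU`
#'   (each `count x J`), `t`, and `policies`.
#' @export
compute_value_matrix <- function(model, policies, t = policies$t) {
  if (t != policies$t) stop("policy set was enumerated for a different trial")
  n <- policies$count
  Q <- H <- EU <- matrix(0, n, model$J)
  lc <- mlog(model$c)
  for (i in seq_len(n)) {
    Tm <- compose_transitions(model, policies$policies[[i]], t)
    H[i, ] <- -colSums(Tm * mlog(Tm))
    EU[i, ] <- colSums(Tm * lc)
  }
  structure(list(Q = H + EU, H = H, EU = EU, t = t, policies = policies),
            class = "value_matrix")
}

#' Decompose policy values into entropy and expected-utility terms
#'
#' @param value A [compute_value_matrix()] result.
#' @return A list with matrices `H` (entropy / exploration bonus, >= 0) and
#'   `EU` (expected utility, <= 0), satisfying `H + EU == Q` exactly.
#' @export
decompose_value <- function(value) {
  stopifnot(inherits(value, "value_matrix"))
  list(H = value$H, EU = value$EU)
}

#' @export
print.value_matrix <- function(x, ...) {
  cat(sprintf("<value_matrix> %d policies x %d states at trial %d\n",
              nrow(x$Q), ncol(x$Q), x$t))
  cat(sprintf("  value range [%.4f, %.4f]\n", min(x$Q), max(x$Q)))
  invisible(x)
}

#' @export
as.data.frame.value_matrix <- function(x, ...) {
  n <- nrow(x$Q); J <- ncol(x$Q)
  data.frame(policy = rep(seq_len(n), J),
             state = rep(seq_len(J), each = n),
             Q = as.vector(x$Q), H = as.vector(x$H), EU = as.vector(x$EU))
}
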