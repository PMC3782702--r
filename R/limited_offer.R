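# The "limited offer" waiting game: five hidden states, two controls,
# time-dependent withdrawal and high-offer hazards, and a softmax goal prior.

#' Hidden-state labels of the limited-offer game
#' @export
LIMITED_OFFER_STATES <- c("low_offer", "high_offer", "no_offer",
                          "accepted_low", "accepted_high")

#' Control labels of the limited-offer game
#' @export
LIMITED_OFFER_CONTROLS <- c("stay", "accept")

#' Parameters of the limited-offer game
#'
#' The agent faces a standing low offer that may be withdrawn at any trial
#' (with a hazard that grows over time) or replaced by a high offer; it must
#' decide how long to wait before accepting. Goal utilities are passed
#' through a softmax to form the prior over final states, so the default
#' `c(1, 1, 1, 2, 4)` makes the accepted-high final state `exp(4 - 2) = 7.39`
#' times more likely than accepted-low, which is `exp(2 - 1) = 2.718` times
#' more likely than not having accepted at all.
#'
#' @param horizon Number of trials (default 16).
#' @param utilities Raw utilities of the five final states, in the order
#'   low offer, high offer, no offer, accepted low, accepted high.
#' @param withdrawal_base Per-trial base rate of offer withdrawal entering
#'   the hazard `r_t = 1 - (1 - withdrawal_base)^t` (default 1/16).
#' @param high_offer_total Cumulative probability, conditional on no
#'   withdrawal, of a high offer appearing within the horizon (default 1/2).
#' @param alpha,beta Gamma-prior parameters on precision (defaults 8, 1).
#' @param preclude_withdrawal If `TRUE`, the withdrawal hazard is zeroed.
#' @param preclude_action If `TRUE`, games built from these parameters run
#'   with action precluded (inference and choice probabilities are computed
#'   but "accept" is never executed in the environment).
#' @return An object of class `limited_offer_params`.
#' @export
limited_offer_params <- function(horizon = 16L,
                                 utilities = c(1, 1, 1, 2, 4),
                                 withdrawal_base = 1 / 16,
                                 high_offer_total = 1 / 2,
                                 alpha = 8, beta = 1,
                                 preclude_withdrawal = FALSE,
                                 preclude_action = FALSE) {
  horizon <- as.integer(horizon)
  stopifnot(horizon >= 1L, length(utilities) == 5L,
            withdrawal_base >= 0, withdrawal_base < 1,
            high_offer_total > 0, high_offer_total < 1)
  structure(list(horizon = horizon, utilities = utilities,
                 withdrawal_base = withdrawal_base,
                 high_offer_total = high_offer_total,
                 alpha = alpha, beta = beta,
                 preclude_withdrawal = preclude_withdrawal,
                 preclude_action = preclude_action),
            class = "limited_offer_params")
}

#' Withdrawal hazard
#'
#' Probability that the standing low offer is withdrawn on leaving trial
#' `t`: `r_t = 1 - (1 - withdrawal_base)^t`, non-decreasing in `t`; zero
#' when withdrawal is precluded.
#'
#' @param t Trial (0 is allowed formally and gives 0).
#' @param params A [limited_offer_params()].
#' @return Probability in `[0, 1)`.
#' @export
hazard_withdrawal <- function(t, params = limited_offer_params()) {
  if (params$preclude_withdrawal) return(rep(0, length(t)))
  1 - (1 - params$withdrawal_base)^t
}

#' High-offer hazard
#'
#' Probability that the low offer is replaced by a high offer on leaving
#' trial `t`: `q_t = (1 - r_t) * (1 - (1 - high_offer_total)^(1/horizon))`.
#' The per-trial rate conditional on no withdrawal is constant, so the
#' cumulative conditional probability of a high offer over the horizon
#' equals `high_offer_total`.
#'
#' @inheritParams hazard_withdrawal
#' @return Probability in `[0, 1)`.
#' @export
hazard_high_offer <- function(t, params = limited_offer_params()) {
  r <- hazard_withdrawal(t, params)
  (1 - r) * (1 - (1 - params$high_offer_total)^(1 / params$horizon))
}

#' Build the limited-offer generative model and process
#'
#' States are ordered (low offer, high offer, no offer, accepted low,
#' accepted high); controls are (1 = reject/stay, 2 = accept/shift). Under
#' "stay" at trial `t` the low offer persists with probability
#' `1 - r_t - q_t`, becomes a high offer with `q_t`, and is withdrawn with
#' `r_t`; the high offer, the no-offer state and both accepted states are
#' absorbing. Under "accept" the standing offer is taken (low -> accepted
#' low, high -> accepted high) and accepting nothing leaves the no-offer
#' state unchanged. The observation matrix is the identity; the initial
#' prior and the true initial state are the low offer.
#'
#' @param params A [limited_offer_params()].
#' @return List with `model` (a [generative_model()]) and `process`
#'   (a [generative_process()] sharing the model's kernels).
#' @export
build_limited_offer <- function(params = limited_offer_params()) {
  horizon <- params$horizon
  r <- hazard_withdrawal(seq_len(horizon), params)
  q <- hazard_high_offer(seq_len(horizon), params)
  if (any(r + q > 1 + 1e-12)) stop("hazard overflow")
  stay <- lapply(seq_len(horizon), function(t) {
    m <- diag(5)
    m[, 1] <- c(1 - r[t] - q[t], q[t], r[t], 0, 0)
    m
  })
  accept <- diag(5)
  accept[, 1] <- c(0, 0, 0, 1, 0)  # low offer -> accepted low
  accept[, 2] <- c(0, 0, 0, 0, 1)  # high offer -> accepted high
  model <- generative_model(
    A = diag(5), B = list(stay, accept),
    utilities = params$utilities, d = one_hot(1, 5),
    horizon = horizon, alpha = params$alpha, beta = params$beta)
  list(model = model,
       process = generative_process(initial_state = 1L),
       params = params)
}

#' Scripted schedules for the limited-offer realizations
#'
#' Builds the named schedule vector used by [generative_process()]:
#' `"high_offer"` replaces the low offer with a high offer at `trial`
#' (default 11), `"withdrawal"` withdraws it at `trial` (default 5).
#'
#' @param event `"high_offer"` or `"withdrawal"`.
#' @param trial Trial at which the scripted state appears.
#' @return Named integer vector suitable as a `schedule`.
#' @export
limited_offer_schedule <- function(event = c("high_offer", "withdrawal"),
                                   trial = NULL) {
  event <- match.arg(event)
  if (is.null(trial)) trial <- if (event == "high_offer") 11L else 5L
  stats::setNames(if (event == "high_offer") 2L else 3L,
                  as.character(as.integer(trial)))
}
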