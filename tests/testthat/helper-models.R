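# Small random model builders used across the suite.

rand_stochastic <- function(J) {
  m <- matrix(stats::rexp(J * J), J)
  sweep(m, 2, colSums(m), "/")
}

random_model <- function(J = 3, K = 2, horizon = 3, alpha = 8, beta = 1) {
  generative_model(
    A = rand_stochastic(J),
    B = replicate(K, rand_stochastic(J), simplify = FALSE),
    utilities = stats::rnorm(J),
    d = softmax(stats::rnorm(J)),
    horizon = horizon, alpha = alpha, beta = beta)
}

# two-control model whose kernels agree across controls: every policy
# predicts the same final-state distribution, so policy beliefs stay
# uniform and the exact posterior factorizes
uninformative_policy_model <- function(J = 2, horizon = 2) {
  Bm <- rand_stochastic(J)
  generative_model(A = rand_stochastic(J), B = list(Bm, Bm),
                   utilities = stats::rnorm(J), d = softmax(stats::rnorm(J)),
                   horizon = horizon)
}

# exact posterior marginals over (current state, policy) by enumeration,
# at fixed precision; independent of the variational path
exact_marginals <- function(model, observations, actions, policies, gamma) {
  cw <- actinf:::config_log_weights(model, observations, actions, policies,
                                    gamma)
  w <- exp(cw$lw)
  w <- w / sum(w)
  t <- cw$t
  list(s = rowsum(rowSums(w), cw$grid[, t])[, 1], pi = colSums(w))
}
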