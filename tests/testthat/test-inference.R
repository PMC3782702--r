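fake_value <- function(Q) {
  structure(list(Q = Q, H = Q * 0, EU = Q,
                 t = 1L, policies = NULL), class = "value_matrix")
}

test_that("state update combines likelihood, empirical prior and optimism bias", {
  # identity likelihood, zero precision: the observed state dominates
  m <- generative_model(A = diag(3),
                        B = list(matrix(1 / 3, 3, 3), matrix(1 / 3, 3, 3)),
                        utilities = c(0, 0, 0), d = rep(1 / 3, 3), horizon = 2)
  vm <- fake_value(matrix(0, 2, 3))
  s <- update_states(one_hot(2, 3), rep(1 / 3, 3), 1L, 0, vm,
                     c(0.5, 0.5), m, t = 2L)
  expect_equal(s[2], 1, tolerance = 1e-10)
  # all three terms uniform: the posterior is uniform
  mu <- generative_model(A = matrix(1 / 3, 3, 3),
                         B = list(matrix(1 / 3, 3, 3), matrix(1 / 3, 3, 3)),
                         utilities = c(0, 0, 0), d = rep(1 / 3, 3),
                         horizon = 2)
  su <- update_states(one_hot(1, 3), rep(1 / 3, 3), 1L, 0, vm,
                      c(0.5, 0.5), mu, t = 2L)
  expect_equal(su, rep(1 / 3, 3))
  # equal evidence, value difference of one nat at unit precision:
  # perception is biased toward the valuable state by softmax([0, -1])
  m2 <- generative_model(A = matrix(0.5, 2, 2),
                         B = list(matrix(0.5, 2, 2), matrix(0.5, 2, 2)),
                         utilities = c(0, 0), d = c(0.5, 0.5), horizon = 2)
  vb <- fake_value(matrix(c(0, -1), 1, 2))
  sb <- update_states(one_hot(1, 2), c(0.5, 0.5), 1L, 1, vb, 1, m2, t = 2L)
  expect_equal(sb, softmax(c(0, -1)))
  expect_equal(sb, c(0.7310586, 0.2689414), tolerance = 1e-7)
  expect_error(update_states(one_hot(1, 3), c(0.5, 0.5), 1L, 1, vb, 1,
                             m2, t = 2L),
               "wrong length")
})

test_that("policy update is the softmax choice rule in expected value", {
  Q <- matrix(c(-1, -2), 2, 1)
  vm <- fake_value(Q)
  # zero precision: all policies equiprobable
  expect_equal(update_policies(vm, 1, 0), c(0.5, 0.5))
  # unit precision: softmax of the value gap
  expect_equal(update_policies(vm, 1, 1), softmax(c(-1, -2)))
  # large precision: mass concentrates on the maximizer
  expect_gt(update_policies(vm, 1, 50)[1], 1 - 1e-10)
  # monotonicity: raising one policy's value raises its probability
  set.seed(61)
  for (i in 1:10) {
    Qr <- -matrix(rexp(6), 2, 3)
    s <- softmax(rnorm(3))
    p0 <- update_policies(fake_value(Qr), s, 2)
    Q2 <- Qr; Q2[1, ] <- Q2[1, ] + 0.3
    p1 <- update_policies(fake_value(Q2), s, 2)
    expect_gt(p1[1], p0[1])
  }
})

test_that("precision update is alpha / (beta - expected value), increasing in value", {
  m <- generative_model(A = diag(2), B = list(diag(2), diag(2)),
                        utilities = c(0, 0), d = c(1, 0), horizon = 2,
                        alpha = 8, beta = 1)
  # zero expected value: precision at its maximum alpha / beta = 8
  up0 <- update_precision(fake_value(matrix(0, 2, 2)), c(1, 0),
                          c(0.5, 0.5), m)
  expect_equal(up0$gamma_hat, 8)
  expect_equal(up0$beta_hat, 1)
  # one nat of expected cost: beta_hat = 2, gamma_hat = 4
  up1 <- update_precision(fake_value(matrix(-1, 2, 2)), c(1, 0),
                          c(0.5, 0.5), m)
  expect_equal(up1$beta_hat, 2)
  expect_equal(up1$gamma_hat, 4)
  # strict monotonicity in expected value
  Es <- seq(-5, 0, by = 0.25)
  g <- vapply(Es, function(E)
    update_precision(fake_value(matrix(E, 2, 2)), c(1, 0),
                     c(0.5, 0.5), m)$gamma_hat, numeric(1))
  expect_true(all(diff(g) > 0))
})

test_that("a value-indifferent model converges immediately", {
  set.seed(71)
  m <- uninformative_policy_model(J = 3, horizon = 3)
  pol <- enumerate_policies(2, 3, 1L)
  fit <- iterate_to_convergence(m, pol, one_hot(1, 3), 1L)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 3L)
  # nothing changes after the first full sweep
  last <- fit$trace[fit$iterations, ]
  expect_lt(max(last$delta_s, last$delta_pi, last$delta_beta), 1e-8)
})

test_that("beliefs stay normalized and precision bounded at every sweep", {
  game <- build_limited_offer()
  pol <- enumerate_policies(2, 16, 1L)
  fit <- iterate_to_convergence(game$model, pol, one_hot(1, 5), 1L)
  expect_true(fit$converged)
  expect_equal(sum(fit$beliefs$s_hat), 1, tolerance = 1e-10)
  expect_equal(sum(fit$beliefs$pi_hat), 1, tolerance = 1e-10)
  expect_true(all(fit$trace$gamma_hat > 0))
  expect_true(all(fit$trace$gamma_hat <= game$model$alpha / game$model$beta))
  expect_gte(fit$beliefs$beta_hat, game$model$beta)
  # first trial of the game: converged precision strictly inside (0, 8)
  expect_gt(fit$beliefs$gamma_hat, 0)
  expect_lt(fit$beliefs$gamma_hat, 8)
})

test_that("post-acceptance precision matches the absorbing-state closed form", {
  game <- build_limited_offer()
  tr <- run_game(game$model,
                 generative_process(schedule = limited_offer_schedule("high_offer")))
  lc5 <- log(game$model$c[5])
  # once the high offer is certain, E = log c5 and gamma = 8 / (1 - log c5)
  expect_equal(tr$expected_value[12], lc5, tolerance = 1e-6)
  expect_equal(tr$gamma_hat[12], 8 / (1 - lc5), tolerance = 1e-6)
})

test_that("identical inputs give bit-identical inference traces", {
  game <- build_limited_offer()
  pol <- enumerate_policies(2, 16, 3L)
  f1 <- iterate_to_convergence(game$model, pol, one_hot(1, 5), 3L,
                               s_prev = one_hot(1, 5), a_prev = 1L)
  f2 <- iterate_to_convergence(game$model, pol, one_hot(1, 5), 3L,
                               s_prev = one_hot(1, 5), a_prev = 1L)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$beliefs, f2$beliefs)
})

test_that("clamped precision recovers exact posterior marginals when the
           factorization is exact", {
  set.seed(81)
  for (i in 1:5) {
    m <- uninformative_policy_model(J = 2, horizon = 2)
    pol <- enumerate_policies(2, 2, 1L)
    o <- list(one_hot(sample(2, 1), 2))
    g <- runif(1, 0.5, 4)
    fit <- iterate_to_convergence(m, pol, o[[1]], 1L, fix_gamma = g,
                                  tol = 1e-12, max_iter = 200)
    ex <- exact_marginals(m, o, integer(0), pol, g)
    expect_equal(fit$beliefs$s_hat, unname(ex$s), tolerance = 1e-4)
    expect_equal(fit$beliefs$pi_hat, unname(ex$pi), tolerance = 1e-4)
  }
})
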