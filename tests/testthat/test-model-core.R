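test_that("softmax is a shift-invariant probability map", {
  p <- softmax(c(1, 1, 1, 2, 4))
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  expect_equal(p[5] / p[4], exp(4 - 2))
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  set.seed(11)
  for (i in 1:10) {
    v <- rnorm(sample(2:6, 1))
    expect_equal(softmax(v + 17), softmax(v))
  }
  expect_error(softmax(numeric(0)), "empty distribution")
})

test_that("generative_model validates its probability structure", {
  ok <- generative_model(A = diag(2), B = list(diag(2), diag(2)),
                         c = c(0.5, 0.5), d = c(1, 0), horizon = 3)
  expect_s3_class(ok, "generative_model")
  expect_equal(ok$J, 2L)
  expect_equal(ok$K, 2L)
  bad_col <- matrix(c(0.5, 0.4, 0, 1), 2)
  expect_error(
    generative_model(A = bad_col, B = list(diag(2), diag(2)),
                     c = c(0.5, 0.5), d = c(1, 0), horizon = 3),
    "sum to 1")
  expect_error(
    generative_model(A = diag(2), B = list(diag(2), diag(2)),
                     c = c(0.6, 0.5), d = c(1, 0), horizon = 3),
    "not a distribution")
  expect_error(
    generative_model(A = diag(2), B = list(diag(2), diag(2)),
                     c = c(0.5, 0.5), d = c(1, 0), horizon = 3, alpha = 0),
    "positive")
  expect_error(
    generative_model(A = diag(2), B = list(diag(2)),
                     c = c(0.5, 0.5), d = c(1, 0), horizon = 3),
    "two control states")
  # utilities are passed through softmax to a proper goal prior
  m <- generative_model(A = diag(2), B = list(diag(2), diag(2)),
                        utilities = c(0, 3), d = c(1, 0), horizon = 2)
  expect_equal(m$c, softmax(c(0, 3)))
})

test_that("compose_transitions matches single-step, absorbing and path-sum cases", {
  set.seed(21)
  # single remaining step: the composition is the final kernel itself
  m <- random_model(J = 3, K = 2, horizon = 4)
  expect_equal(compose_transitions(m, 2L, t = 4L), m$B[[2]])
  # absorbing state stays one-hot under any policy
  B1 <- rand_stochastic(3); B2 <- rand_stochastic(3)
  B1[, 2] <- c(0, 1, 0); B2[, 2] <- c(0, 1, 0)
  ma <- generative_model(A = diag(3), B = list(B1, B2),
                         utilities = rnorm(3), d = c(1, 0, 0), horizon = 3)
  Tm <- compose_transitions(ma, c(1L, 2L, 1L), t = 1L)
  expect_equal(Tm[, 2], c(0, 1, 0))
  # brute-force path enumeration over all intermediate state sequences
  mb <- random_model(J = 2, K = 2, horizon = 3)
  pol <- c(1L, 2L, 1L)
  Tm <- compose_transitions(mb, pol, t = 1L)
  brute <- matrix(0, 2, 2)
  for (j in 1:2) for (i in 1:2) for (a in 1:2) for (b in 1:2) {
    brute[i, j] <- brute[i, j] +
      mb$B[[pol[3]]][i, b] * mb$B[[pol[2]]][b, a] * mb$B[[pol[1]]][a, j]
  }
  expect_equal(Tm, brute, tolerance = 1e-12)
  expect_error(compose_transitions(mb, c(1L, 1L), t = 1L), "length")
})

test_that("composition preserves column-stochasticity on random models", {
  set.seed(31)
  for (i in 1:20) {
    J <- sample(2:5, 1); K <- sample(2:3, 1); h <- sample(2:5, 1)
    m <- random_model(J, K, h)
    pol <- sample.int(K, h, replace = TRUE)
    Tm <- compose_transitions(m, pol, t = 1L)
    expect_true(all(abs(colSums(Tm) - 1) < 1e-9))
    expect_true(all(Tm >= 0))
  }
})

test_that("policy values are non-positive KL divergences with exact H + EU split", {
  set.seed(41)
  for (i in 1:15) {
    m <- random_model(J = sample(2:4, 1), K = 2, horizon = sample(2:4, 1))
    pol <- enumerate_policies(m$K, m$horizon, 1L)
    vm <- compute_value_matrix(m, pol, 1L)
    expect_true(all(vm$Q <= 1e-10))
    expect_true(all(vm$H >= -1e-12))
    expect_true(all(vm$EU <= 1e-12))
    expect_equal(vm$Q, vm$H + vm$EU)
    # oracle: direct KL summation over final states equals -Q
    for (k in seq_len(pol$count)) {
      Tm <- compose_transitions(m, pol$policies[[k]], 1L)
      for (j in seq_len(m$J)) {
        p <- Tm[, j]
        kl <- sum(ifelse(p > 0, p * (log(p) - log(m$c)), 0))
        expect_equal(-vm$Q[k, j], kl, tolerance = 1e-9)
      }
    }
  }
})

test_that("value attains zero exactly when the prediction equals the goal prior", {
  set.seed(51)
  m <- random_model(J = 3, K = 2, horizon = 2)
  pol <- enumerate_policies(2, 2, 1L)
  Tm <- compose_transitions(m, pol$policies[[1]], 1L)
  # re-point the goal prior at a reachable predicted distribution
  m2 <- generative_model(A = m$A, B = m$B, c = Tm[, 1], d = m$d, horizon = 2)
  vm <- compute_value_matrix(m2, pol, 1L)
  expect_equal(vm$Q[1, 1], 0, tolerance = 1e-10)
  expect_true(all(vm$Q[vm$Q != vm$Q[1, 1]] < 0))
})

test_that("value matrix examples: point-mass, limited-offer and uniform goals", {
  # absorbing goal state: point-mass prediction gives Q = log c_k, H = 0
  game <- build_limited_offer()
  pol <- enumerate_policies(2, 16, 1L)
  vm <- compute_value_matrix(game$model, pol, 1L)
  lc5 <- log(game$model$c[5])
  expect_equal(lc5, -0.2505225, tolerance = 1e-6)
  # from accepted-high (column 5) every policy predicts accepted-high
  expect_equal(unname(vm$Q[, 5]), rep(lc5, pol$count))
  expect_equal(unname(vm$H[, 5]), rep(0, pol$count), tolerance = 1e-12)
  # uniform goal prior with a deterministic prediction: Q = -log J
  m <- generative_model(A = diag(2), B = list(diag(2), diag(2)),
                        c = c(0.5, 0.5), d = c(1, 0), horizon = 2)
  vmu <- compute_value_matrix(m, enumerate_policies(2, 2, 1L), 1L)
  expect_equal(unname(vmu$Q), matrix(-log(2), 2, 2))
})

test_that("decompose_value returns the exact entropy/expected-utility split", {
  game <- build_limited_offer()
  pol <- enumerate_policies(2, 16, 8L)
  vm <- compute_value_matrix(game$model, pol, 8L)
  dec <- decompose_value(vm)
  expect_identical(dec$H + dec$EU, vm$Q)
  # independent summation oracle at trial 8, low offer held
  for (k in seq_len(pol$count)) {
    Tm <- compose_transitions(game$model, pol$policies[[k]], 8L)
    p <- Tm[, 1]
    H <- -sum(ifelse(p > 0, p * log(p), 0))
    EU <- sum(p * log(game$model$c))
    expect_equal(dec$H[k, 1], H, tolerance = 1e-9)
    expect_equal(dec$EU[k, 1], EU, tolerance = 1e-9)
  }
})
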