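test_that("nonrespondent target follows the total-probability decomposition", {
  # observed already matches the population => missing must too
  expect_equal(target_missing_proportion(0.7, 0.7, 0.5), 0.7)
  # hand arithmetic: (0.7 - 0.8 * 0.55) / 0.45
  expect_equal(target_missing_proportion(0.7, 0.8, 0.55), 0.26 / 0.45,
               tolerance = 1e-12)
  # incompatible population/observed/response combination: (0.9-0.18)/0.1 = 7.2
  expect_error(target_missing_proportion(0.9, 0.2, 0.9), "7.2")
  expect_error(target_missing_proportion(c(a = 0.9, b = 0.05),
                                         c(a = 0.2, b = 0.4), 0.9), "a")
  expect_error(target_missing_proportion(0.5, 0.5, 1), "p_r")
})

test_that("predicted nonrespondent proportion behaves like a mean expit", {
  expect_equal(predicted_missing_proportion(0, rep(0, 7)), 0.5)
  expect_equal(predicted_missing_proportion(60, rnorm(20)), 1, tolerance = 1e-9)
  expect_equal(predicted_missing_proportion(-60, rnorm(20)), 0, tolerance = 1e-9)
  # expit(-0.5) + expit(0.5) = 1 symmetry with half y=0, half y=1
  eta <- c(rep(0, 5), rep(1, 5))  # theta0 = 0, theta_y = 1
  expect_equal(predicted_missing_proportion(-0.5, eta), 0.5)
  expect_error(predicted_missing_proportion(0, numeric(0)), "nonrespondent")
})

test_that("predicted proportion is strictly increasing in delta", {
  set.seed(41)
  for (i in 1:20) {
    eta <- rnorm(50, sd = 2)
    ds <- sort(runif(10, -8, 8))
    preds <- vapply(ds, predicted_missing_proportion, 0, eta = eta)
    expect_true(all(diff(preds) > 0))
  }
})

test_that("binary bisection solves the calibration equation", {
  set.seed(42)
  eta <- rnorm(100)
  # target equal to the unadjusted prediction => delta = 0
  t0 <- predicted_missing_proportion(0, eta)
  expect_equal(solve_delta_binary(eta, t0)$delta, 0, tolerance = 1e-8)
  # shared linear predictor: closed-form logit inverse
  expect_equal(solve_delta_binary(rep(0, 10), 0.7)$delta, qlogis(0.7),
               tolerance = 1e-8)
  expect_equal(solve_delta_binary(rep(1.3, 10), 0.2)$delta, qlogis(0.2) - 1.3,
               tolerance = 1e-8)
  expect_error(solve_delta_binary(eta, 1.2), "\\(0, 1\\)")
})

test_that("bisection agrees with grid-search and Brent oracles on random instances", {
  set.seed(43)
  for (i in 1:15) {
    eta <- rnorm(40, mean = runif(1, -2, 2), sd = runif(1, 0.3, 2))
    target <- runif(1, 0.05, 0.95)
    sol <- solve_delta_binary(eta, target)
    expect_true(sol$converged)
    expect_lte(abs(sol$residual), 1e-8)
    expect_lt(abs(sol$delta - grid_delta_oracle(eta, target)), 1e-3)
    expect_lt(abs(sol$delta - uniroot_delta_oracle(eta, target)), 1e-6)
  }
})

test_that("multinomial solver hits its targets and conserves the simplex", {
  set.seed(44)
  for (i in 1:10) {
    eta <- matrix(rnorm(60 * 3, sd = 1.5), 60, 3)
    # unadjusted predictions as targets => zero adjustment
    t0 <- colMeans(exp(eta) / (1 + rowSums(exp(eta))))
    expect_equal(solve_delta_categorical(eta, t0)$delta, rep(0, 3),
                 tolerance = 1e-7)
    # random feasible targets
    raw <- runif(4, 0.5, 2)
    targets <- (raw / sum(raw))[1:3]
    sol <- solve_delta_categorical(eta, targets)
    expect_lte(max(abs(sol$residual)), 1e-8)
    achieved <- colMeans(calmi:::softmax_nonbase(eta, sol$delta))
    # conservation: achieved non-base proportions plus base complement sum to 1
    expect_equal(sum(achieved) + mean(1 / (1 + rowSums(exp(sweep(eta, 2,
      sol$delta, "+"))))), 1, tolerance = 1e-10)
  }
  expect_error(solve_delta_categorical(matrix(0, 5, 2), c(0.6, 0.6)),
               "infeasible")
})

test_that("intercept-only multinomial calibration matches the closed-form softmax shift", {
  set.seed(45)
  for (i in 1:5) {
    theta0 <- rnorm(3)
    eta <- matrix(theta0, 30, 3, byrow = TRUE)
    raw <- runif(4, 0.3, 2)
    tgt <- raw / sum(raw)
    sol <- solve_delta_categorical(eta, tgt[2:4])
    p_hat <- c(1, exp(theta0)) / (1 + sum(exp(theta0)))
    closed <- log(tgt[2:4] / tgt[1]) - log(p_hat[2:4] / p_hat[1])
    expect_equal(sol$delta, closed, tolerance = 1e-7)
  }
})

test_that("multinomial solver matches the nested-bisection brute force (3 levels)", {
  set.seed(46)
  for (i in 1:8) {
    eta <- matrix(rnorm(40 * 2, sd = runif(1, 0.5, 2)), 40, 2)
    raw <- runif(3, 0.4, 2)
    targets <- (raw / sum(raw))[2:3]
    sol <- solve_delta_categorical(eta, targets)
    oracle <- nested_bisection_oracle(eta, targets)
    expect_lt(max(abs(sol$delta - oracle)), 1e-6)
  }
})

test_that("binary and two-level categorical solvers agree", {
  set.seed(47)
  for (i in 1:10) {
    eta <- rnorm(50, sd = runif(1, 0.5, 2))
    target <- runif(1, 0.1, 0.9)
    db <- solve_delta_binary(eta, target)$delta
    dc <- solve_delta_categorical(matrix(eta, ncol = 1), target)$delta
    expect_lt(abs(db - dc), 1e-8)
  }
})

test_that("solving restores the total-probability identity", {
  set.seed(48)
  eta <- rnorm(80, sd = 1.5)
  p_r <- 0.55; p_obs <- 0.8; p_pop <- 0.7
  tgt <- target_missing_proportion(p_pop, p_obs, p_r)
  sol <- solve_delta_binary(eta, tgt)
  achieved <- predicted_missing_proportion(sol$delta, eta)
  expect_equal(p_obs * p_r + achieved * (1 - p_r), p_pop, tolerance = 1e-9)
})
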