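toy2 <- matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE)

test_that("markov_step propagates occupancy and conserves mass", {
  expect_equal(markov_step(c(0.4, 0.6), diag(2)), c(0.4, 0.6))
  expect_equal(markov_step(c(1, 0), toy2), c(0.9, 0.1))
  withr::local_seed(5)
  for (i in 1:20) {
    occ <- as.vector(stats::rmultinom(1, 100, rep(1, 4))) / 100
    M <- matrix(rgamma(16, 1), 4, 4)
    M <- M / rowSums(M)
    expect_equal(sum(markov_step(occ, M)), 1, tolerance = 1e-12)
  }
  bad <- matrix(c(0.5, 0.4, 0, 1), 2, 2, byrow = TRUE)
  expect_error(markov_step(c(1, 0), bad), class = "excea_validation_error")
})

test_that("build_trace matches the matrix-power oracle and keeps death monotone", {
  tr <- build_trace(c(1, 0), toy2, 5)
  expect_equal(nrow(tr), 6)
  # time-homogeneous trace row t = initial %*% M^t
  Mt <- diag(2)
  for (t in 0:5) {
    expect_equal(unclass(tr)[t + 1, ], drop(c(1, 0) %*% Mt),
                 tolerance = 1e-14, ignore_attr = TRUE)
    Mt <- Mt %*% toy2
  }
  expect_true(all(diff(unclass(tr)[, 2]) >= 0))
  expect_equal(rowSums(unclass(tr)), rep(1, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(build_trace(c(1, 0), toy2, 0), class = "excea_domain_error")
  # failures inside matrix_fn are tagged with the cycle
  expect_error(build_trace(c(1, 0), function(t) stop("boom"), 3), "cycle 0")
})

test_that("discount factors follow the cycle-end convention", {
  expect_equal(discount_factor(0.05, 0), 1)
  expect_equal(discount_factor(0.05, 2), 0.907029, tolerance = 1e-6)
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
  expect_error(discount_factor(0.05, -1), class = "excea_domain_error")
  expect_error(discount_factor(-0.01, 1), class = "excea_domain_error")
})

test_that("accrual reproduces the half-cycle trapezoid closed forms", {
  alive <- matrix(c(rep(1, 6), rep(0, 6)), ncol = 2)
  rw <- cycle_rewards(state_cost = c(0, 0), state_utility = c(1, 0))
  out0 <- accrue_outcomes(alive, NULL, rw, rate = 0)
  expect_equal(out0$qaly, 5)
  expect_equal(out0$cost, 0)
  out5 <- accrue_outcomes(alive, NULL, rw, rate = 0.05)
  expect_equal(out5$qaly, 0.5 + sum(1.05^-(1:4)) + 0.5 * 1.05^-5,
               tolerance = 1e-12)
  expect_equal(out5$qaly, 4.437714, tolerance = 1e-6)
  # without the correction, all six cycle points count fully
  outf <- accrue_outcomes(alive, NULL, rw, rate = 0, half_cycle = FALSE)
  expect_equal(outf$qaly, 6)
  # discounted totals are non-increasing in the rate
  rates <- c(0, 0.01, 0.03, 0.05, 0.1)
  q <- vapply(rates, function(r) accrue_outcomes(alive, NULL, rw, r)$qaly,
              numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("transition rewards attach to flows, discounted at arrival", {
  # everyone moves state 1 -> 2 in cycle 1 and stays
  M <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)
  tr <- build_trace(c(1, 0), M, 3)
  flows <- lapply(1:3, function(t) unclass(tr)[t, ] * M)
  tc <- matrix(c(0, 1000, 0, 0), 2, 2, byrow = TRUE)
  td <- matrix(c(0, 0.1, 0, 0), 2, 2, byrow = TRUE)
  rw <- cycle_rewards(c(0, 0), c(1, 1), trans_cost = tc,
                      trans_disutility = td)
  out <- accrue_outcomes(tr, flows, rw, rate = 0.05)
  expect_equal(out$cost, 1000 * 1.05^-1, tolerance = 1e-12)
  # disutility subtracts once from the QALY stream
  expect_equal(out$qaly,
               (0.5 + 1.05^-1 + 1.05^-2 + 0.5 * 1.05^-3) - 0.1 * 1.05^-1,
               tolerance = 1e-12)
  # a one-time cohort cost lands at its cycle's discount factor, unhalved
  rw2 <- rep(list(rw), 4)
  rw2[[2]] <- cycle_rewards(c(0, 0), c(1, 1), one_time_cost = 500)
  out2 <- accrue_outcomes(tr, flows, rw2, rate = 0.05)
  expect_equal(out2$cost, 500 * 1.05^-1, tolerance = 1e-12)
})

test_that("accrual agrees with a per-individual microsimulation oracle", {
  M <- matrix(c(0.7, 0.2, 0.1,
                0.0, 0.8, 0.2,
                0.0, 0.0, 1.0), 3, 3, byrow = TRUE)
  sc <- c(100, 300, 0)
  su <- c(0.9, 0.6, 0)
  tc <- matrix(0, 3, 3); tc[1, 2] <- 1000; tc[1, 3] <- 500
  td <- matrix(0, 3, 3); td[1, 2] <- 0.1
  horizon <- 10; rate <- 0.03

  tr <- build_trace(c(1, 0, 0), M, horizon)
  flows <- lapply(seq_len(horizon), function(t) unclass(tr)[t, ] * M)
  rw <- cycle_rewards(sc, su, trans_cost = tc, trans_disutility = td)
  out <- accrue_outcomes(tr, flows, rw, rate = rate)

  withr::local_seed(404)
  sim <- microsim_oracle(2e4, M, horizon, sc, su, tc, td, rate)
  se_cost <- stats::sd(sim$cost) / sqrt(length(sim$cost))
  se_qaly <- stats::sd(sim$qaly) / sqrt(length(sim$qaly))
  expect_lt(abs(mean(sim$cost) - out$cost), 3 * se_cost)
  expect_lt(abs(mean(sim$qaly) - out$qaly), 3 * se_qaly)
})

test_that("accrual validates reward dimensions", {
  alive <- matrix(c(rep(1, 3), rep(0, 3)), ncol = 2)
  rw3 <- cycle_rewards(c(0, 0, 0), c(1, 1, 0))
  expect_error(accrue_outcomes(alive, NULL, rw3),
               class = "excea_validation_error")
  rw <- cycle_rewards(c(0, 0), c(1, 0))
  expect_error(accrue_outcomes(alive, NULL, rep(list(rw), 2)),
               class = "excea_validation_error")
  expect_error(cycle_rewards(c(0, 0), c(1.2, 0)),
               class = "excea_validation_error")
})
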