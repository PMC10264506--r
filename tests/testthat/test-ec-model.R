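test_that("baseline risks annualise by the probability-rate equations", {
  risks <- annualize_baseline_risks(point_estimates(fixture_registry()))
  expect_equal(risks$p_cvd, 0.01220881, tolerance = 1e-6)
  expect_equal(risks$p_recurrence, 0.01941175, tolerance = 1e-6)
  expect_equal(risks$d_post_chd, 0.02993992, tolerance = 1e-6)
  expect_equal(risks$d_post_hf, 0.06752366, tolerance = 1e-6)
  expect_equal(risks$d_post_recurrence, 0.08971790, tolerance = 1e-6)
  # case fatalities pass through unchanged
  expect_equal(risks$fatal_stroke, 0.478)
  expect_equal(risks$fatal_chd, 0.424)
  expect_equal(risks$fatal_hf, 0.424)
  expect_error(annualize_baseline_risks(list(p_cvd_14yr = 0.1)),
               class = "excea_missing_parameter")
})

test_that("the transition matrix degenerates to identity without any risk", {
  M <- build_transition_matrix(null_draw(), standard_care_arm(), 64,
                               zero_life_table())
  expect_equal(unclass(M), diag(6), ignore_attr = TRUE)
})

test_that("exercise hazard ratios strictly reduce event exits", {
  draw <- point_estimates(fixture_registry())
  lt <- generate_life_table()
  Mex <- build_transition_matrix(draw, exercise_arm(), 64, lt)
  Msc <- build_transition_matrix(draw, standard_care_arm(), 64, lt)
  # every event destination (post states and recurrence) shrinks under hr < 1
  expect_true(all(Mex[1, 2:5] < Msc[1, 2:5]))
  expect_gt(Mex[1, 1], Msc[1, 1])
  # post-event rows only exit to death; dead row is identity
  for (s in 2:5) {
    expect_equal(sum(Mex[s, -c(s, 6)]), 0)
  }
  expect_equal(Mex[6, ], c(rep(0, 5), 1), ignore_attr = TRUE)
})

test_that("transition rows are stochastic across random draws", {
  reg <- fixture_registry()
  draws <- sample_parameters(reg, n = 200, seed = 21)
  lt <- generate_life_table()
  for (i in seq_len(nrow(draws))) {
    M <- build_transition_matrix(as.list(draws[i, -1]),
                                 exercise_arm(), 64 + (i %% 6), lt)
    expect_equal(rowSums(M), rep(1, 6), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(M >= 0 & M <= 1))
    ev <- attr(M, "events")
    expect_equal(M[1, 6], sum(ev), tolerance = 1e-12)
  }
})

test_that("background mortality alone reproduces the life table survival", {
  lt <- generate_life_table()
  draw <- null_draw()
  out <- run_arm(draw, standard_care_arm(), 10, lt, flat_utility_table(),
                 discount_rate = 0)
  q <- lt$qx[lt$age %in% (64:73)]
  expect_equal(unclass(out$trace)[-1, 1], cumprod(1 - q),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("rewards wire utilities, disutilities and costs to the states", {
  draw <- point_estimates(fixture_registry())
  ut <- flat_utility_table(0.8)
  sc <- build_rewards(draw, standard_care_arm(), 64, 1, ut)
  expect_equal(sc$state_cost[1], 1601)
  expect_equal(sc$state_cost[2], 1601 + 5662)
  expect_equal(sc$state_cost[5], 4880)
  expect_equal(sc$state_cost[6], 0)
  expect_equal(sc$one_time_cost, 0)
  expect_equal(sc$state_utility[1], 0.8)
  expect_equal(sc$state_utility[5], 0.8 - 0.112)
  expect_equal(sc$state_utility, c(0.8, 0.651, 0.720, 0.789, 0.688, 0))
  expect_equal(sc$trans_cost[1, 2:5], c(12215, 10177, 10270, 13126),
               ignore_attr = TRUE)
  expect_equal(sc$trans_disutility[1, 2:4], c(0.075, 0.15, 0.07),
               ignore_attr = TRUE)

  ex <- build_rewards(draw, exercise_arm(), 64, 1, ut)
  expect_equal(ex$state_cost[1] + ex$one_time_cost, 1601 + 1381)
  ex2 <- build_rewards(draw, exercise_arm(), 65, 2, ut)
  expect_equal(ex2$one_time_cost, 0)

  # recurrence utility floors at zero
  low <- build_rewards(draw, standard_care_arm(), 64, 1,
                       flat_utility_table(0.05))
  expect_equal(low$state_utility[5], 0)
  expect_error(build_rewards(draw, standard_care_arm(), 300, 1, ut),
               class = "excea_range_error")
})

test_that("fatal-event transition cost averages over causes of death", {
  draw <- point_estimates(fixture_registry())
  lt <- flat_life_table(0)  # no background death: only fatal events in 1->6
  M <- build_transition_matrix(draw, standard_care_arm(), 64, lt)
  ev <- attr(M, "events")
  rw <- build_rewards(draw, standard_care_arm(), 64, 1, flat_utility_table(),
                      fatal_weights = ev)
  expected <- sum(ev[1:3] * c(12215, 10177, 10270)) / sum(ev[1:3])
  expect_equal(rw$trans_cost[1, 6], expected, tolerance = 1e-12)
  # override replaces the default acute-cost mapping
  rw2 <- build_rewards(draw, standard_care_arm(), 64, 1, flat_utility_table(),
                       fatal_event_cost = c(stroke = 0, chd = 0, hf = 0),
                       fatal_weights = ev)
  expect_equal(rw2$trans_cost[1, 6], 0)
})

test_that("run_arm trivial cases isolate the intervention cost", {
  lt <- zero_life_table()
  ut <- flat_utility_table(1)
  sc <- run_arm(null_draw(), standard_care_arm(), 5, lt, ut,
                discount_rate = 0)
  expect_equal(sc$qaly, 5)
  expect_equal(sc$cost, 0)
  ex <- run_arm(null_draw(c_exercise = 1381), exercise_arm(), 5, lt, ut,
                discount_rate = 0.05)
  expect_equal(ex$cost, 1381 * 1.05^-1, tolerance = 1e-12)
  expect_equal(ex$qaly, 0.5 + sum(1.05^-(1:4)) + 0.5 * 1.05^-5,
               tolerance = 1e-12)
})

test_that("null intervention gives exactly equivalent arms", {
  reg <- fixture_registry()
  draw <- point_estimates(reg)
  draw$hr_cvd_exercise <- 1
  draw$hr_recurrence_exercise <- 1
  draw$c_exercise <- 0
  lt <- generate_life_table(); ut <- generate_utility_table()
  ex <- run_arm(draw, exercise_arm(), 5, lt, ut)
  sc <- run_arm(draw, standard_care_arm(), 5, lt, ut)
  expect_identical(ex$cost, sc$cost)
  expect_identical(ex$qaly, sc$qaly)
})

test_that("exercise keeps more of the cohort event-free at every cycle", {
  reg <- fixture_registry()
  draws <- sample_parameters(reg, n = 50, seed = 31)
  lt <- generate_life_table(); ut <- generate_utility_table()
  for (i in seq_len(nrow(draws))) {
    draw <- as.list(draws[i, -1])
    ex <- run_arm(draw, exercise_arm(), 5, lt, ut)
    sc <- run_arm(draw, standard_care_arm(), 5, lt, ut)
    expect_true(all(unclass(ex$trace)[, 1] >= unclass(sc$trace)[, 1]))
  }
})
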