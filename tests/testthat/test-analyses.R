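test_that("base case satisfies the net-benefit identities", {
  reg <- fixture_registry()
  bc <- base_case(reg)
  expect_s3_class(bc, "ec_ce_result")
  expect_identical(bc$inmb, bc$wtp * bc$delta_qaly - bc$delta_cost)
  expect_identical(bc$icer, bc$delta_cost / bc$delta_qaly)
  g <- glance(bc)
  expect_named(g, c("delta_cost", "delta_qaly", "icer", "inmb", "wtp",
                    "status", "kind"))
  expect_equal(tidy(bc)$arm, c("exercise", "standard_care"))
  # QALYs and costs must be positive and bounded by the horizon
  expect_true(all(tidy(bc)$qaly > 0 & tidy(bc)$qaly < 5))
})

test_that("null intervention is flagged equivalent with undefined ICER", {
  reg <- edited_registry(function(tab) {
    tab$mean[tab$name == "hr_cvd_exercise"] <- 1
    tab$ci_low[tab$name == "hr_cvd_exercise"] <- 1
    tab$ci_high[tab$name == "hr_cvd_exercise"] <- 1
    tab$mean[tab$name == "hr_recurrence_exercise"] <- 1
    tab$ci_low[tab$name == "hr_recurrence_exercise"] <- 1
    tab$ci_high[tab$name == "hr_recurrence_exercise"] <- 1
    tab$mean[tab$name == "c_exercise"] <- 0
    tab$ci_low[tab$name == "c_exercise"] <- 0
    tab$ci_high[tab$name == "c_exercise"] <- 0
    tab$family[tab$name %in% c("hr_cvd_exercise", "hr_recurrence_exercise",
                               "c_exercise")] <- "fixed"
    tab
  })
  bc <- base_case(reg)
  expect_equal(bc$delta_cost, 0)
  expect_equal(bc$delta_qaly, 0)
  expect_true(is.na(bc$icer))
  expect_equal(bc$status, "equivalent")
})

test_that("dominance is flagged when exercise saves money and QALYs", {
  reg <- fixture_registry()
  bc7 <- base_case(reg, horizon = 7)
  if (bc7$delta_cost < 0 && bc7$delta_qaly > 0) {
    expect_equal(bc7$status, "dominant")
    expect_gt(bc7$inmb, 0)
  } else {
    skip("fixture no longer dominant at horizon 7")
  }
})

test_that("PSA is seed-deterministic and degenerates to the base case", {
  reg <- fixture_registry()
  p1 <- run_psa(reg, n_iter = 25, seed = 42)
  p2 <- run_psa(reg, n_iter = 25, seed = 42)
  expect_identical(p1$iterations, p2$iterations)
  expect_identical(glance(p1), glance(p2))

  fixed <- fixed_registry()
  pf <- run_psa(fixed, n_iter = 1, seed = 1)
  bc <- base_case(fixed)
  expect_identical(pf$summary$delta_cost, bc$delta_cost)
  expect_identical(pf$summary$delta_qaly, bc$delta_qaly)
  expect_identical(pf$summary$icer, bc$icer)
  # ratio-of-means ICER equals mean increments ratio
  it <- tidy(p1)
  expect_equal(p1$summary$icer, mean(it$delta_cost) / mean(it$delta_qaly),
               tolerance = 1e-12)
  q <- glance(p1)
  expect_true(q$delta_cost_lo <= q$delta_cost &&
                q$delta_cost <= q$delta_cost_hi)
  expect_error(run_psa(reg, n_iter = 0), class = "excea_domain_error")
})

test_that("CEAC has its definitional limits and monotonicity", {
  reg <- fixture_registry()
  psa <- run_psa(reg, n_iter = 100, seed = 8)
  it <- tidy(psa)
  cc <- ceac(psa, wtp_grid = c(0, 25000, 50000, 1e9))
  expect_equal(cc$p_cost_effective[1], mean(it$delta_cost < 0))
  expect_equal(cc$p_cost_effective[4], mean(it$delta_qaly > 0))
  if (all(it$delta_qaly >= 0)) {
    expect_true(all(diff(cc$p_cost_effective) >= 0))
  }
  expect_error(ceac(psa, wtp_grid = numeric(0)),
               class = "excea_validation_error")
  # degenerate PSA with uniformly positive iNMB is certain
  pf <- run_psa(fixed_registry(), n_iter = 3, seed = 1)
  stopifnot(pf$summary$inmb > 0)
  expect_equal(ceac(pf, 50000)$p_cost_effective, 1)
})

test_that("tornado bars are CI-bounded one-way ICER ranges, widest first", {
  reg <- fixture_registry()
  expect_message(tor <- tornado(reg), "skipping")
  expect_true(all(diff(tor$width) <= 0))
  expect_true(all(c("parameter", "icer_low", "icer_high", "width") %in%
                    names(tor)))
  # ICER increases with the intervention cost
  ex <- tor[tor$parameter == "c_exercise", ]
  expect_gt(ex$icer_high, ex$icer_low)
  expect_false(any(c("q_age", "u_baseline", "share_stroke") %in%
                     tor$parameter))

  # a collapsed CI yields a zero-width bar
  regz <- edited_registry(function(tab) {
    i <- tab$name == "du_hf"
    tab$ci_low[i] <- tab$mean[i]; tab$ci_high[i] <- tab$mean[i]
    tab
  })
  torz <- suppressMessages(tornado(regz))
  expect_equal(torz$width[torz$parameter == "du_hf"], 0, tolerance = 1e-9)
})

test_that("horizon sweep tracks cost-effectiveness over time", {
  reg <- fixture_registry()
  sw <- horizon_sweep(reg, years = 1:8)
  expect_equal(sw$horizon, 1:8)
  # intervention cost dominates a 1-year horizon
  expect_gt(sw$icer[1], 50000)
  # ICER improves monotonically with the horizon on the base-case fixture
  expect_true(all(diff(sw$icer) < 0))
  expect_true(all(sw$inmb[sw$dominant] > 0))
  fce <- attr(sw, "first_cost_effective_year")
  expect_true(all(sw$cost_effective[sw$horizon >= fce]))
  expect_error(horizon_sweep(reg, years = c(0, 5)),
               class = "excea_domain_error")
})

test_that("extended supervision adds exactly the discounted session fees", {
  reg <- fixture_registry()
  bc <- base_case(reg)
  es <- extended_supervision_scenario(reg)
  expect_equal(es$delta_cost, bc$delta_cost + 36 * 75 * 1.05^-1,
               tolerance = 1e-9)
  expect_identical(es$delta_qaly, bc$delta_qaly)
  expect_gt(es$icer, bc$icer)
})

test_that("result plots build without error", {
  reg <- fixture_registry()
  psa <- run_psa(reg, n_iter = 20, seed = 2)
  expect_s3_class(autoplot(psa), "ggplot")
  expect_s3_class(autoplot(ceac(psa, c(0, 50000))), "ggplot")
  expect_s3_class(plot_tornado(suppressMessages(tornado(reg)), top = 5),
                  "ggplot")
  expect_s3_class(autoplot(horizon_sweep(reg, years = 1:3)), "ggplot")
  draw <- point_estimates(reg)
  arm <- run_arm(draw, exercise_arm(), 5, generate_life_table(),
                 generate_utility_table())
  expect_s3_class(autoplot(arm$trace), "ggplot")
})
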