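default_tables <- function(life_table, utility_table) {
  list(life = life_table %||% generate_life_table(),
       util = utility_table %||% generate_utility_table())
}

new_ce_result <- function(arms, wtp, kind = "base_case") {
  dc <- arms$cost[arms$arm == "exercise"] - arms$cost[arms$arm == "standard_care"]
  dq <- arms$qaly[arms$arm == "exercise"] - arms$qaly[arms$arm == "standard_care"]
  structure(list(
    arms = arms,
    delta_cost = dc, delta_qaly = dq,
    icer = if (dq != 0) dc / dq else NA_real_,
    status = ce_status(dc, dq),
    wtp = wtp,
    inmb = wtp * dq - dc,
    kind = kind
  ), class = "ec_ce_result")
}

ce_status <- function(dc, dq) {
  if (dq == 0) {
    if (dc == 0) "equivalent" else "icer_undefined"
  } else if (dc < 0 && dq > 0) "dominant"
  else if (dc > 0 && dq < 0) "dominated"
  else "trade_off"
}

#' Deterministic base-case cost-effectiveness analysis
#'
#' Runs both strategy arms at the registry's point estimates and compares
#' them: incremental cost, incremental QALYs, ICER (with a dominance flag
#' when exercise is cheaper and more effective) and incremental net monetary
#' benefit `iNMB = wtp * dQALY - dCost`.
#'
#' @param registry An `ec_registry` from [parse_parameter_table()].
#' @param horizon Time horizon in years (default 5).
#' @param wtp Willingness-to-pay threshold in AUD per QALY (default 50,000).
#' @param life_table,utility_table Age-indexed tables; defaults are the
#'   synthetic [generate_life_table()] / [generate_utility_table()].
#' @param discount_rate Annual discount rate (default 0.05).
#' @param supervision_addon Extra first-cycle exercise cost (AUD), used by
#'   the extended-supervision scenario.
#' @param fatal_event_cost Optional fatal-event cost override.
#' @return An object of class `ec_ce_result`; see [tidy.ec_ce_result()] and
#'   [glance.ec_ce_result()].
#' @examples
#' reg <- parse_parameter_table(excea_example("parameters.csv"))
#' glance(base_case(reg))
#' @export
base_case <- function(registry, horizon = 5, wtp = 50000,
                      life_table = NULL, utility_table = NULL,
                      discount_rate = 0.05, supervision_addon = 0,
                      fatal_event_cost = NULL) {
  tabs <- default_tables(life_table, utility_table)
  draw <- point_estimates(registry)
  evaluate_draw(draw, horizon, tabs$life, tabs$util, discount_rate,
                supervision_addon, fatal_event_cost) |>
    new_ce_result(wtp = wtp)
}

evaluate_draw <- function(draw, horizon, life, util, discount_rate,
                          supervision_addon = 0, fatal_event_cost = NULL) {
  ex <- run_arm(draw, exercise_arm(supervision_addon), horizon, life, util,
                discount_rate, fatal_event_cost = fatal_event_cost)
  sc <- run_arm(draw, standard_care_arm(), horizon, life, util,
                discount_rate, fatal_event_cost = fatal_event_cost)
  tibble::tibble(arm = c("exercise", "standard_care"),
                 cost = c(ex$cost, sc$cost),
                 qaly = c(ex$qaly, sc$qaly))
}

#' Probabilistic sensitivity analysis
#'
#' Propagates joint parameter uncertainty through the model by Monte Carlo:
#' each iteration takes one joint draw from the calibrated distributions and
#' runs both arms on it (common random parameters across arms), recording
#' per-iteration costs and QALYs. The summary reports means, 2.5/97.5
#' percentile intervals, the ratio-of-means ICER and the iNMB.
#'
#' @inheritParams base_case
#' @param n_iter Number of Monte Carlo iterations (default 10,000).
#' @param seed Integer seed; identical seeds reproduce the analysis exactly.
#' @return An object of class `ec_psa` with elements `iterations` (tibble:
#'   `.draw`, per-arm costs/QALYs, increments, iNMB), `summary`
#'   (an `ec_ce_result` from the means), `n_iter` and `seed`.
#' @examples
#' reg <- parse_parameter_table(excea_example("parameters.csv"))
#' psa <- run_psa(reg, n_iter = 50, seed = 1)
#' glance(psa)
#' @export
run_psa <- function(registry, n_iter = 10000, seed = NULL, horizon = 5,
                    wtp = 50000, life_table = NULL, utility_table = NULL,
                    discount_rate = 0.05, supervision_addon = 0,
                    fatal_event_cost = NULL) {
  if (n_iter < 1) abort("`n_iter` must be at least 1.",
                        class = "excea_domain_error")
  tabs <- default_tables(life_table, utility_table)
  draws <- sample_parameters(registry, n = n_iter, seed = seed)
  cost_ex <- cost_sc <- qaly_ex <- qaly_sc <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    draw <- as.list(draws[i, -1])
    res <- tryCatch(
      evaluate_draw(draw, horizon, tabs$life, tabs$util, discount_rate,
                    supervision_addon, fatal_event_cost),
      error = function(e) abort(sprintf("PSA iteration %d failed", i),
                                parent = e)
    )
    cost_ex[i] <- res$cost[1]; qaly_ex[i] <- res$qaly[1]
    cost_sc[i] <- res$cost[2]; qaly_sc[i] <- res$qaly[2]
  }
  iterations <- tibble::tibble(
    .draw = seq_len(n_iter),
    cost_exercise = cost_ex, qaly_exercise = qaly_ex,
    cost_standard_care = cost_sc, qaly_standard_care = qaly_sc,
    delta_cost = cost_ex - cost_sc, delta_qaly = qaly_ex - qaly_sc,
    inmb = wtp * (qaly_ex - qaly_sc) - (cost_ex - cost_sc)
  )
  means <- tibble::tibble(
    arm = c("exercise", "standard_care"),
    cost = c(mean(cost_ex), mean(cost_sc)),
    qaly = c(mean(qaly_ex), mean(qaly_sc))
  )
  structure(list(
    iterations = iterations,
    summary = new_ce_result(means, wtp = wtp, kind = "psa_means"),
    n_iter = n_iter, seed = seed, wtp = wtp
  ), class = "ec_psa")
}

psa_quantiles <- function(psa, probs = c(0.025, 0.975)) {
  it <- psa$iterations
  vars <- c("cost_exercise", "qaly_exercise", "cost_standard_care",
            "qaly_standard_care", "delta_cost", "delta_qaly", "inmb")
  out <- lapply(vars, function(v) quantile(it[[v]], probs, names = FALSE))
  ratio <- it$delta_cost / it$delta_qaly
  out <- c(out, list(quantile(ratio[is.finite(ratio)], probs, names = FALSE)))
  tibble::tibble(quantity = c(vars, "icer_pairwise"),
                 lo = vapply(out, `[`, numeric(1), 1),
                 hi = vapply(out, `[`, numeric(1), 2))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that exercise is
#' cost-effective: the fraction of PSA iterations with positive incremental
#' net monetary benefit `wtp * dQALY_i - dCost_i > 0`.
#'
#' @param psa An `ec_psa` from [run_psa()].
#' @param wtp_grid Vector of willingness-to-pay values (default 0 to
#'   100,000 by 1,000).
#' @return A tibble of class `ec_ceac` with columns `wtp`, `p_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  if (length(wtp_grid) == 0) {
    abort("`wtp_grid` must be non-empty.", class = "excea_validation_error")
  }
  it <- psa$iterations
  p <- vapply(wtp_grid, function(l) mean(l * it$delta_qaly - it$delta_cost > 0),
              numeric(1))
  structure(tibble::tibble(wtp = wtp_grid, p_cost_effective = p),
            class = c("ec_ceac", class(tibble::tibble())))
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the deterministic base case with each CI-carrying parameter set
#' to its lower then upper 95% bound, all other parameters at their means,
#' and records the resulting ICER. Entries are sorted by decreasing bar
#' width `|ICER_high - ICER_low|`. Parameters without both CI bounds
#' (dirichlet shares, table lookups, fixed values) are skipped with a
#' message.
#'
#' @inheritParams base_case
#' @return A tibble of class `ec_tornado` with columns `parameter`,
#'   `icer_low`, `icer_high`, `width`, plus the base-case ICER as attribute
#'   `icer_base`.
#' @export
tornado <- function(registry, horizon = 5, wtp = 50000,
                    life_table = NULL, utility_table = NULL,
                    discount_rate = 0.05, supervision_addon = 0,
                    fatal_event_cost = NULL) {
  tabs <- default_tables(life_table, utility_table)
  base_draw <- point_estimates(registry)
  has_ci <- !is.na(registry$ci_low) & !is.na(registry$ci_high) &
    samplable(registry)
  skipped <- registry$name[!has_ci]
  if (length(skipped) > 0) {
    rlang::inform(paste0("tornado: skipping parameter(s) without CI bounds: ",
                         paste(skipped, collapse = ", ")))
  }
  icer_at <- function(draw) {
    res <- evaluate_draw(draw, horizon, tabs$life, tabs$util, discount_rate,
                         supervision_addon, fatal_event_cost)
    dc <- res$cost[1] - res$cost[2]; dq <- res$qaly[1] - res$qaly[2]
    if (dq == 0) NA_real_ else dc / dq
  }
  rows <- purrr::map(which(has_ci), function(i) {
    lo_draw <- hi_draw <- base_draw
    lo_draw[[registry$name[i]]] <- registry$ci_low[i]
    hi_draw[[registry$name[i]]] <- registry$ci_high[i]
    tibble::tibble(parameter = registry$name[i],
                   icer_low = icer_at(lo_draw), icer_high = icer_at(hi_draw))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(width = abs(.data$icer_high - .data$icer_low)) |>
    dplyr::arrange(dplyr::desc(.data$width))
  attr(out, "icer_base") <- icer_at(base_draw)
  class(out) <- c("ec_tornado", class(tibble::tibble()))
  out
}

#' Time-horizon sweep
#'
#' Re-runs the deterministic base case at each requested horizon and reports
#' when the intervention first becomes cost-effective (positive iNMB at the
#' threshold) and when it first dominates standard care (cheaper and more
#' effective).
#'
#' @inheritParams base_case
#' @param years Horizons to evaluate (integer years within 1 to 40).
#' @return A tibble of class `ec_sweep` with one row per horizon
#'   (`horizon`, `delta_cost`, `delta_qaly`, `icer`, `inmb`, `dominant`,
#'   `cost_effective`) and attributes `first_cost_effective_year`,
#'   `first_dominant_year` (NA when never reached).
#' @export
horizon_sweep <- function(registry, years = 1:10, wtp = 50000,
                          life_table = NULL, utility_table = NULL,
                          discount_rate = 0.05, supervision_addon = 0,
                          fatal_event_cost = NULL) {
  if (any(years < 1 | years > 40)) {
    abort("`years` must lie within 1..40.", class = "excea_domain_error")
  }
  rows <- purrr::map(years, function(h) {
    r <- base_case(registry, horizon = h, wtp = wtp,
                   life_table = life_table, utility_table = utility_table,
                   discount_rate = discount_rate,
                   supervision_addon = supervision_addon,
                   fatal_event_cost = fatal_event_cost)
    tibble::tibble(horizon = h, delta_cost = r$delta_cost,
                   delta_qaly = r$delta_qaly, icer = r$icer, inmb = r$inmb,
                   dominant = r$status == "dominant",
                   cost_effective = r$inmb > 0)
  })
  out <- dplyr::bind_rows(rows)
  first_or_na <- function(x) if (any(x)) out$horizon[which(x)[1]] else NA_integer_
  attr(out, "first_cost_effective_year") <- first_or_na(out$cost_effective)
  attr(out, "first_dominant_year") <- first_or_na(out$dominant)
  class(out) <- c("ec_sweep", class(tibble::tibble()))
  out
}

#' Extended-supervision scenario
#'
#' Costs an alternative programme design in which supervision continues for
#' a further year: 36 additional physiologist-supervised sessions at $75 per
#' hour (AUD 2,700), added to the exercise arm's first-cycle intervention
#' cost. Effectiveness is unchanged.
#'
#' @inheritParams base_case
#' @param sessions,rate_per_hour Add-on schedule (defaults 36 sessions at
#'   $75/hour).
#' @return An `ec_ce_result` (kind `"extended_supervision"`).
#' @export
extended_supervision_scenario <- function(registry, horizon = 5, wtp = 50000,
                                          life_table = NULL,
                                          utility_table = NULL,
                                          discount_rate = 0.05,
                                          sessions = 36, rate_per_hour = 75,
                                          fatal_event_cost = NULL) {
  res <- base_case(registry, horizon = horizon, wtp = wtp,
                   life_table = life_table, utility_table = utility_table,
                   discount_rate = discount_rate,
                   supervision_addon = sessions * rate_per_hour,
                   fatal_event_cost = fatal_event_cost)
  res$kind <- "extended_supervision"
  res
}
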