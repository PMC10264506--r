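#' The six health states of the model
#'
#' Ordered state identifiers: `no_cvd` (post-treatment, disease-free),
#' `post_stroke`, `post_chd`, `post_hf` (survivors of a first cardiovascular
#' event), `post_recurrence` (survivors of a cancer recurrence) and the
#' absorbing `dead` state. States are mutually exclusive: a first CVD event
#' or recurrence moves a woman out of `no_cvd` permanently, and the post-
#' event states admit no further event transitions, only death.
#'
#' @return Character vector of the six state names, in model order.
#' @export
health_states <- function() {
  c("no_cvd", "post_stroke", "post_chd", "post_hf", "post_recurrence", "dead")
}

DEAD <- 6L

#' Define a strategy arm
#'
#' @param label `"exercise"` or `"standard_care"`.
#' @param hr_cvd,hr_recurrence Hazard ratios applied to the baseline CVD and
#'   recurrence risks. For the exercise arm these default to the registry
#'   draw's values at run time (pass `NULL`); standard care fixes both at 1.
#' @param supervision_addon Extra first-cycle intervention cost (AUD) on top
#'   of the base programme fee, e.g. `36 * 75` for a year of extended
#'   supervised sessions. Ignored for standard care.
#' @return A list of class `ec_arm`.
#' @examples
#' exercise_arm()
#' standard_care_arm()
#' @export
strategy_arm <- function(label, hr_cvd = NULL, hr_recurrence = NULL,
                         supervision_addon = 0) {
  label <- match.arg(label, c("exercise", "standard_care"))
  if (label == "standard_care") {
    hr_cvd <- 1; hr_recurrence <- 1; supervision_addon <- 0
  }
  structure(list(label = label, hr_cvd = hr_cvd,
                 hr_recurrence = hr_recurrence,
                 supervision_addon = supervision_addon),
            class = "ec_arm")
}

#' @rdname strategy_arm
#' @export
exercise_arm <- function(supervision_addon = 0) {
  strategy_arm("exercise", supervision_addon = supervision_addon)
}

#' @rdname strategy_arm
#' @export
standard_care_arm <- function() strategy_arm("standard_care")

arm_hrs <- function(arm, draw) {
  list(
    cvd = arm$hr_cvd %||% draw$hr_cvd_exercise,
    rec = arm$hr_recurrence %||% draw$hr_recurrence_exercise
  )
}

as_draw_list <- function(draw) {
  if (is.data.frame(draw)) {
    if (nrow(draw) != 1) {
      abort("`draw` must be a single parameter vector (one row).",
            class = "excea_validation_error")
    }
    draw <- as.list(draw)
  }
  draw
}

need <- function(draw, nm) {
  v <- draw[[nm]]
  if (is.null(v) || is.na(v)) {
    abort(sprintf("parameter '%s' missing from the draw.", nm),
          class = "excea_missing_parameter")
  }
  v
}

#' Annualise the registry's multi-year baseline risks
#'
#' Converts the cumulative risks and multi-year survival fractions tabulated
#' in the sources into one-year cycle probabilities under a constant-hazard
#' assumption: the 14-year cumulative CVD and recurrence risks via
#' [prob_to_rate()]/[rate_to_prob()], and the 5-year post-event and
#' post-recurrence survival fractions via [survival_to_annual_death_prob()].
#' Case-fatality probabilities of the acute events are within-cycle
#' quantities already and pass through unchanged.
#'
#' @param draw One parameter draw (one-row tibble or named list), e.g. from
#'   [point_estimates()] or [sample_parameters()].
#' @return Named list of annual probabilities: `p_cvd`, `p_recurrence`,
#'   `d_post_stroke`, `d_post_chd`, `d_post_hf`, `d_post_recurrence`,
#'   `fatal_stroke`, `fatal_chd`, `fatal_hf`.
#' @examples
#' reg <- parse_parameter_table(excea_example("parameters.csv"))
#' annualize_baseline_risks(point_estimates(reg))$p_cvd
#' @export
annualize_baseline_risks <- function(draw) {
  draw <- as_draw_list(draw)
  follow_up <- 14
  list(
    p_cvd = rate_to_prob(prob_to_rate(need(draw, "p_cvd_14yr"), follow_up)),
    p_recurrence = rate_to_prob(
      prob_to_rate(need(draw, "p_recurrence_14yr"), follow_up)),
    d_post_stroke = survival_to_annual_death_prob(need(draw, "s5_post_stroke"), 5),
    d_post_chd = survival_to_annual_death_prob(need(draw, "s5_post_chd"), 5),
    d_post_hf = survival_to_annual_death_prob(need(draw, "s5_post_hf"), 5),
    d_post_recurrence = survival_to_annual_death_prob(
      need(draw, "s5_post_recurrence"), 5),
    fatal_stroke = need(draw, "p_fatal_stroke"),
    fatal_chd = need(draw, "p_fatal_chd_hf"),
    fatal_hf = need(draw, "p_fatal_chd_hf")
  )
}

#' Build the one-cycle transition matrix at a given attained age
#'
#' From `no_cvd`, the competing exits (cancer recurrence, first CVD event,
#' background death) are resolved simultaneously on the rate scale: each
#' annual probability is converted to a rate, the total exit probability is
#' `1 - exp(-sum of rates)`, and it is allocated to causes in proportion to
#' their rates (order-independent). The CVD exit is split into stroke, CHD
#' and heart failure by the dirichlet shares, and each event is split into
#' fatal (to `dead`, by the event's case fatality) and non-fatal (to its
#' post-event state). Exercise-arm hazard ratios scale the CVD and
#' recurrence risks before conversion. From each post-event state the only
#' exit is death, combining the disease-specific annual death probability
#' with background mortality via [combine_mortality()]; `dead` is absorbing.
#'
#' @param draw One parameter draw (one-row tibble or named list).
#' @param arm An `ec_arm` from [strategy_arm()].
#' @param attained_age Integer age used for the life-table lookup.
#' @param life_table Tibble with columns `age`, `qx`.
#' @return A 6x6 row-stochastic matrix (states in [health_states()] order)
#'   with an `events` attribute recording the decomposition of the
#'   `no_cvd -> dead` entry (fatal event probabilities by type and background
#'   death) needed to attach one-time fatal-event costs to flows.
#' @export
build_transition_matrix <- function(draw, arm, attained_age, life_table) {
  draw <- as_draw_list(draw)
  risks <- annualize_baseline_risks(draw)
  hrs <- arm_hrs(arm, draw)
  q_bg <- lookup_age(life_table, "qx", round(attained_age))
  build_matrix_impl(draw, risks, hrs, q_bg)
}

build_matrix_impl <- function(draw, risks, hrs, q_bg) {
  p_cvd <- apply_hazard_ratio(risks$p_cvd, hrs$cvd)
  p_rec <- apply_hazard_ratio(risks$p_recurrence, hrs$rec)
  shares <- c(need(draw, "share_stroke"), need(draw, "share_chd"),
              need(draw, "share_hf"))
  shares <- shares / sum(shares)

  r <- c(cvd = prob_to_rate(p_cvd), rec = prob_to_rate(p_rec),
         bg = prob_to_rate(min(q_bg, 1 - 1e-12)))
  r_tot <- sum(r)
  p_exit <- rate_to_prob(r_tot)
  alloc <- if (r_tot > 0) r / r_tot * p_exit else c(cvd = 0, rec = 0, bg = 0)

  ev <- alloc[["cvd"]] * shares
  fatal <- ev * c(risks$fatal_stroke, risks$fatal_chd, risks$fatal_hf)
  nonfatal <- ev - fatal

  M <- matrix(0, 6, 6, dimnames = list(health_states(), health_states()))
  M[1, 2:4] <- nonfatal
  M[1, 5] <- alloc[["rec"]]
  M[1, 6] <- alloc[["bg"]] + sum(fatal)
  M[1, 1] <- 1 - p_exit
  d_post <- c(risks$d_post_stroke, risks$d_post_chd, risks$d_post_hf,
              risks$d_post_recurrence)
  for (s in 2:5) {
    M[s, 6] <- combine_mortality(d_post[s - 1], q_bg)
    M[s, s] <- 1 - M[s, 6]
  }
  M[6, 6] <- 1
  if (any(M < 0)) {
    bad <- which(M < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative transition probability in cell (%s -> %s).",
                  health_states()[bad[1]], health_states()[bad[2]]),
          class = "excea_model_error")
  }
  check_stochastic(M)
  attr(M, "events") <- c(fatal_stroke = fatal[[1]], fatal_chd = fatal[[2]],
                         fatal_hf = fatal[[3]], bg_death = alloc[["bg"]])
  M
}

#' Assemble the per-cycle rewards for one arm at a given age
#'
#' State utilities: `no_cvd` takes the age-specific baseline utility;
#' the post-event states take their absolute tabulated utilities;
#' `post_recurrence` takes the baseline utility minus the recurrence
#' disutility (floored at 0); `dead` is 0. One-time disutilities for a
#' first-time stroke/CHD/heart-failure event attach to the non-fatal entry
#' transitions. State costs: every alive non-recurrence state carries annual
#' cancer surveillance; the post-event states add their follow-up costs;
#' `post_recurrence` carries follow-up cancer care (no surveillance).
#' One-time costs attach to event entries (acute treatment), recurrence
#' entry (recurrence treatment) and fatal-event deaths (the configured
#' fatal-event cost, by default the event's acute treatment cost). The
#' exercise programme fee (plus any extended-supervision add-on) enters as a
#' whole-cohort `one_time_cost` in cycle 1 only.
#'
#' @param draw One parameter draw (one-row tibble or named list).
#' @param arm An `ec_arm`.
#' @param attained_age Age for the baseline-utility lookup.
#' @param cycle Cycle index (0-based cycle points; the intervention fee is
#'   charged at `cycle == 1`).
#' @param utility_table Tibble with columns `age`, `utility`.
#' @param fatal_event_cost Optional named override `c(stroke=, chd=, hf=)`
#'   of the one-time cost attached to a fatal event; default: the acute
#'   treatment cost of the event type.
#' @param fatal_weights Optional decomposition of the `no_cvd -> dead` flow
#'   (the `events` attribute of [build_transition_matrix()]); used to weight
#'   the fatal-event cost by cause within the merged death transition. When
#'   absent, background death is assumed negligible in that cell and weights
#'   come from the event shares and case fatalities alone.
#' @return A [cycle_rewards()] object.
#' @export
build_rewards <- function(draw, arm, attained_age, cycle, utility_table,
                          fatal_event_cost = NULL, fatal_weights = NULL) {
  draw <- as_draw_list(draw)
  u_base <- lookup_age(utility_table, "utility", round(attained_age))
  u <- c(u_base,
         need(draw, "u_post_stroke"), need(draw, "u_post_chd"),
         need(draw, "u_post_hf"),
         max(u_base - need(draw, "du_recurrence"), 0),
         0)
  surv <- need(draw, "c_surveillance")
  sc <- c(surv,
          surv + need(draw, "c_post_stroke_fu"),
          surv + need(draw, "c_post_chd_fu"),
          surv + need(draw, "c_post_hf_fu"),
          need(draw, "c_recurrence_fu"),
          0)
  acute <- c(stroke = need(draw, "c_stroke_acute"),
             chd = need(draw, "c_chd_acute"),
             hf = need(draw, "c_hf_acute"))
  fatal_cost <- fatal_event_cost %||% acute

  tc <- matrix(0, 6, 6, dimnames = list(health_states(), health_states()))
  tc[1, 2:4] <- acute
  tc[1, 5] <- need(draw, "c_recurrence_treatment")
  tc[1, 6] <- fatal_death_cost(draw, fatal_cost, fatal_weights)

  td <- matrix(0, 6, 6, dimnames = dimnames(tc))
  td[1, 2:4] <- c(need(draw, "du_stroke"), need(draw, "du_chd"),
                  need(draw, "du_hf"))

  one_time <- if (arm$label == "exercise" && cycle == 1) {
    need(draw, "c_exercise") + arm$supervision_addon
  } else 0

  cycle_rewards(state_cost = sc, state_utility = u,
                trans_cost = tc, trans_disutility = td,
                one_time_cost = one_time)
}

# Expected one-time cost per unit of no_cvd -> dead flow: fatal events carry
# the fatal-event cost, background deaths carry nothing.
fatal_death_cost <- function(draw, fatal_cost, fatal_weights) {
  if (is.null(fatal_weights)) {
    w <- c(need(draw, "share_stroke") * need(draw, "p_fatal_stroke"),
           need(draw, "share_chd") * need(draw, "p_fatal_chd_hf"),
           need(draw, "share_hf") * need(draw, "p_fatal_chd_hf"))
    return(sum(w / sum(w) * fatal_cost))
  }
  tot <- sum(fatal_weights)
  if (tot <= 0) return(0)
  sum(fatal_weights[c("fatal_stroke", "fatal_chd", "fatal_hf")] *
        fatal_cost) / tot
}

#' Run one strategy arm through the cohort model
#'
#' Starts the whole cohort in `no_cvd` at the (rounded) starting age, builds
#' the age-dependent trace over the horizon, and accrues discounted costs
#' and QALYs with half-cycle correction. The exercise programme fee is
#' charged once to the whole cohort at the cycle-1 discount factor.
#'
#' @param draw One parameter draw.
#' @param arm An `ec_arm`.
#' @param horizon Time horizon in years (`>= 1`).
#' @param life_table,utility_table Age-indexed tables covering
#'   `[start_age, start_age + horizon]`.
#' @param discount_rate Annual discount rate (default 0.05).
#' @param half_cycle Apply half-cycle correction (default `TRUE`).
#' @param fatal_event_cost Optional fatal-event cost override, see
#'   [build_rewards()].
#' @return An `ec_outcomes` with an added `trace` element.
#' @examples
#' reg <- parse_parameter_table(excea_example("parameters.csv"))
#' run_arm(point_estimates(reg), exercise_arm(), 5,
#'         generate_life_table(), generate_utility_table())
#' @export
run_arm <- function(draw, arm, horizon = 5, life_table, utility_table,
                    discount_rate = 0.05, half_cycle = TRUE,
                    fatal_event_cost = NULL) {
  draw <- as_draw_list(draw)
  start_age <- round(need(draw, "age_start"))
  risks <- annualize_baseline_risks(draw)
  hrs <- arm_hrs(arm, draw)

  mats <- lapply(0:(horizon - 1), function(t) {
    q_bg <- lookup_age(life_table, "qx", start_age + t)
    build_matrix_impl(draw, risks, hrs, q_bg)
  })
  trace <- build_trace(c(1, rep(0, 5)), function(t) mats[[t + 1]], horizon)
  flows <- lapply(seq_len(horizon), function(t) {
    trace[t, ] * mats[[t]]
  })
  rewards <- lapply(0:horizon, function(t) {
    fw <- if (t >= 1) attr(mats[[min(t, horizon)]], "events") else NULL
    build_rewards(draw, arm, start_age + t, cycle = t,
                  utility_table = utility_table,
                  fatal_event_cost = fatal_event_cost,
                  fatal_weights = fw)
  })
  out <- accrue_outcomes(trace, flows, rewards, rate = discount_rate,
                         half_cycle = half_cycle)
  out$trace <- trace
  out$arm <- arm$label
  out
}
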