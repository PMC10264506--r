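# Shared fixtures: the packaged registry, flat toy tables, and a
# per-individual microsimulation oracle for the accrual engine.

fixture_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- parse_parameter_table(excea_example("parameters.csv"))
    }
    cache
  }
})

# Registry with every samplable row degraded to a point mass at its mean.
fixed_registry <- function() {
  tab <- readr::read_csv(excea_example("parameters.csv"),
                         show_col_types = FALSE)
  tab$family[tab$family != "table"] <- "fixed"
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(tab, path)
  parse_parameter_table(path)
}

# Registry re-parsed after a column edit (recalibrates distributions).
edited_registry <- function(edit) {
  tab <- readr::read_csv(excea_example("parameters.csv"),
                         show_col_types = FALSE)
  tab <- edit(tab)
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(tab, path)
  parse_parameter_table(path)
}

flat_life_table <- function(q = 0.02, max_age = 110) {
  structure(tibble::tibble(age = 0:max_age,
                           qx = c(rep(q, max_age), 1)),
            class = c("ec_life_table", class(tibble::tibble())))
}

zero_life_table <- function() flat_life_table(q = 0)

flat_utility_table <- function(u = 1, max_age = 110) {
  structure(tibble::tibble(age = 0:max_age, utility = rep(u, max_age + 1)),
            class = c("ec_utility_table", class(tibble::tibble())))
}

# A parameter draw with every risk, cost and disutility switched off; pass
# overrides to turn individual pieces back on.
null_draw <- function(...) {
  base <- list(
    age_start = 64, p_cvd_14yr = 0, p_recurrence_14yr = 0,
    share_stroke = 0.35, share_chd = 0.31, share_hf = 0.34,
    p_fatal_stroke = 0, p_fatal_chd_hf = 0,
    s5_post_chd = 1, s5_post_stroke = 1, s5_post_hf = 1,
    s5_post_recurrence = 1,
    hr_cvd_exercise = 1, hr_recurrence_exercise = 1,
    u_post_stroke = 1, u_post_chd = 1, u_post_hf = 1,
    du_recurrence = 0, du_stroke = 0, du_chd = 0, du_hf = 0,
    c_exercise = 0, c_surveillance = 0,
    c_stroke_acute = 0, c_chd_acute = 0, c_hf_acute = 0,
    c_post_stroke_fu = 0, c_post_chd_fu = 0, c_post_hf_fu = 0,
    c_recurrence_treatment = 0, c_recurrence_fu = 0
  )
  modifyList(base, list(...))
}

# Brute-force per-individual simulation of a cohort model: same reward and
# discounting conventions as accrue_outcomes (trapezoid half-cycle on state
# rewards, one-time rewards on transitions at the arrival cycle's factor).
microsim_oracle <- function(n_ind, M, horizon, state_cost, state_utility,
                            trans_cost, trans_disutility, rate,
                            half_cycle = TRUE, init_state = 1L) {
  n_states <- nrow(M)
  cum <- t(apply(M, 1, cumsum))
  states <- matrix(init_state, n_ind, horizon + 1)
  for (t in seq_len(horizon)) {
    u <- runif(n_ind)
    prev <- states[, t]
    nxt <- integer(n_ind)
    for (s in seq_len(n_states)) {
      sel <- prev == s
      if (any(sel)) {
        nxt[sel] <- findInterval(u[sel], cum[s, ], left.open = TRUE) + 1L
      }
    }
    states[, t + 1] <- nxt
  }
  w <- rep(1, horizon + 1)
  if (half_cycle) w[c(1, horizon + 1)] <- 0.5
  df <- (1 + rate)^-(0:horizon)
  cost <- qaly <- numeric(n_ind)
  for (t in 0:horizon) {
    s <- states[, t + 1]
    cost <- cost + w[t + 1] * df[t + 1] * state_cost[s]
    qaly <- qaly + w[t + 1] * df[t + 1] * state_utility[s]
    if (t >= 1) {
      idx <- cbind(states[, t], s)
      cost <- cost + df[t + 1] * trans_cost[idx]
      qaly <- qaly - df[t + 1] * trans_disutility[idx]
    }
  }
  list(cost = cost, qaly = qaly)
}
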