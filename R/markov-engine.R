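#' One-time-step update of a cohort occupancy vector
#'
#' @param occupancy Numeric vector summing to 1 (fractions of the cohort in
#'   each state).
#' @param M Row-stochastic transition matrix over the same states.
#' @return `occupancy %*% M`, a vector with mass conserved.
#' @export
markov_step <- function(occupancy, M) {
  check_stochastic(M)
  if (abs(sum(occupancy) - 1) > 1e-9 || any(occupancy < -1e-12)) {
    abort("`occupancy` must be a non-negative vector summing to 1.",
          class = "excea_validation_error")
  }
  drop(occupancy %*% M)
}

check_stochastic <- function(M, tol = 1e-9) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    abort("transition matrix must be square.", class = "excea_validation_error")
  }
  if (any(M < -tol) || any(M > 1 + tol)) {
    abort("transition probabilities must lie in [0, 1].",
          class = "excea_validation_error")
  }
  bad <- which(abs(rowSums(M) - 1) > tol)
  if (length(bad) > 0) {
    abort(sprintf("transition matrix row(s) %s do not sum to 1.",
                  paste(bad, collapse = ", ")),
          class = "excea_validation_error")
  }
  invisible(M)
}

#' Compute a cohort trace over a fixed horizon
#'
#' Row 0 of the trace is the initial distribution; row `t + 1` is row `t`
#' propagated through the cycle-`t` transition matrix, so a model with
#' age-dependent transitions supplies a `matrix_fn` closing over the age at
#' each cycle.
#'
#' @param initial Initial occupancy vector (sums to 1).
#' @param matrix_fn Either a single transition matrix (time-homogeneous) or
#'   a function `function(cycle)` returning the matrix governing the
#'   transition from cycle `cycle` to `cycle + 1` (cycles numbered from 0).
#' @param horizon Number of one-year cycles (`>= 1`).
#' @return A `(horizon + 1) x n_states` matrix of occupancy fractions with
#'   class `ec_trace`; row names are cycle indices.
#' @export
build_trace <- function(initial, matrix_fn, horizon) {
  if (horizon < 1) abort("`horizon` must be at least 1.",
                         class = "excea_domain_error")
  fn <- if (is.function(matrix_fn)) matrix_fn else function(t) matrix_fn
  n <- length(initial)
  tr <- matrix(NA_real_, nrow = horizon + 1, ncol = n)
  tr[1, ] <- initial
  for (t in seq_len(horizon)) {
    M <- withCallingHandlers(
      fn(t - 1L),
      error = function(e) abort(sprintf("matrix_fn failed at cycle %d", t - 1L),
                                parent = e)
    )
    tr[t + 1, ] <- markov_step(tr[t, ], M)
  }
  dimnames(tr) <- list(cycle = 0:horizon,
                       state = colnames(if (is.function(matrix_fn)) fn(0) else matrix_fn))
  structure(tr, class = c("ec_trace", "matrix", "array"))
}

#' @export
tidy.ec_trace <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(unclass(x), responseName = "occupancy",
                                        stringsAsFactors = FALSE)) |>
    dplyr::mutate(cycle = as.integer(.data$cycle))
}

#' Discount factor for an annual rate at a given cycle
#'
#' Cycle-end convention: outcomes accrued in cycle `t` are discounted by
#' `(1 + rate)^-t`, with cycle 0 undiscounted.
#'
#' @param rate Annual discount rate (`>= 0`, e.g. 0.05).
#' @param cycle Cycle index (`>= 0`), may be a vector.
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(rate, cycle) {
  if (rate < 0) abort("`rate` must be non-negative.", class = "excea_domain_error")
  if (any(cycle < 0)) abort("`cycle` must be non-negative.",
                            class = "excea_domain_error")
  (1 + rate)^(-cycle)
}

#' Per-cycle reward structure
#'
#' Bundles everything that can be accrued in one model cycle: per-state
#' running costs and utilities, one-time rewards attached to transitions
#' (entering flows), and an optional whole-cohort one-time cost (used for
#' the intervention fee in its first cycle).
#'
#' @param state_cost,state_utility Numeric vectors, one entry per state
#'   (AUD per cycle, QALY weight per cycle). Utilities must lie in `[0, 1]`.
#' @param trans_cost,trans_disutility Square matrices over the states; entry
#'   `(i, j)` is the one-time cost/disutility charged per unit of flow moving
#'   `i -> j` during the cycle. Default 0.
#' @param one_time_cost Scalar cost charged once to the whole cohort at this
#'   cycle's discount factor (never half-weighted).
#' @return A list of class `ec_rewards`.
#' @export
cycle_rewards <- function(state_cost, state_utility,
                          trans_cost = NULL, trans_disutility = NULL,
                          one_time_cost = 0) {
  n <- length(state_cost)
  if (length(state_utility) != n) {
    abort("state cost and utility vectors differ in length.",
          class = "excea_validation_error")
  }
  if (any(state_utility < 0 | state_utility > 1)) {
    abort("state utilities must lie in [0, 1].",
          class = "excea_validation_error")
  }
  zero <- matrix(0, n, n)
  trans_cost <- trans_cost %||% zero
  trans_disutility <- trans_disutility %||% zero
  if (!all(dim(trans_cost) == n) || !all(dim(trans_disutility) == n)) {
    abort("transition reward matrices must be n_states x n_states.",
          class = "excea_validation_error")
  }
  structure(list(state_cost = state_cost, state_utility = state_utility,
                 trans_cost = trans_cost, trans_disutility = trans_disutility,
                 one_time_cost = one_time_cost),
            class = "ec_rewards")
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' State rewards are evaluated at every cycle point `t = 0..H` as
#' `occupancy_t . reward_t`, discounted by [discount_factor()] at `t`; with
#' half-cycle correction on, the first and final cycle points receive weight
#' 1/2 (the trapezoid rule). One-time transition rewards are applied to the
#' flows moving between states during cycle `t -> t + 1` and discounted at
#' `t + 1`; they are never half-weighted because they are instantaneous
#' events, not running accruals. A `one_time_cost` in the rewards for cycle
#' point `t` is charged to the whole cohort at `t`'s discount factor.
#'
#' @param trace An `ec_trace` (or plain matrix) with `H + 1` rows.
#' @param flows List of `H` flow matrices; element `t` decomposes the move
#'   from trace row `t` to row `t + 1` (`flows[[t]][i, j]` = cohort fraction
#'   moving `i -> j`). May be `NULL` when no transition rewards are used.
#' @param rewards A single [cycle_rewards()] object (applied at every cycle)
#'   or a list of `H + 1` of them, element `t + 1` governing cycle point `t`
#'   (its transition rewards apply to `flows[[t]]`).
#' @param rate Annual discount rate.
#' @param half_cycle Apply half-cycle correction to state rewards
#'   (default `TRUE`).
#' @return An object of class `ec_outcomes`: list with `cost`, `qaly`
#'   totals and a `by_cycle` tibble breakdown.
#' @export
accrue_outcomes <- function(trace, flows = NULL, rewards, rate = 0.05,
                            half_cycle = TRUE) {
  H <- nrow(trace) - 1L
  n <- ncol(trace)
  if (inherits(rewards, "ec_rewards")) {
    rewards <- rep(list(rewards), H + 1)
  }
  if (length(rewards) != H + 1) {
    abort(sprintf("need %d reward sets for %d cycles, got %d.",
                  H + 1, H, length(rewards)),
          class = "excea_validation_error")
  }
  if (!is.null(flows) && length(flows) != H) {
    abort("`flows` must have one matrix per cycle.",
          class = "excea_validation_error")
  }
  w <- rep(1, H + 1)
  if (half_cycle) w[c(1, H + 1)] <- 0.5
  df <- discount_factor(rate, 0:H)

  cost <- qaly <- numeric(H + 1)
  for (t in 0:H) {
    rw <- rewards[[t + 1]]
    if (length(rw$state_cost) != n) {
      abort("reward dimension does not match the trace.",
            class = "excea_validation_error")
    }
    occ <- trace[t + 1, ]
    cost[t + 1] <- w[t + 1] * df[t + 1] * sum(occ * rw$state_cost) +
      df[t + 1] * rw$one_time_cost
    qaly[t + 1] <- w[t + 1] * df[t + 1] * sum(occ * rw$state_utility)
    if (t >= 1 && !is.null(flows)) {
      fl <- flows[[t]]
      cost[t + 1] <- cost[t + 1] + df[t + 1] * sum(fl * rw$trans_cost)
      qaly[t + 1] <- qaly[t + 1] - df[t + 1] * sum(fl * rw$trans_disutility)
    }
  }
  structure(list(
    cost = sum(cost), qaly = sum(qaly),
    by_cycle = tibble::tibble(cycle = 0:H, cost = cost, qaly = qaly)
  ), class = "ec_outcomes")
}

#' @export
print.ec_outcomes <- function(x, ...) {
  cat(sprintf("<ec_outcomes> discounted cost $%.2f, QALYs %.4f over %d cycles\n",
              x$cost, x$qaly, nrow(x$by_cycle) - 1))
  invisible(x)
}

#' @export
tidy.ec_outcomes <- function(x, ...) x$by_cycle

#' @export
glance.ec_outcomes <- function(x, ...) {
  tibble::tibble(cost = x$cost, qaly = x$qaly)
}
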