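#' Convert a cumulative probability to a constant event rate
#'
#' Inverts the exponential (constant-hazard) relationship between a
#' cumulative event probability observed over `t` years and the underlying
#' annualised rate: `r = -log(1 - p) / t`.
#'
#' @param p Cumulative probability of the event over `t` years, in `[0, 1)`.
#' @param t Observation period in years (`> 0`).
#' @return Event rate per person-year (non-negative scalar or vector).
#' @examples
#' prob_to_rate(0.158, 14)
#' @seealso [rate_to_prob()], [apply_hazard_ratio()]
#' @export
prob_to_rate <- function(p, t = 1) {
  if (any(t <= 0)) abort("`t` must be positive.", class = "excea_domain_error")
  if (any(p < 0 | p > 1)) {
    abort("`p` must lie in [0, 1).", class = "excea_domain_error")
  }
  if (any(p == 1)) {
    abort("`p` = 1 implies an infinite rate.", class = "excea_domain_error")
  }
  -log1p(-p) / t
}

#' Convert a constant event rate to a cumulative probability
#'
#' @param r Event rate per person-year (`>= 0`).
#' @param t Period in years (`> 0`).
#' @return Probability `1 - exp(-r * t)` in `[0, 1]`.
#' @examples
#' rate_to_prob(prob_to_rate(0.158, 14), 1)
#' @export
rate_to_prob <- function(r, t = 1) {
  if (any(t <= 0)) abort("`t` must be positive.", class = "excea_domain_error")
  if (any(r < 0)) abort("`r` must be non-negative.", class = "excea_domain_error")
  -expm1(-r * t)
}

#' Apply a hazard ratio to an annual transition probability
#'
#' Multiplies the underlying constant hazard by `hr` and transforms back to
#' the probability scale: `1 - (1 - p)^hr`. With `hr < 1` the probability is
#' strictly reduced; `hr = 1` is the identity.
#'
#' @param p Annual probability in `[0, 1)`.
#' @param hr Hazard ratio (`> 0`).
#' @return Adjusted annual probability.
#' @examples
#' apply_hazard_ratio(0.0171, 0.77)
#' @export
apply_hazard_ratio <- function(p, hr) {
  if (any(hr <= 0)) abort("`hr` must be positive.", class = "excea_domain_error")
  if (any(p < 0 | p >= 1)) {
    abort("`p` must lie in [0, 1).", class = "excea_domain_error")
  }
  -expm1(hr * log1p(-p))
}

#' Convert a multi-year survival fraction to an annual death probability
#'
#' Under a constant hazard, a fraction `S` surviving `horizon` years implies
#' an annual death probability `1 - S^(1/horizon)`.
#'
#' @param S Survival fraction over the period, in `(0, 1]`.
#' @param horizon Length of the period in years (`> 0`).
#' @return Annual probability of death.
#' @examples
#' survival_to_annual_death_prob(0.859, 5) # five-year survival after CHD
#' @export
survival_to_annual_death_prob <- function(S, horizon) {
  if (any(horizon <= 0)) abort("`horizon` must be positive.", class = "excea_domain_error")
  if (any(S > 1) || any(S < 0)) {
    abort("`S` must lie in (0, 1].", class = "excea_domain_error")
  }
  if (any(S == 0)) {
    warn("`S` = 0: the whole cohort dies within one cycle.")
    return(ifelse(S == 0, 1, -expm1(log(S) / horizon)))
  }
  -expm1(log(S) / horizon)
}

#' Combine two competing annual death probabilities
#'
#' Disease-specific and background mortality are treated as independent
#' competing risks and combined multiplicatively on the survival scale:
#' `1 - (1 - p_disease) * (1 - p_background)` (additive on the rate scale).
#'
#' @param p_disease,p_background Annual probabilities in `[0, 1)`.
#' @return Combined annual death probability, always `>= max(inputs)`.
#' @export
combine_mortality <- function(p_disease, p_background) {
  if (any(p_disease < 0 | p_disease >= 1) || any(p_background < 0 | p_background >= 1)) {
    abort("probabilities must lie in [0, 1).", class = "excea_domain_error")
  }
  1 - (1 - p_disease) * (1 - p_background)
}
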