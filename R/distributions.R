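z975 <- function() qnorm(0.975)

#' Calibrate a samplable distribution from a mean and 95% interval
#'
#' Turns one registry row (distribution family, mean, 95% CI) into a fully
#' parameterised distribution. The calibration keeps the analytic mean equal
#' to the stated mean and, where the family has a remaining free parameter,
#' chooses it by least squares on the 2.5% and 97.5% quantiles against the
#' stated interval:
#'
#' * `normal` — `sd = (ci_high - ci_low) / (2 * 1.96)` (closed form);
#' * `lognormal` — `sdlog = (log(ci_high) - log(ci_low)) / (2 * 1.96)`,
#'   `meanlog = log(mean) - sdlog^2 / 2` so the analytic mean is exact;
#' * `beta` — `shape1 = mean * nu`, `shape2 = (1 - mean) * nu`, with the
#'   precision `nu` found by numeric search;
#' * `gamma` — `shape = k`, `rate = k / mean`, with `k` found by numeric
#'   search;
#' * `dirichlet` — concentration `alpha_i = mean_i * n_eff` (joint over the
#'   component means, which must sum to 1);
#' * `fixed` / `table` — a degenerate point mass (tables are resolved against
#'   their age-indexed lookup elsewhere).
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"normal"`,
#'   `"dirichlet"`, `"fixed"`, `"table"`.
#' @param mean Stated mean (for `dirichlet`, the vector of component means).
#' @param ci_low,ci_high Stated 95% interval bounds; required for the four
#'   CI-calibrated families, ignored otherwise.
#' @param n_eff Dirichlet effective sample size (default 100).
#' @return An object of class `ec_dist` with elements `family`, `mean` and
#'   the family's hyperparameters.
#' @examples
#' calibrate_distribution("normal", 64.1, 46.9, 80.7)$sd
#' calibrate_distribution("lognormal", 0.77, 0.67, 0.88)$sdlog
#' @export
calibrate_distribution <- function(family, mean, ci_low = NA_real_,
                                   ci_high = NA_real_, n_eff = 100) {
  family <- match.arg(family,
    c("beta", "gamma", "lognormal", "normal", "dirichlet", "fixed", "table"))
  needs_ci <- family %in% c("beta", "gamma", "lognormal", "normal")
  if (needs_ci && (is.na(ci_low) || is.na(ci_high))) {
    abort(sprintf("family '%s' requires both CI bounds.", family),
          class = "excea_calibration_error")
  }
  d <- switch(family,
    normal = list(sd = (ci_high - ci_low) / (2 * z975())),
    lognormal = {
      if (mean <= 0 || ci_low <= 0) {
        abort("lognormal requires positive mean and bounds.",
              class = "excea_calibration_error")
      }
      sdlog <- (log(ci_high) - log(ci_low)) / (2 * z975())
      list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
    },
    beta = {
      if (mean <= 0 || mean >= 1) {
        abort("beta mean must lie strictly inside (0, 1).",
              class = "excea_calibration_error")
      }
      nu <- exp(optimize(function(lnu) {
        a <- mean * exp(lnu); b <- (1 - mean) * exp(lnu)
        (stats::qbeta(0.025, a, b) - ci_low)^2 +
          (stats::qbeta(0.975, a, b) - ci_high)^2
      }, c(log(1e-2), log(1e9)), tol = 1e-10)$minimum)
      list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
    },
    gamma = {
      if (mean <= 0) {
        abort("gamma mean must be positive.", class = "excea_calibration_error")
      }
      k <- exp(optimize(function(lk) {
        kk <- exp(lk); r <- kk / mean
        (stats::qgamma(0.025, kk, rate = r) - ci_low)^2 +
          (stats::qgamma(0.975, kk, rate = r) - ci_high)^2
      }, c(log(1e-3), log(1e9)), tol = 1e-10)$minimum)
      list(shape = k, rate = k / mean)
    },
    dirichlet = {
      if (abs(sum(mean) - 1) > 1e-3) {
        abort("dirichlet component means must sum to 1.",
              class = "excea_calibration_error")
      }
      list(alpha = mean * n_eff)
    },
    fixed = list(),
    table = list()
  )
  structure(c(list(family = family, mean = mean,
                   ci_low = ci_low, ci_high = ci_high), d),
            class = "ec_dist")
}

#' @export
print.ec_dist <- function(x, ...) {
  pars <- setdiff(names(x), c("family", "mean", "ci_low", "ci_high"))
  cat(sprintf("<ec_dist %s> mean %.4g", x$family, x$mean[1]))
  for (p in pars) cat(sprintf(", %s = %s", p,
                              paste(signif(x[[p]], 5), collapse = "/")))
  cat("\n")
  invisible(x)
}

#' Analytic mean of a calibrated distribution
#' @param d An `ec_dist`.
#' @return The distribution's analytic mean (vector for dirichlet).
#' @export
dist_mean <- function(d) {
  switch(d$family,
    normal = d$mean,
    lognormal = exp(d$meanlog + d$sdlog^2 / 2),
    beta = d$shape1 / (d$shape1 + d$shape2),
    gamma = d$shape / d$rate,
    dirichlet = d$alpha / sum(d$alpha),
    d$mean
  )
}

#' Analytic quantiles of a calibrated distribution
#' @param d An `ec_dist`.
#' @param p Probabilities.
#' @return Quantiles (NA for point masses and dirichlet).
#' @export
dist_quantile <- function(d, p = c(0.025, 0.975)) {
  switch(d$family,
    normal = qnorm(p, d$mean, d$sd),
    lognormal = stats::qlnorm(p, d$meanlog, d$sdlog),
    beta = stats::qbeta(p, d$shape1, d$shape2),
    gamma = stats::qgamma(p, d$shape, rate = d$rate),
    rep(NA_real_, length(p))
  )
}

#' Draw random variates from a calibrated distribution
#'
#' @param d An `ec_dist`.
#' @param n Number of draws.
#' @return For scalar families a numeric vector of length `n`; for dirichlet
#'   an `n` x `k` matrix whose rows sum to 1.
#' @export
dist_sample <- function(d, n = 1) {
  switch(d$family,
    normal = rnorm(n, d$mean, d$sd),
    lognormal = rlnorm(n, d$meanlog, d$sdlog),
    beta = rbeta(n, d$shape1, d$shape2),
    gamma = rgamma(n, d$shape, rate = d$rate),
    dirichlet = {
      k <- length(d$alpha)
      g <- matrix(rgamma(n * k, shape = rep(d$alpha, each = n)), nrow = n)
      g / rowSums(g)
    },
    fixed = rep(d$mean, n),
    table = rep(NA_real_, n)
  )
}

#' @export
tidy.ec_dist <- function(x, ...) {
  pars <- setdiff(names(x), c("family", "mean", "ci_low", "ci_high"))
  tibble::tibble(
    family = x$family,
    hyperparameter = unlist(lapply(pars, function(p) {
      if (length(x[[p]]) > 1) paste0(p, seq_along(x[[p]])) else p
    })),
    value = unlist(x[pars], use.names = FALSE)
  )
}
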