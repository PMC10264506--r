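#' @export
print.ec_ce_result <- function(x, ...) {
  cat(sprintf("<ec_ce_result: %s>\n", x$kind))
  cat(sprintf("  exercise      $%8.0f  %.4f QALYs\n",
              x$arms$cost[1], x$arms$qaly[1]))
  cat(sprintf("  standard care $%8.0f  %.4f QALYs\n",
              x$arms$cost[2], x$arms$qaly[2]))
  cat(sprintf("  dCost $%.0f, dQALY %.4f, status %s\n",
              x$delta_cost, x$delta_qaly, x$status))
  icer_txt <- if (is.na(x$icer)) "undefined" else sprintf("$%.0f/QALY", x$icer)
  cat(sprintf("  ICER %s, iNMB $%.0f at WTP $%s\n", icer_txt, x$inmb,
              format(x$wtp, big.mark = ",")))
  invisible(x)
}

#' Tidy a cost-effectiveness result
#'
#' @param x An `ec_ce_result`.
#' @param ... Unused.
#' @return One row per arm: `arm`, `cost`, `qaly`.
#' @export
tidy.ec_ce_result <- function(x, ...) x$arms

#' One-row summary of a cost-effectiveness result
#'
#' @param x An `ec_ce_result`.
#' @param ... Unused.
#' @return A tibble with `delta_cost`, `delta_qaly`, `icer`, `inmb`, `wtp`,
#'   `status`.
#' @export
glance.ec_ce_result <- function(x, ...) {
  tibble::tibble(delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
                 icer = x$icer, inmb = x$inmb, wtp = x$wtp,
                 status = x$status, kind = x$kind)
}

#' @export
print.ec_psa <- function(x, ...) {
  cat(sprintf("<ec_psa> %d iterations (seed %s)\n", x$n_iter,
              x$seed %||% "unset"))
  print(x$summary)
  invisible(x)
}

#' Per-iteration PSA results
#'
#' @param x An `ec_psa`.
#' @param ... Unused.
#' @return The per-iteration tibble (costs, QALYs, increments, iNMB).
#' @export
tidy.ec_psa <- function(x, ...) x$iterations

#' PSA summary with percentile intervals
#'
#' @param x An `ec_psa`.
#' @param ... Unused.
#' @return A one-row tibble: mean per-arm costs and QALYs, mean increments,
#'   ratio-of-means ICER, iNMB, and 2.5/97.5 percentile bounds on the
#'   increments and iNMB.
#' @export
glance.ec_psa <- function(x, ...) {
  q <- psa_quantiles(x)
  pick <- function(v, which) q[[which]][q$quantity == v]
  s <- x$summary
  tibble::tibble(
    n_iter = x$n_iter,
    cost_exercise = s$arms$cost[1], qaly_exercise = s$arms$qaly[1],
    cost_standard_care = s$arms$cost[2], qaly_standard_care = s$arms$qaly[2],
    delta_cost = s$delta_cost, delta_cost_lo = pick("delta_cost", "lo"),
    delta_cost_hi = pick("delta_cost", "hi"),
    delta_qaly = s$delta_qaly, delta_qaly_lo = pick("delta_qaly", "lo"),
    delta_qaly_hi = pick("delta_qaly", "hi"),
    icer = s$icer,
    icer_lo = pick("icer_pairwise", "lo"), icer_hi = pick("icer_pairwise", "hi"),
    inmb = s$inmb, inmb_lo = pick("inmb", "lo"), inmb_hi = pick("inmb", "hi"),
    wtp = s$wtp
  )
}
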