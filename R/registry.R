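registry_cols <- c("name", "family", "mean", "ci_low", "ci_high",
                   "group", "units", "source")
known_families <- c("beta", "gamma", "lognormal", "normal",
                    "dirichlet", "table", "fixed")

#' Path to a file shipped with the package
#'
#' @param file File name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return Full path to the packaged file.
#' @examples
#' excea_example("parameters.csv")
#' @export
excea_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "excea")))
  }
  path <- system.file("extdata", file, package = "excea")
  if (!nzchar(path)) abort(sprintf("no packaged file '%s'.", file))
  path
}

#' Load and calibrate the model parameter registry
#'
#' Reads the tabulated model parameters (transition probabilities, health
#' utilities and costs, each with a distribution family, mean and 95% CI),
#' validates them, and calibrates every row into a samplable distribution
#' via [calibrate_distribution()]. Rows of family `"table"` are age-indexed
#' lookups (background mortality, baseline utility) supplied separately as
#' life/utility tables; they carry no mean and are never sampled.
#'
#' Dirichlet rows are tied together by their `group` label and calibrated
#' jointly; their means must sum to 1 (within 0.001).
#'
#' @param path Path to a parameter table: CSV with header
#'   `name,family,mean,ci_low,ci_high,group,units,source`, or a JSON array of
#'   records with the same fields. The packaged base-case table is at
#'   `excea_example("parameters.csv")`.
#' @param n_eff Dirichlet effective sample size passed to the calibration.
#' @return A tibble of class `ec_registry`, one row per parameter, with a
#'   `dist` list-column of calibrated `ec_dist` objects.
#' @examples
#' reg <- parse_parameter_table(excea_example("parameters.csv"))
#' dplyr::count(reg, family)
#' @export
parse_parameter_table <- function(path, n_eff = 100) {
  if (!file.exists(path)) abort(sprintf("file '%s' not found.", path))
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    suppressWarnings(readr::read_csv(path, col_types = readr::cols(
      name = "c", family = "c", mean = "d", ci_low = "d", ci_high = "d",
      group = "c", units = "c", source = "c"), progress = FALSE))
  }
  missing <- setdiff(registry_cols, names(tab))
  if (nrow(tab) == 0 || length(missing) > 0) {
    abort(paste0("parameter table schema invalid",
                 if (length(missing)) paste0(": missing column(s) ",
                                             paste(missing, collapse = ", "))
                 else ": no rows"),
          class = "excea_schema_error")
  }
  tab <- tab[registry_cols]
  validate_registry(tab)
  as_ec_registry(tab, n_eff = n_eff)
}

validate_registry <- function(tab) {
  bad_row <- function(i, msg) {
    abort(sprintf("parameter '%s': %s", tab$name[i], msg),
          class = "excea_validation_error")
  }
  if (anyDuplicated(tab$name)) {
    abort(sprintf("duplicate parameter name(s): %s",
                  paste(unique(tab$name[duplicated(tab$name)]), collapse = ", ")),
          class = "excea_validation_error")
  }
  for (i in seq_len(nrow(tab))) {
    fam <- tab$family[i]; m <- tab$mean[i]
    lo <- tab$ci_low[i]; hi <- tab$ci_high[i]; un <- tab$units[i] %||% ""
    if (!fam %in% known_families) bad_row(i, sprintf("unknown family '%s'", fam))
    if (fam == "table") next
    if (is.na(m)) bad_row(i, "mean is required")
    if (!is.na(lo) && !is.na(hi)) {
      if (lo > hi) bad_row(i, "ci_low exceeds ci_high")
      if (lo > m || m > hi) bad_row(i, "mean falls outside the stated CI")
    }
    if (fam == "beta" && (m < 0 || m > 1)) {
      bad_row(i, "beta mean outside [0, 1]")
    }
    if (un %in% c("probability", "proportion", "utility") && (m < 0 || m > 1)) {
      bad_row(i, sprintf("%s outside [0, 1]", un))
    }
    if (un %in% c("AUD", "disutility") && m < 0) {
      bad_row(i, sprintf("negative %s", un))
    }
    if (un == "ratio" && m <= 0) bad_row(i, "hazard ratio must be positive")
  }
  for (g in unique(stats::na.omit(tab$group[tab$family == "dirichlet"]))) {
    s <- sum(tab$mean[which(tab$family == "dirichlet" & !is.na(tab$group) &
                              tab$group == g)])
    if (abs(s - 1) > 1e-3) {
      abort(sprintf("dirichlet group '%s' means sum to %.4f, not 1.", g, s),
            class = "excea_validation_error")
    }
  }
  invisible(tab)
}

as_ec_registry <- function(tab, n_eff = 100) {
  dists <- vector("list", nrow(tab))
  for (g in unique(stats::na.omit(tab$group[tab$family == "dirichlet"]))) {
    idx <- which(tab$family == "dirichlet" & !is.na(tab$group) & tab$group == g)
    joint <- calibrate_distribution("dirichlet", tab$mean[idx], n_eff = n_eff)
    for (k in seq_along(idx)) {
      d <- joint
      d$component <- k
      dists[[idx[k]]] <- d
    }
  }
  for (i in seq_len(nrow(tab))) {
    if (!is.null(dists[[i]])) next
    dists[[i]] <- calibrate_distribution(tab$family[i], tab$mean[i],
                                         tab$ci_low[i], tab$ci_high[i])
  }
  tab$dist <- dists
  class(tab) <- c("ec_registry", class(tibble::as_tibble(tab)))
  tab
}

#' Write a registry back to its tabular form
#'
#' Serialises the eight declared columns (dropping the calibrated `dist`
#' list-column, which is recomputed on parse) so that a write/parse round
#' trip is lossless.
#'
#' @param registry An `ec_registry`.
#' @param path Output path; `.json` writes a JSON array, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(registry, path) {
  tab <- registry[registry_cols]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(tab, path, progress = FALSE)
  }
  invisible(path)
}

samplable <- function(registry) registry$family != "table"

#' Base-case (point-estimate) parameter vector
#'
#' @param registry An `ec_registry`.
#' @return A one-row tibble with one column per samplable parameter, holding
#'   its stated mean. Table-family rows are resolved against their external
#'   lookup tables and are omitted here.
#' @examples
#' reg <- parse_parameter_table(excea_example("parameters.csv"))
#' point_estimates(reg)$c_exercise
#' @export
point_estimates <- function(registry) {
  keep <- samplable(registry)
  tibble::as_tibble(as.list(setNames(registry$mean[keep], registry$name[keep])))
}

#' Draw parameter vectors for probabilistic sensitivity analysis
#'
#' Draws `n` independent realisations of every samplable parameter. Dirichlet
#' groups are drawn jointly so their components sum to 1 exactly. After
#' drawing, probabilities and utilities are clipped to `[0, 1]` and costs and
#' disutilities to `[0, Inf)` to guard against extreme tail draws.
#'
#' @param registry An `ec_registry`.
#' @param n Number of draws (rows).
#' @param seed Optional integer seed; the same seed yields identical draws
#'   and the caller's RNG state is left untouched.
#' @return A tibble with `n` rows, a `.draw` index column and one column per
#'   parameter.
#' @examples
#' reg <- parse_parameter_table(excea_example("parameters.csv"))
#' sample_parameters(reg, n = 3, seed = 42)
#' @export
sample_parameters <- function(registry, n = 1, seed = NULL) {
  draw_fn <- function() {
    out <- vector("list", nrow(registry))
    done <- logical(nrow(registry))
    for (g in unique(stats::na.omit(registry$group[registry$family == "dirichlet"]))) {
      idx <- which(registry$family == "dirichlet" & !is.na(registry$group) &
                     registry$group == g)
      joint <- dist_sample(registry$dist[[idx[1]]], n)
      for (k in seq_along(idx)) {
        out[[idx[k]]] <- joint[, k]
        done[idx[k]] <- TRUE
      }
    }
    for (i in seq_len(nrow(registry))) {
      if (done[i] || registry$family[i] == "table") next
      x <- dist_sample(registry$dist[[i]], n)
      un <- registry$units[i] %||% ""
      if (un %in% c("probability", "proportion", "utility")) {
        x <- pmin(pmax(x, 0), 1)
      } else if (un %in% c("AUD", "disutility")) {
        x <- pmax(x, 0)
      }
      out[[i]] <- x
    }
    keep <- !vapply(out, is.null, logical(1))
    tibble::as_tibble(setNames(out[keep], registry$name[keep]))
  }
  draws <- if (is.null(seed)) draw_fn() else withr::with_seed(seed, draw_fn())
  if (ncol(draws) == 0) draws <- tibble::tibble(.rows = n)
  dplyr::bind_cols(tibble::tibble(.draw = seq_len(n)), draws)
}

#' @export
print.ec_registry <- function(x, ...) {
  cat(sprintf("<ec_registry> %d parameters (%d samplable, %d table lookups)\n",
              nrow(x), sum(samplable(x)), sum(!samplable(x))))
  NextMethod()
}
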