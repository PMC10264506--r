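#' Generate a synthetic female period life table
#'
#' Produces an age-indexed table of annual death probabilities from a
#' Gompertz-Makeham hazard, `q_x = 1 - exp(-(a + b * c^x))`, as a documented
#' stand-in for a national female life table (the default parameters give a
#' period life expectancy at age 64 of about 23 years, typical of women in a
#' high-income country). A real life table in the same `age,qx` CSV schema
#' can be substituted anywhere one is accepted.
#'
#' @param makeham_a Age-independent (background) hazard component (`>= 0`).
#' @param gompertz_b Gompertz level parameter (`> 0`).
#' @param gompertz_c Gompertz rate of ageing (`> 1`).
#' @param max_age Closure age; `q` is forced to 1 there.
#' @return A tibble of class `ec_life_table` with columns `age` (0 to
#'   `max_age`) and `qx`.
#' @examples
#' lt <- generate_life_table()
#' life_expectancy(lt, 64)
#' @export
generate_life_table <- function(makeham_a = 2e-4, gompertz_b = 8e-6,
                                gompertz_c = 1.11, max_age = 110) {
  if (makeham_a < 0 || gompertz_b <= 0 || gompertz_c <= 1) {
    abort("require a >= 0, b > 0, c > 1.", class = "excea_domain_error")
  }
  age <- 0:max_age
  qx <- pmin(-expm1(-(makeham_a + gompertz_b * gompertz_c^age)), 1)
  if (any(qx[age < 90] >= 1)) {
    warn("hazard reaches q = 1 before age 90; check the parameters.")
  }
  qx[length(qx)] <- 1
  structure(tibble::tibble(age = age, qx = qx),
            class = c("ec_life_table", class(tibble::tibble())))
}

#' Period life expectancy implied by a life table
#'
#' Brute-force summation of the survival curve from `from_age` to the table's
#' closure age, counting each year lived at its start-of-year survivors
#' (mid-year refinement of half a year for the death cohort).
#'
#' @param life_table A tibble with columns `age`, `qx`.
#' @param from_age Age at which to evaluate remaining life expectancy.
#' @return Expected remaining years of life (scalar).
#' @export
life_expectancy <- function(life_table, from_age) {
  q <- life_table$qx[life_table$age >= from_age]
  surv <- cumprod(1 - q)
  lived <- (c(1, head(surv, -1)) + surv) / 2
  sum(lived)
}

#' Generate a synthetic age-specific baseline utility table
#'
#' Linear-decline stand-in for age-specific EQ-5D population norms:
#' `u(age) = clamp(u_ref - slope * (age - 60) / 10, 0, 1)`. The defaults
#' (0.81 at age 60, declining 0.03 per decade) approximate published female
#' utility norms at these ages; a real norms table in the same `age,utility`
#' CSV schema can be substituted.
#'
#' @param u_ref Utility at age 60, in `(0, 1]`.
#' @param slope Utility decline per decade of age (`>= 0`).
#' @param age_range Integer ages to tabulate.
#' @return A tibble of class `ec_utility_table` with columns `age`, `utility`.
#' @examples
#' generate_utility_table()[generate_utility_table()$age == 70, ]
#' @export
generate_utility_table <- function(u_ref = 0.81, slope = 0.03,
                                   age_range = 0:110) {
  if (u_ref <= 0 || u_ref > 1 || slope < 0) {
    abort("require u_ref in (0, 1] and slope >= 0.",
          class = "excea_domain_error")
  }
  u <- pmin(pmax(u_ref - slope * (age_range - 60) / 10, 0), 1)
  structure(tibble::tibble(age = age_range, utility = u),
            class = c("ec_utility_table", class(tibble::tibble())))
}

#' Read an age-indexed table from CSV
#'
#' @param path CSV with columns `age` and either `qx` (life table) or
#'   `utility` (utility table).
#' @return A tibble typed as `ec_life_table` or `ec_utility_table`.
#' @export
read_age_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "d"),
                         progress = FALSE)
  if (!"age" %in% names(tab) || !any(c("qx", "utility") %in% names(tab))) {
    abort("age table needs columns `age` and `qx` or `utility`.",
          class = "excea_schema_error")
  }
  cls <- if ("qx" %in% names(tab)) "ec_life_table" else "ec_utility_table"
  structure(tab, class = c(cls, class(tibble::tibble())))
}

lookup_age <- function(table, col, age) {
  i <- match(age, table$age)
  if (anyNA(i)) {
    abort(sprintf("age(s) %s outside the %s table range.",
                  paste(age[is.na(i)], collapse = ", "), col),
          class = "excea_range_error")
  }
  table[[col]][i]
}

#' Write the self-contained model input bundle
#'
#' Writes everything the pipeline needs to a directory: the packaged
#' parameter table (verbatim copy), a generated life table, a generated
#' baseline utility table, a default run configuration, and a manifest
#' recording the generation parameters and seed. Output is deterministic:
#' the same seed gives byte-identical files.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Integer seed recorded in the manifest (the generators are
#'   deterministic closed forms; the seed feeds downstream analyses).
#' @param life_args,utility_args Optional lists of arguments overriding the
#'   [generate_life_table()] / [generate_utility_table()] defaults.
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture_bundle <- function(outdir, seed = 1L,
                                 life_args = list(), utility_args = list()) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok) abort(sprintf("cannot create '%s'.", outdir))
  paths <- c(
    parameters = file.path(outdir, "parameters.csv"),
    life_table = file.path(outdir, "life_table.csv"),
    utility_table = file.path(outdir, "utility_table.csv"),
    config = file.path(outdir, "config.yaml"),
    manifest = file.path(outdir, "manifest.json")
  )
  file.copy(excea_example("parameters.csv"), paths[["parameters"]],
            overwrite = TRUE)
  lt <- do.call(generate_life_table, life_args)
  ut <- do.call(generate_utility_table, utility_args)
  readr::write_csv(lt, paths[["life_table"]], progress = FALSE)
  readr::write_csv(ut, paths[["utility_table"]], progress = FALSE)
  cfg <- run_config(params = paths[["parameters"]],
                    life_table = paths[["life_table"]],
                    utilities = paths[["utility_table"]],
                    seed = as.integer(seed), out = outdir)
  yaml::write_yaml(unclass(cfg), paths[["config"]])
  jsonlite::write_json(
    list(seed = as.integer(seed),
         life_table = modifyList(formals_defaults(generate_life_table),
                                 life_args),
         utility_table = modifyList(formals_defaults(generate_utility_table),
                                    utility_args)),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

formals_defaults <- function(fn) {
  fml <- formals(fn)
  fml <- fml[vapply(fml, function(x) is.numeric(x) || is.call(x), logical(1))]
  lapply(fml, function(x) eval(x, baseenv()))
}
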