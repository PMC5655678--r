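#' Analysis configuration
#'
#' Bundles everything [run_analysis()] needs: the datasets (as tibbles or CSV
#' paths), their analysis kinds, the storm-year exclusions, ln-transform
#' flags, and the reporting thresholds.
#'
#' @param datasets Named list; each element is either a tibble in the
#'   [read_series_csv()] dialect or a path to such a CSV.
#' @param kinds Named character vector mapping dataset names to
#'   `"overwinter"`, `"adult"` or `"egg"`. Defaults to matching names.
#' @param exclude_years Terminal years of storm-affected growth transitions to
#'   drop (default 2002 and 2004, the two documented mass-mortality storms).
#' @param conservative_years Superset of `exclude_years` used in the
#'   conservative rerun (default adds 2010 and 2016, storms without
#'   documented mass mortality).
#' @param conservative If `TRUE`, append a rerun with the conservative
#'   exclusion set to the report.
#' @param show_cut,plausible_cut,level Reporting thresholds: AICc-difference
#'   display cutoff, plausibility cutoff, and confidence level.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(datasets, kinds = NULL,
                            exclude_years = c(2002, 2004),
                            conservative_years = c(2002, 2004, 2010, 2016),
                            conservative = FALSE,
                            show_cut = 7, plausible_cut = 2, level = 0.95) {
  stopifnot(is.list(datasets), length(datasets) > 0,
            !is.null(names(datasets)), all(nzchar(names(datasets))))
  if (is.null(kinds)) {
    kinds <- stats::setNames(names(datasets), names(datasets))
  }
  kinds <- vapply(kinds, match.arg, character(1),
                  choices = c("overwinter", "adult", "egg"))
  if (!all(names(datasets) %in% names(kinds))) {
    stop("every dataset needs an analysis kind", call. = FALSE)
  }
  if (!all(exclude_years %in% conservative_years)) {
    stop("conservative exclusion set must contain the default set",
         call. = FALSE)
  }
  structure(list(datasets = datasets, kinds = kinds,
                 exclude_years = as.integer(exclude_years),
                 conservative_years = as.integer(conservative_years),
                 conservative = conservative,
                 show_cut = show_cut, plausible_cut = plausible_cut,
                 level = level),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' The YAML mirrors [analysis_config()]: a `datasets` mapping of name to CSV
#' path, an optional `kinds` mapping, and scalar keys `exclude_years`,
#' `conservative_years`, `conservative`, `show_cut`, `plausible_cut`,
#' `level`.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$datasets)) stop("config has no 'datasets' entry", call. = FALSE)
  args <- list(datasets = as.list(y$datasets))
  if (!is.null(y$kinds)) args$kinds <- unlist(y$kinds)
  for (key in c("exclude_years", "conservative_years", "conservative",
                "show_cut", "plausible_cut", "level")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  do.call(analysis_config, args)
}

#' Analyse one dataset for density dependence
#'
#' The single-dataset engine behind [run_analysis()]: builds growth rates with
#' storm-year exclusions, screens for delayed (lag-2) density dependence,
#' enumerates and fits the direct-dependence candidate set by maximum
#' likelihood, ranks it by AICc, and computes conditional model-averaged
#' coefficients and residual diagnostics for the best model.
#'
#' @param series Tibble of abundance records (`series_id`, `site`, `year`,
#'   `value`).
#' @param kind `"overwinter"` (single series, linear models) or `"adult"` /
#'   `"egg"` (multi-site, random site intercept, ln-transformed density).
#' @param exclude_years Terminal years to drop before fitting.
#' @param level Confidence level for averaged coefficients.
#' @return A list with elements `kind`, `n_obs`, `delayed` (screening
#'   `candidate_table` of lag-1-only vs lag-1+lag-2), `table` (the ranked
#'   `candidate_table`), `averaged` (`averaged_coefficients`), `diagnostics`
#'   (residual summary for the rank-1 model) and `dataset` (the prepared
#'   `growth_dataset`).
#' @export
analyze_dataset <- function(series, kind = c("overwinter", "adult", "egg"),
                            exclude_years = c(2002, 2004), level = 0.95) {
  kind <- match.arg(kind)
  ln_transform <- kind != "overwinter"

  obs2 <- compute_growth_rates(series, lag = 2) %>%
    exclude_transitions(exclude_years)
  obs <- dplyr::select(obs2, -"lag2")

  # Delayed-feedback screen: lag-1 vs lag-1 + lag-2 on the lag-2-complete rows
  delayed <- NULL
  ds2 <- prepare_predictors(obs2[!is.na(obs2$lag2), , drop = FALSE],
                            ln_transform = ln_transform)
  d_spec <- delayed_spec(kind)
  direct_only <- model_spec("L1", random = d_spec$random)
  delayed_fits <- list(fit_ml(build_design(direct_only, ds2)),
                       fit_ml(build_design(d_spec, ds2)))
  delayed <- rank_candidates(delayed_fits)

  # Main candidate set on the full observation set
  dataset <- prepare_predictors(obs, ln_transform = ln_transform)
  candidates <- enumerate_candidates(full_spec(kind))
  fits <- purrr::map(candidates, function(sp) fit_ml(build_design(sp, dataset)))
  table <- rank_candidates(fits)
  averaged <- model_average(table, level = level)
  best_fit <- attr(table, "fits", exact = TRUE)[[1]]
  diagnostics <- residual_diagnostics(best_fit)

  list(kind = kind, n_obs = attr(table, "n_obs", exact = TRUE),
       delayed = delayed, table = table, averaged = averaged,
       diagnostics = diagnostics, dataset = dataset)
}

#' Run the full multi-dataset density-dependence analysis
#'
#' Orchestrates [analyze_dataset()] over every dataset in the configuration,
#' optionally appending a conservative rerun with the wider storm-exclusion
#' set. A failure in one dataset is reported and does not stop the others.
#'
#' @param config An `analysis_config`.
#' @return An `analysis_report`: a named list of per-dataset results (each as
#'   returned by [analyze_dataset()], or an `error` element on failure), with
#'   the configuration stored in attribute `config` and conservative reruns
#'   under `conservative`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  load_one <- function(x) {
    if (is.character(x)) read_series_csv(x) else tibble::as_tibble(x)
  }
  run_one <- function(name, years) {
    tryCatch(
      analyze_dataset(load_one(config$datasets[[name]]),
                      kind = config$kinds[[name]],
                      exclude_years = years, level = config$level),
      error = function(e) {
        warning("dataset '", name, "' failed: ", conditionMessage(e),
                call. = FALSE)
        list(kind = config$kinds[[name]], error = conditionMessage(e))
      }
    )
  }
  results <- purrr::map(names(config$datasets), run_one,
                        years = config$exclude_years)
  names(results) <- names(config$datasets)
  conservative <- NULL
  if (isTRUE(config$conservative)) {
    conservative <- purrr::map(names(config$datasets), run_one,
                               years = config$conservative_years)
    names(conservative) <- names(config$datasets)
  }
  structure(list(results = results, conservative = conservative),
            config = config, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cfg <- attr(x, "config", exact = TRUE)
  for (name in names(x$results)) {
    res <- x$results[[name]]
    cat("==", name, sprintf("(%s)\n", res$kind))
    if (!is.null(res$error)) {
      cat("   failed:", res$error, "\n")
      next
    }
    cat(report_table(res$table, cfg$show_cut, cfg$plausible_cut), sep = "\n")
    cat("model-averaged coefficients (conditional):\n")
    print(as.data.frame(res$averaged), row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' Residual diagnostics for a fitted model
#'
#' Numeric summaries of the residual distribution: skewness, excess kurtosis,
#' and the Spearman rank correlation between absolute residuals and fitted
#' values (a heteroscedasticity indicator). Reported as numbers with no
#' pass/fail gate; degenerate cases (constant residuals) are reported as `NA`.
#'
#' @param fit A converged `dd_fit`.
#' @return A one-row tibble with `skewness`, `excess_kurtosis`,
#'   `abs_resid_fitted_cor` and `n`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "dd_fit"))
  r <- fit$residuals
  n <- length(r)
  s <- stats::sd(r)
  if (!is.finite(s) || s < 1e-12) {
    return(tibble::tibble(skewness = NA_real_, excess_kurtosis = NA_real_,
                          abs_resid_fitted_cor = NA_real_, n = n))
  }
  z <- (r - mean(r)) / s
  rho <- if (stats::sd(fit$fitted) < 1e-12) NA_real_ else
    suppressWarnings(stats::cor(abs(r), fit$fitted, method = "spearman"))
  tibble::tibble(skewness = mean(z^3),
                 excess_kurtosis = mean(z^4) - 3,
                 abs_resid_fitted_cor = rho,
                 n = n)
}

#' Write an analysis report to CSV and JSON files
#'
#' Emits, per dataset, the ranked candidate table and averaged coefficients as
#' CSV, and one JSON file with the full report (tables, delayed screen,
#' diagnostics) at full precision. Outputs are deterministic: identical
#' inputs and configuration give byte-identical files.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  as_plain <- function(tbl) as.data.frame(tbl)
  json <- list()
  for (name in names(report$results)) {
    res <- report$results[[name]]
    if (!is.null(res$error)) {
      json[[name]] <- list(kind = res$kind, error = res$error)
      next
    }
    p1 <- file.path(dir, paste0(name, "_candidates.csv"))
    p2 <- file.path(dir, paste0(name, "_averaged.csv"))
    readr::write_csv(as_plain(res$table), p1, progress = FALSE)
    readr::write_csv(as_plain(res$averaged), p2, progress = FALSE)
    paths <- c(paths, p1, p2)
    json[[name]] <- list(kind = res$kind, n_obs = res$n_obs,
                         delayed = as_plain(res$delayed),
                         candidates = as_plain(res$table),
                         averaged = as_plain(res$averaged),
                         diagnostics = as_plain(res$diagnostics))
  }
  pj <- file.path(dir, "report.json")
  jsonlite::write_json(json, pj, digits = NA, auto_unbox = TRUE)
  invisible(c(paths, pj))
}

#' The overwintering forest-area series shipped with the package
#'
#' Total forest area (hectares) occupied by overwintering monarch aggregations
#' in central Mexico, one value per overwintering season labelled by the
#' season's starting calendar year (1993 = the 1993/94 season), compiled from
#' public WWF-Mexico / Monarch Watch press reports. This is the standard
#' whole-population abundance proxy for the Eastern migratory population.
#'
#' @return A tibble in the [read_series_csv()] dialect (24 seasons,
#'   1993-2016).
#' @export
wwf_overwintering <- function() {
  read_series_csv(system.file("extdata", "wwf_overwintering.csv",
                              package = "densdep", mustWork = TRUE))
}
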