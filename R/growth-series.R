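#' Read annual abundance-index series from CSV
#'
#' Reads one or more abundance-index time series (e.g. hectares of forest
#' occupied by overwintering monarchs, adult density indices, or eggs per
#' host-plant stem) from a plain CSV file with columns `series_id`, `site`,
#' `year`, `value`.
#'
#' @param path Path to a CSV file with a header row and columns
#'   `series_id`, `site`, `year`, `value`.
#' @return A tibble with columns `series_id` (character), `site` (character),
#'   `year` (integer) and `value` (double), sorted by series and year.
#'   Each distinct `series_id` is one abundance series.
#' @details Values must be strictly positive (growth rates are log ratios) and
#'   a series may not contain two rows for the same year. Rows are validated
#'   and offending rows are identified in error messages.
#' @export
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' writeLines(c("series_id,site,year,value",
#'              "mx,mexico,1994,7.81",
#'              "mx,mexico,1995,12.61",
#'              "mx,mexico,1996,18.19"), csv)
#' read_series_csv(csv)
read_series_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("series_id", "site", "year", "value")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("input CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    series_id = as.character(raw$series_id),
    site = as.character(raw$site),
    year = raw$year,
    value = raw$value
  )
  validate_abundance_series(out)
  out %>%
    dplyr::mutate(year = as.integer(.data$year), value = as.double(.data$value)) %>%
    dplyr::arrange(.data$series_id, .data$year)
}

#' @keywords internal
validate_abundance_series <- function(series) {
  if (!is.numeric(series$year) || any(series$year != round(series$year))) {
    stop("column 'year' must contain integer calendar years", call. = FALSE)
  }
  if (!is.numeric(series$value)) {
    stop("column 'value' must be numeric", call. = FALSE)
  }
  bad <- which(!is.finite(series$value) | series$value <= 0)
  if (length(bad) > 0) {
    stop("abundance values must be positive and finite; offending row(s): ",
         paste(sprintf("%s/%d (value %s)", series$series_id[bad],
                       series$year[bad], format(series$value[bad])),
               collapse = ", "),
         call. = FALSE)
  }
  dup <- series %>%
    dplyr::count(.data$series_id, .data$year) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (series_id, year) pairs: ",
         paste(sprintf("%s/%d", dup$series_id, dup$year), collapse = ", "),
         call. = FALSE)
  }
  invisible(series)
}

#' Construct log growth-rate observations from abundance series
#'
#' For every consecutive pair of years (t-1, t) in each series, computes the
#' annual population growth rate R = ln(N_t / N_{t-1}) together with the raw
#' lagged abundance predictors. Transitions spanning a gap in years are not
#' emitted, and the lag-2 predictor is only recorded when the value two years
#' before the terminal year exists.
#'
#' @param series A tibble of abundance records as returned by
#'   [read_series_csv()] (columns `series_id`, `site`, `year`, `value`).
#' @param lag Maximum density lag to carry as a predictor, 1 or 2.
#' @return A tibble of growth observations with columns `series_id`, `site`,
#'   `terminal_year` (the year t of the transition t-1 -> t), `response`
#'   (R, dimensionless), `lag1` (raw N_{t-1}) and, when `lag = 2`, `lag2`
#'   (raw N_{t-2}, `NA` where unavailable).
#' @export
compute_growth_rates <- function(series, lag = 1) {
  stopifnot(lag %in% c(1L, 2L))
  if (!all(c("series_id", "site", "year", "value") %in% names(series))) {
    stop("'series' must have columns series_id, site, year, value", call. = FALSE)
  }
  validate_abundance_series(series)
  one_series <- function(df) {
    df <- dplyr::arrange(df, .data$year)
    if (nrow(df) < 2) {
      warning("series '", df$series_id[1],
              "' has fewer than 2 points; no growth rates computed",
              call. = FALSE)
      return(tibble::tibble())
    }
    yr <- df$year
    val <- df$value
    i <- which(diff(yr) == 1L) + 1L   # terminal index of gap-free transitions
    out <- tibble::tibble(
      series_id = df$series_id[i],
      site = df$site[i],
      terminal_year = yr[i],
      response = log(val[i] / val[i - 1L]),
      lag1 = val[i - 1L]
    )
    if (lag == 2L) {
      # value two calendar years before terminal year, if present
      idx2 <- match(out$terminal_year - 2L, yr)
      out$lag2 <- val[idx2]
    }
    out
  }
  series %>%
    dplyr::group_by(.data$series_id) %>%
    dplyr::group_split() %>%
    purrr::map(one_series) %>%
    purrr::list_rbind()
}

#' Drop growth observations for event-affected years
#'
#' Removes growth-rate observations whose terminal year is in `years_to_drop`,
#' e.g. transitions ending in a year whose abundance was depressed by a
#' catastrophic winter storm. Exclusion is keyed on the terminal year of the
#' transition; transitions that merely use an event-year abundance as a lagged
#' predictor are retained.
#'
#' @param observations A tibble of growth observations from
#'   [compute_growth_rates()].
#' @param years_to_drop Integer vector of terminal years to remove (a set;
#'   duplicates are ignored). May be empty.
#' @return The filtered tibble. The number of removed observations is reported
#'   via `message()`; years in `years_to_drop` matching no observation trigger
#'   a warning.
#' @export
exclude_transitions <- function(observations, years_to_drop) {
  years_to_drop <- unique(as.integer(years_to_drop))
  if (length(years_to_drop) == 0) {
    return(observations)
  }
  unmatched <- setdiff(years_to_drop, observations$terminal_year)
  if (length(unmatched) > 0) {
    warning("exclusion year(s) ", paste(unmatched, collapse = ", "),
            " match no growth observation", call. = FALSE)
  }
  keep <- !(observations$terminal_year %in% years_to_drop)
  message(sum(!keep), " growth observation(s) removed for terminal year(s) ",
          paste(years_to_drop, collapse = ", "))
  out <- observations[keep, , drop = FALSE]
  attr(out, "excluded_years") <- sort(years_to_drop)
  out
}

#' Prepare standardized model predictors from growth observations
#'
#' Optionally ln-transforms the lagged density predictors, then centres and
#' scales every predictor (including the time covariate, taken as the terminal
#' calendar year) to mean 0 and SD 1 over the retained observations.
#' Transformation metadata (ln flag, mean, SD) is stored so estimates can be
#' mapped back to the original scale.
#'
#' @param observations A tibble of growth observations (after any exclusions).
#' @param ln_transform If `TRUE`, ln-transform the lagged density predictors
#'   before standardization (used for adult-density and egg-density analyses
#'   to improve linearity).
#' @param standardize If `TRUE` (default), centre and scale predictors to
#'   mean 0, SD 1. Standardization uses the sample (n-1) SD.
#' @return A `growth_dataset`: a tibble with columns `series_id`, `site`,
#'   `terminal_year`, `response`, `lag1`, `lag2` (if present) and `time`, with
#'   attributes `predictor_meta` (a tibble of per-predictor ln flag, mean, SD)
#'   and `excluded_years`.
#' @export
prepare_predictors <- function(observations, ln_transform = FALSE,
                               standardize = TRUE) {
  obs <- tibble::as_tibble(observations)
  if (nrow(obs) < 3) {
    stop("need at least 3 growth observations to build an analysis dataset",
         call. = FALSE)
  }
  predictors <- intersect(c("lag1", "lag2"), names(obs))
  if (ln_transform) {
    for (p in predictors) {
      x <- obs[[p]]
      if (any(x[!is.na(x)] <= 0)) {
        stop("cannot ln-transform non-positive values in predictor '", p, "'",
             call. = FALSE)
      }
      obs[[p]] <- log(x)
    }
  }
  obs$time <- as.double(obs$terminal_year)
  meta <- purrr::map(c(predictors, "time"), function(p) {
    x <- obs[[p]]
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (standardize) {
      if (!is.finite(s) || s < 1e-12) {
        stop("predictor '", p, "' has zero variance; standardization undefined",
             call. = FALSE)
      }
      obs[[p]] <<- (x - m) / s
    }
    tibble::tibble(predictor = p,
                   ln_transformed = ln_transform && p %in% predictors,
                   mean = if (standardize) m else 0,
                   sd = if (standardize) s else 1)
  }) %>% purrr::list_rbind()
  structure(obs,
            predictor_meta = meta,
            excluded_years = attr(observations, "excluded_years", exact = TRUE),
            class = c("growth_dataset", class(tibble::tibble())))
}

#' Predictor standardization metadata of a growth dataset
#'
#' @param dataset A `growth_dataset` from [prepare_predictors()].
#' @return A tibble with columns `predictor`, `ln_transformed`, `mean`, `sd`.
#' @export
predictor_meta <- function(dataset) {
  attr(dataset, "predictor_meta", exact = TRUE)
}

#' Map standardized predictor values back to the original scale
#'
#' Inverts the centring/scaling (and, if recorded, the ln transform) applied by
#' [prepare_predictors()].
#'
#' @param x Numeric vector on the standardized scale.
#' @param dataset The `growth_dataset` whose metadata defines the transform.
#' @param predictor Name of the predictor (`"lag1"`, `"lag2"` or `"time"`).
#' @return Numeric vector on the original measurement scale.
#' @export
unstandardize <- function(x, dataset, predictor) {
  meta <- predictor_meta(dataset)
  row <- meta[meta$predictor == predictor, ]
  if (nrow(row) != 1) {
    stop("no standardization metadata for predictor '", predictor, "'",
         call. = FALSE)
  }
  out <- x * row$sd + row$mean
  if (row$ln_transformed) out <- exp(out)
  out
}
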