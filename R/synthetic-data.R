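#' Parameters of the stochastic density-dependence simulator
#'
#' Defines the data-generating twin of the analysis models: a discrete-time
#' stochastic population with Ricker or Gompertz density feedback, a linear
#' time trend in growth rate, lognormal process noise and (for multi-site
#' simulations) Gaussian site-level random intercepts.
#'
#' On the log scale the recursion is
#' `ln N_t = ln N_{t-1} + a + b * D_{t-1} + c * ttilde + storm_t + eps_t`,
#' where `D_{t-1}` is `N_{t-1}` (Ricker) or `ln N_{t-1}` (Gompertz),
#' `ttilde` is the standardized year index, and `eps_t ~ N(0, sigma_e^2)`.
#'
#' @param a Intrinsic growth intercept (per year, log scale).
#' @param b Density-dependence slope (per abundance unit for `"ricker"`, per
#'   ln-unit for `"gompertz"`); negative values regulate.
#' @param c Linear time-trend coefficient per standardized year (default 0).
#' @param sigma_e Process-noise SD on the log scale (>= 0).
#' @param sigma_u SD of site random intercepts on the log scale (>= 0;
#'   multi-site simulations only).
#' @param n0 Initial abundance (> 0).
#' @param mode `"ricker"` or `"gompertz"`.
#' @return A `sim_params` list.
#' @export
sim_params <- function(a, b, c = 0, sigma_e = 0, sigma_u = 0, n0,
                       mode = c("ricker", "gompertz")) {
  mode <- match.arg(mode)
  stopifnot(sigma_e >= 0, sigma_u >= 0, n0 > 0)
  structure(list(a = a, b = b, c = c, sigma_e = sigma_e, sigma_u = sigma_u,
                 n0 = n0, mode = mode),
            class = "sim_params")
}

#' Specify catastrophic storm years
#'
#' Storms are exogenous mass-mortality events applied as additive negative
#' shocks on the log-abundance scale in the named years — they are not model
#' terms, mirroring how such events are treated in the analysis (excluded,
#' not fitted).
#'
#' @param years Integer years in which a storm depresses abundance.
#' @param log_mortality Negative shock on the log scale (e.g. -1.2 means the
#'   population is multiplied by exp(-1.2) ~ 0.30 on top of its dynamics).
#' @return A `storm_spec` list.
#' @export
storm_spec <- function(years, log_mortality) {
  stopifnot(log_mortality < 0)
  structure(list(years = as.integer(years), log_mortality = log_mortality),
            class = "storm_spec")
}

#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Simulate one abundance time series
#'
#' Runs the stochastic recursion described in [sim_params()] over a range of
#' calendar years. With `sigma_e = 0` and no storms the series follows the
#' deterministic skeleton exactly; identical seeds give identical series.
#'
#' @param params A `sim_params`.
#' @param years Integer vector of consecutive calendar years (length >= 3).
#' @param storms A `storm_spec` or `NULL`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param series_id,site Labels attached to the output rows.
#' @param intercept_shift Additive shift of `a` (used internally for site
#'   random intercepts).
#' @return A tibble with columns `series_id`, `site`, `year`, `value` — the
#'   same dialect [read_series_csv()] reads.
#' @export
simulate_series <- function(params, years, storms = NULL, seed = NULL,
                            series_id = "sim", site = "sim",
                            intercept_shift = 0) {
  stopifnot(inherits(params, "sim_params"), length(years) >= 3,
            all(diff(years) == 1))
  with_seed(seed, {
    tn <- length(years)
    ttilde <- as.numeric(scale(seq_len(tn)))
    eps <- if (params$sigma_e > 0) stats::rnorm(tn, 0, params$sigma_e) else numeric(tn)
    storm_shock <- numeric(tn)
    if (!is.null(storms)) {
      storm_shock[years %in% storms$years] <- storms$log_mortality
    }
    logN <- numeric(tn)
    logN[1] <- log(params$n0)
    for (t in 2:tn) {
      dens <- if (params$mode == "ricker") exp(logN[t - 1]) else logN[t - 1]
      logN[t] <- logN[t - 1] + params$a + intercept_shift + params$b * dens +
        params$c * ttilde[t] + storm_shock[t] + eps[t]
      if (logN[t] < log(1e-12)) {
        stop("simulated abundance underflowed below 1e-12 in year ", years[t],
             "; weaken the decline or noise parameters", call. = FALSE)
      }
    }
    tibble::tibble(series_id = series_id, site = site, year = as.integer(years),
                   value = exp(logN))
  })
}

#' Simulate several site series sharing a density-dependence slope
#'
#' Each site gets its own intercept `a + u_s`, `u_s ~ N(0, sigma_u^2)` drawn
#' once per site, and then runs the (typically Gompertz) recursion
#' independently — the data-generating twin of the multi-site random-intercept
#' analyses.
#'
#' @param params A `sim_params` (with `sigma_u` the intercept SD).
#' @param site_count Number of sites (>= 2).
#' @param years Integer vector of consecutive calendar years.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble of all site series stacked, sites labelled
#'   `site1...siteK`, one `series_id` per site.
#' @export
simulate_multisite <- function(params, site_count, years, seed = NULL) {
  stopifnot(site_count >= 2)
  with_seed(seed, {
    u <- if (params$sigma_u > 0) stats::rnorm(site_count, 0, params$sigma_u) else numeric(site_count)
    purrr::map(seq_len(site_count), function(s) {
      simulate_series(params, years,
                      series_id = paste0("series", s),
                      site = paste0("site", s),
                      intercept_shift = u[s])
    }) %>% purrr::list_rbind()
  })
}

#' A packaged monarch-like simulation scenario
#'
#' Generates three synthetic datasets with the shape and effect sizes of the
#' monarch density-dependence study: (i) a single 24-year overwintering
#' series (Ricker feedback, negative time trend, two catastrophic storm years
#' mid-series); (ii) six 17-year Gompertz adult-density site series; and
#' (iii) five 18-year Gompertz egg-density site series spread over three
#' region labels. Standardized-scale density effects are in the -0.6 to -0.9
#' range typical of the study system.
#'
#' @param seed Integer seed driving all three datasets.
#' @return A list with elements `overwinter`, `adult`, `egg` (tibbles in the
#'   [read_series_csv()] dialect) and `storm_years` (the two storm years of
#'   the overwintering series, to be excluded in analysis).
#' @export
monarch_like_scenario <- function(seed = 1) {
  with_seed(seed, {
    ow_years <- 1993:2016
    storms <- storm_spec(c(2002, 2004), log_mortality = -1.2)
    ow <- simulate_series(
      sim_params(a = 1.6, b = -0.22, c = -0.35, sigma_e = 0.45, n0 = 6,
                 mode = "ricker"),
      years = ow_years, storms = storms,
      series_id = "overwinter", site = "mexico"
    )
    adult <- simulate_multisite(
      sim_params(a = 2.5, b = -1.4, c = 0, sigma_e = 0.35, sigma_u = 0.15,
                 n0 = 6, mode = "gompertz"),
      site_count = 6, years = 1998:2014
    )
    egg <- simulate_multisite(
      sim_params(a = -1.8, b = -1.5, c = 0, sigma_e = 0.4, sigma_u = 0.15,
                 n0 = 0.3, mode = "gompertz"),
      site_count = 5, years = 1997:2014
    )
    # five egg series over three region labels, as in the field data
    egg$site <- c("south", "midwest", "midwest", "northeast",
                  "northeast")[match(egg$series_id, unique(egg$series_id))]
    list(overwinter = ow, adult = adult, egg = egg,
         storm_years = storms$years)
  })
}
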