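# Small programmatic fixtures shared across test files.

# A gap-free single-site abundance tibble.
make_series <- function(values, years = seq_along(values) + 1993,
                        id = "s1", site = "site1") {
  tibble::tibble(series_id = id, site = site,
                 year = as.integer(years), value = values)
}

# Write a series tibble to a temp CSV and return the path.
series_csv <- function(series) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(series, path, progress = FALSE)
  path
}

# Prepared growth dataset from a raw series, silencing the exclusion log.
prepared <- function(series, exclude = integer(), ln = FALSE, lag = 1) {
  obs <- compute_growth_rates(series, lag = lag)
  if (length(exclude) > 0) {
    obs <- suppressMessages(exclude_transitions(obs, exclude))
  }
  prepare_predictors(obs, ln_transform = ln)
}

# A hand-built dd_fit-shaped object for model-averaging arithmetic tests.
fake_fit <- function(terms, estimates, ses, loglik, n, spec_terms = terms,
                     random = NULL, df_resid = Inf) {
  spec <- model_spec(setdiff(spec_terms, "(Intercept)"), random = random)
  structure(list(
    spec = spec,
    coefficients = tibble::tibble(term = c("(Intercept)", terms),
                                  estimate = c(0, estimates),
                                  se = c(0, ses)),
    sigma2_e = 1, sigma2_u = NULL, loglik = loglik, n_obs = as.integer(n),
    k_params = length(terms) + 2L, converged = TRUE, r2 = 0,
    fitted = numeric(0), residuals = numeric(0), df_resid = df_resid
  ), class = "dd_fit")
}

# Deterministic multi-site growth design for likelihood tests.
lmm_test_design <- function(seed = 11, site_count = 3, years = 2000:2009,
                            terms = "L1") {
  series <- simulate_multisite(
    sim_params(a = 1, b = -0.5, sigma_e = 0.3, sigma_u = 0.4, n0 = 7,
               mode = "gompertz"),
    site_count = site_count, years = years, seed = seed
  )
  ds <- prepare_predictors(compute_growth_rates(series, lag = 1),
                           ln_transform = TRUE)
  build_design(model_spec(terms, random = "site"), ds)
}
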