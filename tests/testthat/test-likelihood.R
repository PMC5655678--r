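test_that("linear ML fit matches closed-form hand results", {
  # y = (-1, 1), intercept only: beta = 0, sigma2 = 1, ll = -ln(2*pi) - 1
  d <- structure(list(y = c(-1, 1),
                      X = matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)")),
                      groups = NULL, spec = model_spec(character()), n = 2L),
                 class = "dd_design")
  fit <- fit_linear_ml(d)
  expect_equal(fit$coefficients$estimate, 0)
  expect_equal(fit$sigma2_e, 1)
  expect_equal(fit$loglik, -log(2 * pi) - 1, tolerance = 1e-12)

  d$y <- c(-1, 0, 1)
  d$X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  fit3 <- fit_linear_ml(d)
  expect_equal(fit3$sigma2_e, 2 / 3)
  expect_equal(fit3$loglik, -3 / 2 * log(2 * pi * 2 / 3) - 3 / 2,
               tolerance = 1e-12)
  # too few rows for the coefficients requested
  d$X <- cbind(d$X, x = c(0, 1, 2), z = c(1, 0, 2))
  expect_error(fit_linear_ml(d), "more observations")
})

test_that("linear ML loglik equals the sum of Gaussian log-densities", {
  set.seed(3)
  ds <- prepared(make_series(exp(rnorm(15, 1, 0.4))))
  fit <- fit_linear_ml(build_design(model_spec(c("L1", "TIME")), ds))
  direct <- sum(dnorm(fit$residuals, 0, sqrt(fit$sigma2_e), log = TRUE))
  expect_equal(fit$loglik, direct, tolerance = 1e-10)
  # and equals the dense oracle with sigma2_u = 0
  dg <- build_design(model_spec(c("L1", "TIME")), ds)
  expect_equal(loglik_dense_oracle(dg, fit$coefficients$estimate, 0,
                                   fit$sigma2_e),
               fit$loglik, tolerance = 1e-10)
  expect_equal(fit$r2, 1 - sum(fit$residuals^2) /
                 sum((dg$y - mean(dg$y))^2))
})

test_that("degenerate linear designs are rejected", {
  set.seed(4)
  ds <- prepared(make_series(exp(rnorm(10))))
  dg <- build_design(model_spec("L1"), ds)
  dg$y <- 2 * dg$X[, "L1"] + 1          # perfectly collinear response
  expect_error(fit_linear_ml(dg), "unbounded")
  dg2 <- build_design(model_spec("L1"), ds)
  dg2$X <- cbind(dg2$X, L1b = dg2$X[, "L1"])  # rank deficient
  expect_error(fit_linear_ml(dg2), "rank deficient")
})

test_that("mixed-model ML matches the dense multivariate-normal oracle", {
  dg <- lmm_test_design(seed = 11)
  fit <- fit_lmm_ml(dg)
  expect_true(fit$converged)
  oracle <- loglik_dense_oracle(dg, fit$coefficients$estimate,
                                fit$sigma2_u, fit$sigma2_e)
  expect_equal(fit$loglik, oracle, tolerance = 1e-8)
  # permuting observations within groups leaves the oracle unchanged
  ord <- order(dg$groups, sample(length(dg$y)))
  dg_perm <- dg
  dg_perm$y <- dg$y[ord]
  dg_perm$X <- dg$X[ord, , drop = FALSE]
  dg_perm$groups <- dg$groups[ord]
  expect_equal(loglik_dense_oracle(dg_perm, fit$coefficients$estimate,
                                   fit$sigma2_u, fit$sigma2_e),
               oracle, tolerance = 1e-10)
})

test_that("mixed-model ML agrees with an independent optimizer of the oracle", {
  dg <- lmm_test_design(seed = 23, site_count = 2, years = 2000:2005)
  fit <- fit_lmm_ml(dg)
  # independent route: direct numerical ML on the dense likelihood
  obj <- function(par) {
    -loglik_dense_oracle(dg, par[1:ncol(dg$X)],
                         exp(par[ncol(dg$X) + 1]), exp(par[ncol(dg$X) + 2]))
  }
  start <- c(rep(0, ncol(dg$X)), log(0.1), log(0.1))
  opt <- optim(start, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-6)
})

test_that("mixed-model ML reproduces lme4 on multi-site growth data", {
  skip_if_not_installed("lme4")
  dg <- lmm_test_design(seed = 5, site_count = 5, years = 2000:2012,
                        terms = c("L1", "TIME"))
  fit <- fit_lmm_ml(dg)
  df <- data.frame(y = dg$y, L1 = dg$X[, "L1"], TIME = dg$X[, "TIME"],
                   g = dg$groups)
  ref <- lme4::lmer(y ~ L1 + TIME + (1 | g), df, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate,
               unname(lme4::fixef(ref)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma2_u, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-5)
})

test_that("with no group variance the mixed fit collapses to the linear fit", {
  series <- simulate_multisite(
    sim_params(a = 1, b = -0.5, sigma_e = 0.3, sigma_u = 0, n0 = 7,
               mode = "gompertz"),
    site_count = 4, years = 2000:2009, seed = 42
  )
  ds <- prepare_predictors(compute_growth_rates(series), ln_transform = TRUE)
  dg <- build_design(model_spec("L1", random = "site"), ds)
  mixed <- fit_lmm_ml(dg)
  dg_lin <- dg
  dg_lin$groups <- NULL
  linear <- fit_linear_ml(dg_lin)
  expect_equal(mixed$sigma2_u, 0)
  expect_equal(mixed$loglik, linear$loglik, tolerance = 1e-6)
  expect_equal(mixed$coefficients$estimate, linear$coefficients$estimate,
               tolerance = 1e-8)
  # parameter counting keeps both variance parameters at the boundary
  expect_equal(mixed$k_params, linear$k_params + 1L)
})

test_that("single-group designs are redirected to the linear fitter", {
  series <- simulate_series(sim_params(a = 1, b = -0.5, sigma_e = 0.3, n0 = 7,
                                       mode = "gompertz"),
                            years = 2000:2009, seed = 2)
  ds <- prepare_predictors(compute_growth_rates(series), ln_transform = TRUE)
  dg <- build_design(model_spec("L1", random = "site"), ds)
  expect_error(fit_lmm_ml(dg), "fit_linear_ml")
})

test_that("marginal pseudo-R2 follows its defining ratio", {
  dg <- lmm_test_design(seed = 31)
  fit <- fit_lmm_ml(dg)
  pred <- drop(dg$X %*% fit$coefficients$estimate)
  expect_equal(fit$r2,
               var(pred) / (var(pred) + fit$sigma2_u + fit$sigma2_e))
  expect_gte(fit$r2, 0)
  expect_lte(fit$r2, 1)
  # intercept-only fixed part explains nothing
  dg0 <- lmm_test_design(seed = 31, terms = character())
  expect_equal(fit_lmm_ml(dg0)$r2, 0)
})

test_that("parameter counting matches the fixed + variance convention", {
  set.seed(8)
  ds <- prepared(make_series(exp(rnorm(24, 1, 0.3))))
  full <- fit_linear_ml(build_design(full_spec("overwinter"), ds))
  expect_equal(full$k_params, 5L)   # 4 fixed + 1 variance
  two <- fit_linear_ml(build_design(model_spec(c("L1", "TIME")), ds))
  expect_equal(two$k_params, 4L)
  mixed <- fit_lmm_ml(lmm_test_design(seed = 7, terms = "L1"))
  expect_equal(mixed$k_params, 4L)  # 2 fixed + 2 variances
})

test_that("tidy and glance summarize fits in broom shape", {
  dg <- lmm_test_design(seed = 13)
  fit <- fit_lmm_ml(dg)
  td <- tidy(fit, conf.int = TRUE)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$df, fit$k_params)
  expect_equal(gl$logLik, fit$loglik)
  expect_equal(nrow(gl), 1)
})
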