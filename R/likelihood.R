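#' Maximum-likelihood fit of a Gaussian linear model
#'
#' Closed-form ML fit of the linear model y = X beta + e, e ~ N(0, sigma2_e I).
#' Coefficients are the least-squares solution; the residual variance is the
#' ML estimate RSS/n (not RSS/(n-p)), so log-likelihoods are comparable across
#' fixed-effect structures and usable in AICc. Standard errors, in contrast,
#' use the degrees-of-freedom-corrected residual variance, matching the Wald
#' intervals conventional linear-model software reports.
#'
#' @param design A `dd_design` from [build_design()] (without grouping).
#' @return A `dd_fit` object: coefficients with standard errors, `sigma2_e`
#'   (ML), `loglik`, `n_obs`, `k_params` (fixed coefficients + 1 variance
#'   parameter), `r2` = 1 - RSS/TSS, fitted values and residuals.
#' @export
fit_linear_ml <- function(design) {
  stopifnot(inherits(design, "dd_design"))
  y <- design$y
  X <- design$X
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more observations than coefficients", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  beta <- qr.coef(qr_x, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  sigma2_ml <- rss / n
  if (sigma2_ml < 1e-12) {
    stop("residual variance numerically zero; likelihood unbounded",
         call. = FALSE)
  }
  loglik <- -n / 2 * log(2 * pi * sigma2_ml) - n / 2
  sigma2_unb <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(xtx_inv) * sigma2_unb)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  new_dd_fit(
    spec = design$spec,
    coefficients = tibble::tibble(term = colnames(X), estimate = unname(beta),
                                  se = unname(se)),
    sigma2_e = sigma2_ml, sigma2_u = NULL,
    loglik = loglik, n_obs = n, k_params = p + 1L,
    converged = TRUE, r2 = r2,
    fitted = fitted, residuals = resid, df_resid = n - p
  )
}

#' Maximum-likelihood fit of a random-intercept linear mixed model
#'
#' Fits y = X beta + u[group] + e with u ~ N(0, sigma2_u), e ~ N(0, sigma2_e)
#' by maximizing the marginal Gaussian likelihood (ML, never REML, so that
#' AICc comparisons across fixed-effect structures are valid). The fixed
#' effects and sigma2_e are profiled out in closed form for a given variance
#' ratio lambda = sigma2_u / sigma2_e; the profile likelihood is then
#' maximized over ln(lambda) on a bounded grid followed by golden-section
#' refinement, with the boundary sigma2_u = 0 always evaluated. The
#' optimization is deterministic (no random restarts).
#'
#' @param design A `dd_design` with a `groups` factor (at least 2 levels).
#' @return A `dd_fit` with `sigma2_u` and `sigma2_e` (ML), marginal
#'   pseudo-R-squared in `r2`, and `k_params` = fixed coefficients + 2
#'   variance parameters (kept at 2 even for boundary fits).
#' @export
fit_lmm_ml <- function(design) {
  stopifnot(inherits(design, "dd_design"))
  if (is.null(design$groups)) {
    stop("design has no grouping factor; use fit_linear_ml()", call. = FALSE)
  }
  g <- droplevels(design$groups)
  if (nlevels(g) < 2) {
    stop("fewer than 2 groups; use fit_linear_ml()", call. = FALSE)
  }
  y <- design$y
  X <- design$X
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("too few observations for a mixed model", call. = FALSE)
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)

  # Profile log-likelihood at variance ratio lambda = sigma2_u / sigma2_e.
  # Per group: V_g = I + lambda J; V_g^{-1} = I - lambda/(1 + lambda n_g) J;
  # log|V_g| = log(1 + lambda n_g).
  idx <- split(seq_len(n), g)
  profile_fit <- function(lambda) {
    XtVX <- matrix(0, p, p)
    XtVy <- numeric(p)
    logdet <- 0
    for (ii in idx) {
      Xg <- X[ii, , drop = FALSE]
      yg <- y[ii]
      ng <- length(ii)
      w <- lambda / (1 + lambda * ng)
      XtVX <- XtVX + crossprod(Xg) - w * tcrossprod(colSums(Xg))
      XtVy <- XtVy + crossprod(Xg, yg) - w * colSums(Xg) * sum(yg)
      logdet <- logdet + log1p(lambda * ng)
    }
    beta <- solve(XtVX, XtVy)
    qform <- 0
    for (ii in idx) {
      rg <- y[ii] - drop(X[ii, , drop = FALSE] %*% beta)
      ng <- length(ii)
      w <- lambda / (1 + lambda * ng)
      qform <- qform + sum(rg^2) - w * sum(rg)^2
    }
    sigma2_e <- qform / n
    ll <- -n / 2 * log(2 * pi * sigma2_e) - logdet / 2 - n / 2
    list(loglik = ll, beta = drop(beta), sigma2_e = sigma2_e,
         XtVX = XtVX, lambda = lambda)
  }
  obj <- function(log_lambda) profile_fit(exp(log_lambda))$loglik

  grid <- seq(-15, 8, length.out = 47)
  vals <- vapply(grid, obj, numeric(1))
  best <- which.max(vals)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-10)
  cand <- profile_fit(exp(opt$maximum))
  at_zero <- profile_fit(0)
  converged <- is.finite(cand$loglik)
  if (at_zero$loglik >= cand$loglik - 1e-8) cand <- at_zero

  sigma2_e <- cand$sigma2_e
  if (sigma2_e < 1e-12) {
    stop("residual variance numerically zero; likelihood unbounded",
         call. = FALSE)
  }
  sigma2_u <- cand$lambda * sigma2_e
  # Wald SEs: cov(beta) = sigma2_e * (X' V^{-1} X)^{-1}, with the residual
  # variance df-corrected as in conventional mixed-model software.
  sigma2_e_unb <- sigma2_e * n / (n - p)
  vcov_beta <- solve(cand$XtVX) * sigma2_e_unb
  se <- sqrt(diag(vcov_beta))
  fitted_fix <- drop(X %*% cand$beta)
  fit <- new_dd_fit(
    spec = design$spec,
    coefficients = tibble::tibble(term = colnames(X),
                                  estimate = unname(cand$beta),
                                  se = unname(se)),
    sigma2_e = sigma2_e, sigma2_u = sigma2_u,
    loglik = cand$loglik, n_obs = n, k_params = p + 2L,
    converged = converged, r2 = NA_real_,
    fitted = fitted_fix, residuals = y - fitted_fix, df_resid = n - p
  )
  fit$r2 <- marginal_pseudo_r2(fit, design)
  fit
}

#' Fit a model specification by maximum likelihood
#'
#' Dispatches to [fit_lmm_ml()] when the design carries a grouping factor and
#' to [fit_linear_ml()] otherwise.
#'
#' @param design A `dd_design`.
#' @return A `dd_fit`.
#' @export
fit_ml <- function(design) {
  if (is.null(design$groups)) fit_linear_ml(design) else fit_lmm_ml(design)
}

#' Marginal pseudo-R-squared of a mixed-model fit
#'
#' Variance explained by the fixed effects alone, relative to the total of
#' fixed-effect, random-intercept and residual variance:
#' var(X beta) / (var(X beta) + sigma2_u + sigma2_e).
#'
#' @param fit A `dd_fit` from [fit_lmm_ml()].
#' @param design The `dd_design` the model was fitted to.
#' @return A number in \[0, 1\]; 0 for an intercept-only fixed part.
#' @export
marginal_pseudo_r2 <- function(fit, design) {
  pred <- drop(design$X %*% fit$coefficients$estimate)
  var_f <- stats::var(pred)
  s2u <- if (is.null(fit$sigma2_u)) 0 else fit$sigma2_u
  denom <- var_f + s2u + fit$sigma2_e
  if (denom < 1e-300) {
    return(if (var_f > 0) 1 else 0)
  }
  var_f / denom
}

#' Dense multivariate-normal log-likelihood oracle
#'
#' Evaluates the log density of the observed responses under the full
#' multivariate normal implied by a random-intercept model, assembling the
#' n-by-n covariance matrix explicitly: Sigma = sigma2_u Z Z' + sigma2_e I.
#' Intended as an independent cross-check of the profiled likelihood in
#' [fit_lmm_ml()]; it shares no code path with it.
#'
#' @param design A `dd_design` (grouping optional; without groups the model is
#'   i.i.d. Gaussian).
#' @param coefficients Numeric vector of fixed-effect coefficients, in design
#'   column order.
#' @param sigma2_u Random-intercept variance (>= 0); ignored when the design
#'   has no groups.
#' @param sigma2_e Residual variance (> 0).
#' @return The log-likelihood as a single number.
#' @export
loglik_dense_oracle <- function(design, coefficients, sigma2_u, sigma2_e) {
  stopifnot(sigma2_e > 0, sigma2_u >= 0)
  y <- design$y
  n <- length(y)
  mu <- drop(design$X %*% coefficients)
  Sigma <- diag(sigma2_e, n)
  if (!is.null(design$groups) && sigma2_u > 0) {
    Z <- stats::model.matrix(~ 0 + g, data.frame(g = design$groups))
    Sigma <- Sigma + sigma2_u * tcrossprod(Z)
  }
  ch <- tryCatch(chol(Sigma),
                 error = function(e) stop("assembled covariance not positive definite",
                                          call. = FALSE))
  z <- backsolve(ch, y - mu, transpose = TRUE)
  -n / 2 * log(2 * pi) - sum(log(diag(ch))) - sum(z^2) / 2
}

#' @keywords internal
new_dd_fit <- function(spec, coefficients, sigma2_e, sigma2_u, loglik, n_obs,
                       k_params, converged, r2, fitted, residuals, df_resid) {
  structure(list(spec = spec, coefficients = coefficients,
                 sigma2_e = sigma2_e, sigma2_u = sigma2_u,
                 loglik = loglik, n_obs = n_obs, k_params = k_params,
                 converged = converged, r2 = r2, fitted = fitted,
                 residuals = residuals, df_resid = df_resid),
            class = "dd_fit")
}

#' @export
print.dd_fit <- function(x, ...) {
  cat("<dd_fit> ", format(x$spec), "\n", sep = "")
  cat(sprintf("  n = %d, k = %d, logLik = %.4f, R2 = %.4f\n",
              x$n_obs, x$k_params, x$loglik, x$r2))
  print(x$coefficients)
  cat(sprintf("  sigma2_e = %.5f", x$sigma2_e))
  if (!is.null(x$sigma2_u)) cat(sprintf(", sigma2_u = %.5f", x$sigma2_u))
  cat("\n")
  invisible(x)
}

#' Tidy the coefficients of a density-dependence model fit
#'
#' @param x A `dd_fit`.
#' @param conf.int If `TRUE`, append Wald confidence limits.
#' @param conf.level Confidence level for the interval.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect coefficient: `term`,
#'   `estimate`, `std.error` and optionally `conf.low`, `conf.high`.
#' @export
tidy.dd_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- tibble::tibble(term = x$coefficients$term,
                        estimate = x$coefficients$estimate,
                        std.error = x$coefficients$se)
  if (conf.int) {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' One-row summary of a density-dependence model fit
#'
#' @param x A `dd_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `logLik`, `nobs`, `df` (parameters counted as
#'   fixed coefficients plus variance parameters), `r.squared`,
#'   `sigma2.resid`, `sigma2.group` and `converged`.
#' @export
glance.dd_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n_obs, df = x$k_params,
                 r.squared = x$r2, sigma2.resid = x$sigma2_e,
                 sigma2.group = if (is.null(x$sigma2_u)) NA_real_ else x$sigma2_u,
                 converged = x$converged)
}
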