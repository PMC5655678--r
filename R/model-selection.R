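#' Second-order Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1), the small-sample corrected
#' criterion appropriate for the short annual series this workflow targets.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (fixed-effect coefficients plus
#'   variance parameters).
#' @param n Number of observations.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-17.892, k = 4, n = 21)
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) {
    stop("AICc undefined for n <= k + 1", call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc differences
#'
#' Each model's relative likelihood is exp(-Delta_i / 2); its weight is that
#' likelihood divided by the sum over all models in the set.
#'
#' @param deltas Numeric vector of AICc differences; the best model has 0.
#' @return Numeric vector of weights summing to 1.
#' @export
#' @examples
#' akaike_weights(c(0, 1.38, 2.40, 3.79, 6.51))
akaike_weights <- function(deltas) {
  if (length(deltas) == 0) return(numeric())
  if (abs(min(deltas)) > 1e-8) {
    stop("deltas must be AICc differences with minimum 0", call. = FALSE)
  }
  lik <- exp(-deltas / 2)
  lik / sum(lik)
}

#' Rank a candidate set of fitted models by AICc
#'
#' Builds the ranked candidate table: AICc, differences from the best model,
#' Akaike weights (normalized over the full candidate set) and variance
#' explained. Rows are sorted by AICc ascending; ties are broken by fewer
#' parameters, then by model label. Unconverged fits are excluded with a
#' warning.
#'
#' @param fits A list of `dd_fit` objects sharing the same observations.
#' @param n Number of observations; defaults to the common `n_obs` of the
#'   fits (they must agree).
#' @return A `candidate_table`: a tibble with columns `rank`, `model`,
#'   `df`, `logLik`, `aicc`, `delta_aicc`, `weight`, `r2`, carrying the fit
#'   list and `n_obs` as attributes for downstream model averaging.
#' @export
rank_candidates <- function(fits, n = NULL) {
  stopifnot(is.list(fits), length(fits) > 0)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv)) {
    warning(sum(!conv), " unconverged fit(s) excluded from ranking",
            call. = FALSE)
    fits <- fits[conv]
  }
  if (length(fits) == 0) stop("no converged fits to rank", call. = FALSE)
  ns <- vapply(fits, function(f) f$n_obs, integer(1))
  if (is.null(n)) {
    if (length(unique(ns)) != 1) {
      stop("fits were made on differing numbers of observations", call. = FALSE)
    }
    n <- ns[1]
  }
  tab <- tibble::tibble(
    model = vapply(fits, function(f) format(f$spec), character(1)),
    df = vapply(fits, function(f) f$k_params, integer(1)),
    logLik = vapply(fits, function(f) f$loglik, numeric(1)),
    r2 = vapply(fits, function(f) f$r2, numeric(1))
  )
  tab$aicc <- aicc(tab$logLik, tab$df, n)
  ord <- order(tab$aicc, tab$df, tab$model)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  tab$weight <- akaike_weights(tab$delta_aicc)
  tab$rank <- seq_len(nrow(tab))
  tab <- tab[, c("rank", "model", "df", "logLik", "aicc", "delta_aicc",
                 "weight", "r2")]
  structure(tab, fits = fits, n_obs = n,
            class = c("candidate_table", class(tab)))
}

#' @export
print.candidate_table <- function(x, ...) {
  cat(report_table(x), sep = "\n")
  invisible(x)
}

#' Conditional model-averaged coefficients with confidence intervals
#'
#' For each fixed-effect term, averages the per-model estimates over the
#' candidate models that contain the term, with Akaike weights renormalized
#' to 1 over that subset (conditional, "natural" averaging). The averaged
#' standard error combines within-model sampling variance and between-model
#' spread of the estimates: SE = sum_i w'_i sqrt(se_i^2 + (b_i - b_bar)^2),
#' with each within-model SE first inflated by t_{df_i, 0.975} / z_{0.975} to
#' reflect small-sample Wald intervals. The confidence interval is
#' b_bar +/- z * SE.
#'
#' @param table A `candidate_table` from [rank_candidates()].
#' @param level Confidence level (default 0.95).
#' @param include_intercept If `TRUE`, also average the intercept.
#' @return An `averaged_coefficients` tibble: `term`, `estimate`, `se`,
#'   `lower`, `upper`, `relative_importance` (summed un-renormalized weight of
#'   models containing the term) and `n_models`.
#' @export
model_average <- function(table, level = 0.95, include_intercept = FALSE) {
  stopifnot(inherits(table, "candidate_table"))
  fits <- attr(table, "fits", exact = TRUE)
  w <- table$weight
  terms <- unique(unlist(purrr::map(fits, function(f) f$coefficients$term)))
  if (!include_intercept) terms <- setdiff(terms, "(Intercept)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- purrr::map(terms, function(term) {
    has <- vapply(fits, function(f) term %in% f$coefficients$term, logical(1))
    wi <- w[has] / sum(w[has])
    est <- vapply(fits[has], function(f) {
      f$coefficients$estimate[f$coefficients$term == term]
    }, numeric(1))
    se <- vapply(fits[has], function(f) {
      f$coefficients$se[f$coefficients$term == term]
    }, numeric(1))
    df <- vapply(fits[has], function(f) f$df_resid, numeric(1))
    se_t <- se * stats::qt(1 - (1 - level) / 2, df) / z
    b_bar <- sum(wi * est)
    se_bar <- sum(wi * sqrt(se_t^2 + (est - b_bar)^2))
    tibble::tibble(term = term, estimate = b_bar, se = se_bar,
                   lower = b_bar - z * se_bar, upper = b_bar + z * se_bar,
                   relative_importance = sum(w[has]),
                   n_models = sum(has))
  })
  out <- purrr::list_rbind(rows)
  structure(out, level = level,
            class = c("averaged_coefficients", class(out)))
}

#' Render a ranked candidate table as an aligned plain-text report
#'
#' Shows models with `delta_aicc < show_cut` (default 7), flagging the
#' plausible set (`delta_aicc < plausible_cut`, default 2) with an asterisk.
#'
#' @param table A `candidate_table`.
#' @param show_cut Only rows with AICc difference below this are rendered.
#' @param plausible_cut AICc difference below which a model is flagged
#'   plausible.
#' @return A character vector of report lines (invisibly usable with
#'   `cat(..., sep = "\n")`).
#' @export
report_table <- function(table, show_cut = 7, plausible_cut = 2) {
  shown <- table[table$delta_aicc < show_cut, , drop = FALSE]
  header <- sprintf("%-4s %-38s %6s %3s %9s %7s %7s %s",
                    "rank", "model", "dAICc", "df", "logLik", "R2", "weight", "")
  if (nrow(shown) == 0) return(character())
  lines <- sprintf("%-4d %-38s %6.2f %3d %9.3f %7.4f %7.3f %s",
                   shown$rank, shown$model, shown$delta_aicc, shown$df,
                   shown$logLik, shown$r2, shown$weight,
                   ifelse(shown$delta_aicc < plausible_cut, "*", ""))
  c(header, lines,
    sprintf("n = %d; * plausible (dAICc < %g); models with dAICc >= %g omitted",
            attr(table, "n_obs", exact = TRUE), plausible_cut, show_cut))
}
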