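# Model-term vocabulary. L1/L2 are the lag-1/lag-2 density predictors (possibly
# ln-transformed and standardized upstream), TIME the standardized calendar
# year, and L1:TIME the product of the standardized L1 and TIME columns.
DD_TERMS <- c("L1", "L2", "TIME", "L1:TIME")

#' Construct a fixed-effects model specification
#'
#' A model specification is an ordered set of fixed-effect terms drawn from
#' `L1`, `L2`, `TIME` and `L1:TIME` (an intercept is always included), plus an
#' optional random-intercept grouping label (the site factor for multi-site
#' analyses). The interaction `L1:TIME` requires both `L1` and `TIME`
#' (marginality), and the delayed-feedback term `L2` is never combined with
#' time terms: delayed density dependence is screened as a separate model.
#'
#' @param terms Character vector of terms, a subset of
#'   `c("L1", "L2", "TIME", "L1:TIME")`. May be empty (intercept-only model).
#' @param random Grouping label for a site-level random intercept, or `NULL`
#'   for an ordinary linear model.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec(c("L1", "TIME"))
#' model_spec("L1", random = "site")
model_spec <- function(terms = character(), random = NULL) {
  terms <- unique(as.character(terms))
  bad <- setdiff(terms, DD_TERMS)
  if (length(bad) > 0) {
    stop("unknown model term(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  terms <- DD_TERMS[DD_TERMS %in% terms]  # canonical order
  if ("L1:TIME" %in% terms && !all(c("L1", "TIME") %in% terms)) {
    stop("interaction L1:TIME requires both main effects (marginality)",
         call. = FALSE)
  }
  if ("L2" %in% terms && any(c("TIME", "L1:TIME") %in% terms)) {
    stop("L2 (delayed feedback) is screened separately and cannot be combined ",
         "with time terms", call. = FALSE)
  }
  structure(list(terms = terms, random = random), class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  rhs <- paste(c("1", x$terms), collapse = " + ")
  out <- paste("R ~", rhs)
  if (!is.null(x$random)) out <- paste(out, "|", x$random)
  out
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Parse the compact text form of a model specification
#'
#' Inverse of `format()` for `model_spec` objects, accepting strings such as
#' `"R ~ 1 + L1 + TIME + L1:TIME | site"`.
#'
#' @param text A single string.
#' @return A `model_spec`.
#' @export
parse_spec <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  parts <- strsplit(text, "|", fixed = TRUE)[[1]]
  random <- if (length(parts) > 1) trimws(parts[2]) else NULL
  rhs <- sub("^\\s*R\\s*~", "", parts[1])
  terms <- trimws(strsplit(rhs, "+", fixed = TRUE)[[1]])
  terms <- setdiff(terms, c("1", ""))
  model_spec(terms, random = random)
}

#' Full model specification for an analysis kind
#'
#' Returns the full direct-density-dependence model for the given analysis:
#' growth rate against lag-1 density, time, and their interaction. The
#' overwintering analysis (a single whole-population series) uses an ordinary
#' linear model; the adult-density and egg-density analyses pool several site
#' series and add a site-level random intercept.
#'
#' @param analysis_kind One of `"overwinter"`, `"adult"`, `"egg"`.
#' @return A `model_spec` with terms `L1`, `TIME`, `L1:TIME` and, for
#'   multi-site kinds, `random = "site"`.
#' @export
full_spec <- function(analysis_kind = c("overwinter", "adult", "egg")) {
  analysis_kind <- match.arg(analysis_kind)
  random <- if (analysis_kind == "overwinter") NULL else "site"
  model_spec(c("L1", "TIME", "L1:TIME"), random = random)
}

#' Delayed (two-year lag) density-dependence screening model
#'
#' The delayed-feedback screen is run before the main candidate-set
#' comparison: growth rate against both the lag-1 and lag-2 density
#' predictors, with the same grouping structure as [full_spec()].
#'
#' @inheritParams full_spec
#' @return A `model_spec` with terms `L1` and `L2`.
#' @export
delayed_spec <- function(analysis_kind = c("overwinter", "adult", "egg")) {
  analysis_kind <- match.arg(analysis_kind)
  random <- if (analysis_kind == "overwinter") NULL else "site"
  model_spec(c("L1", "L2"), random = random)
}

#' Enumerate all candidate models nested in a full model
#'
#' Produces every subset of the full model's terms that respects marginality
#' (an interaction only appears together with both its main effects),
#' including the intercept-only model. The order is deterministic: by term
#' count, then lexically by the formatted term set.
#'
#' @param full A `model_spec`, typically from [full_spec()].
#' @return A list of `model_spec` objects.
#' @export
#' @examples
#' length(enumerate_candidates(full_spec("overwinter")))  # 5
enumerate_candidates <- function(full) {
  stopifnot(inherits(full, "model_spec"))
  terms <- full$terms
  m <- length(terms)
  subsets <- purrr::map(seq_len(2^m) - 1L, function(mask) {
    terms[bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0]
  })
  ok <- purrr::keep(subsets, function(s) {
    !("L1:TIME" %in% s) || all(c("L1", "TIME") %in% s)
  })
  specs <- purrr::map(ok, model_spec, random = full$random)
  labels <- purrr::map_chr(specs, format)
  specs[order(lengths(purrr::map(specs, "terms")), labels)]
}

#' Build the numeric design matrix for a model specification
#'
#' Assembles the response vector and fixed-effect design matrix (intercept
#' plus one column per term) from a prepared growth dataset. The interaction
#' column is the elementwise product of the standardized `L1` and `TIME`
#' columns. Rows lacking a required lag-2 predictor are dropped with a
#' reported count.
#'
#' @param spec A `model_spec`.
#' @param dataset A `growth_dataset` from [prepare_predictors()].
#' @return An object of class `dd_design`: a list with elements `y` (response),
#'   `X` (numeric matrix with named columns), `groups` (factor of site labels,
#'   or `NULL`), `spec`, and `n` (rows retained).
#' @export
build_design <- function(spec, dataset) {
  stopifnot(inherits(spec, "model_spec"))
  col_for <- c(L1 = "lag1", L2 = "lag2", TIME = "time")
  needed <- col_for[intersect(spec$terms, names(col_for))]
  missing <- setdiff(needed, names(dataset))
  if (length(missing) > 0) {
    stop("dataset lacks predictor column(s) for term(s): ",
         paste(names(needed)[needed %in% missing], collapse = ", "),
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(dataset))
  for (cl in needed) keep <- keep & !is.na(dataset[[cl]])
  if (any(!keep)) {
    message(sum(!keep), " observation(s) dropped: missing lag predictor")
  }
  d <- dataset[keep, , drop = FALSE]
  X <- matrix(1, nrow = nrow(d), ncol = 1, dimnames = list(NULL, "(Intercept)"))
  for (term in spec$terms) {
    col <- if (term == "L1:TIME") d$lag1 * d$time else d[[col_for[[term]]]]
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- term
  }
  groups <- NULL
  if (!is.null(spec$random)) {
    if (!"site" %in% names(d)) {
      stop("dataset has no 'site' column for random-intercept grouping",
           call. = FALSE)
    }
    groups <- factor(d$site)
  }
  structure(list(y = d$response, X = X, groups = groups, spec = spec,
                 n = nrow(d)),
            class = "dd_design")
}
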