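# Model specifications: outcome, predictor set with per-predictor transforms,
# and model family. The design matrix always carries an intercept first.

#' Specify a regression model
#'
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names (may be empty
#'   for an intercept-only model).
#' @param transforms Named character vector mapping predictor names to
#'   `"identity"` or `"sqrt"`; unnamed predictors default to identity. The
#'   square-root transform is only legal on nonnegative columns.
#' @param family One of `"beta"` (logit mean link, constant precision),
#'   `"robust_linear"` (Huber M-estimation) or `"ols"`.
#' @param percent Is the outcome stored in percent? If `TRUE` it is divided
#'   by 100 before fitting (required for the beta family, whose response must
#'   lie strictly inside (0, 1)), and predictions are returned on the same
#'   proportion scale.
#' @return Object of class `sc_model_spec`.
#' @export
model_spec <- function(outcome, predictors = character(),
                       transforms = NULL,
                       family = c("beta", "robust_linear", "ols"),
                       percent = FALSE) {
  family <- match.arg(family)
  tr <- setNames(rep("identity", length(predictors)), predictors)
  if (!is.null(transforms)) {
    unknown <- setdiff(names(transforms), predictors)
    if (length(unknown) > 0)
      stop("transform given for non-predictor column(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    bad <- setdiff(transforms, c("identity", "sqrt"))
    if (length(bad) > 0)
      stop("unsupported transform(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    tr[names(transforms)] <- transforms
  }
  structure(list(outcome = outcome, predictors = predictors,
                 transforms = tr, family = family, percent = percent),
            class = "sc_model_spec")
}

#' @export
print.sc_model_spec <- function(x, ...) {
  lab <- vapply(x$predictors, function(p)
    if (x$transforms[[p]] == "sqrt") paste0("sqrt(", p, ")") else p,
    character(1))
  cat(x$family, " model: ", x$outcome, " ~ ",
      if (length(lab) == 0) "1" else paste(lab, collapse = " + "),
      if (x$percent) "   [percent outcome]" else "", "\n", sep = "")
  invisible(x)
}

# Design matrix (intercept first) and outcome on the fitting scale.
build_design <- function(spec, data, need_outcome = TRUE) {
  n <- nrow(data)
  cols <- lapply(spec$predictors, function(p) {
    v <- data[[p]]
    if (is.null(v)) stop("predictor column not found: ", p, call. = FALSE)
    if (spec$transforms[[p]] == "sqrt") {
      if (any(v < 0, na.rm = TRUE))
        stop("sqrt transform on negative values in column ", p, call. = FALSE)
      v <- sqrt(v)
    }
    v
  })
  X <- cbind(`(Intercept)` = rep(1, n))
  if (length(cols) > 0) {
    M <- do.call(cbind, cols)
    colnames(M) <- vapply(spec$predictors, function(p)
      if (spec$transforms[[p]] == "sqrt") paste0("sqrt(", p, ")") else p,
      character(1))
    X <- cbind(X, M)
  }
  y <- NULL
  if (need_outcome) {
    y <- data[[spec$outcome]]
    if (is.null(y)) stop("outcome column not found: ", spec$outcome,
                         call. = FALSE)
    if (spec$percent) y <- y / 100
  }
  list(X = X, y = y)
}

drop_predictor <- function(spec, predictor) {
  keep <- setdiff(spec$predictors, predictor)
  model_spec(spec$outcome, keep,
             transforms = spec$transforms[intersect(names(spec$transforms), keep)],
             family = spec$family, percent = spec$percent)
}

#' Fit a model according to its specification
#'
#' Dispatches to [fit_beta()], [fit_robust_linear()] or [fit_ols()].
#'
#' @param spec A [model_spec()].
#' @param data City-level data frame.
#' @return An `sc_fit` object.
#' @export
fit_model <- function(spec, data) {
  switch(spec$family,
         beta = fit_beta(spec, data),
         robust_linear = fit_robust_linear(spec, data),
         ols = fit_ols(spec, data))
}

new_fit <- function(spec, coefficients, fitted, residuals, converged,
                    iterations, X, y, vcov = NULL, phi = NULL, sigma = NULL,
                    loglik = NULL) {
  structure(list(spec = spec, coefficients = coefficients, fitted = fitted,
                 residuals = residuals, converged = converged,
                 iterations = iterations, X = X, y = y, vcov = vcov,
                 phi = phi, sigma = sigma, loglik = loglik),
            class = "sc_fit")
}

#' @export
coef.sc_fit <- function(object, ...) object$coefficients

#' @export
print.sc_fit <- function(x, ...) {
  print(x$spec)
  cat("coefficients:\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$phi)) cat("precision phi:", signif(x$phi, 5), "\n")
  if (!is.null(x$sigma)) cat("scale sigma:", signif(x$sigma, 5), "\n")
  cat("converged:", x$converged, "in", x$iterations, "iterations\n")
  invisible(x)
}

#' Predict from a fitted model
#'
#' Applies the spec's transforms to `newdata`, forms the linear predictor and
#' inverts the link: logistic for the beta family (predictions strictly in
#' (0, 1)), identity for the linear families. Linear-family predictions are
#' deliberately not clamped.
#'
#' @param object An `sc_fit`.
#' @param newdata Data frame of new city rows.
#' @param ... Unused.
#' @return Numeric vector of response-scale predictions.
#' @export
predict.sc_fit <- function(object, newdata, ...) {
  X <- build_design(object$spec, newdata, need_outcome = FALSE)$X
  eta <- drop(X %*% object$coefficients)
  if (object$spec$family == "beta") plogis(eta) else eta
}

# Wald p-values for the regression coefficients (normal reference for the
# beta and robust families, t for OLS).
wald_pvalues <- function(fit) {
  se <- sqrt(diag(fit$vcov))[seq_along(fit$coefficients)]
  z <- fit$coefficients / se
  if (fit$spec$family == "ols") {
    df <- length(fit$y) - length(fit$coefficients)
    2 * stats::pt(-abs(z), df = df)
  } else {
    2 * stats::pnorm(-abs(z))
  }
}
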