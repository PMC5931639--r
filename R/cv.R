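# Leave-one-out cross-validation, PRESS and absolute-error summaries,
# Pearson feature screening, maximal-model construction, and the
# significance-guided PRESS-minimising backward elimination.

#' Leave-one-out cross-validation of a fixed model specification
#'
#' Each city is predicted from a model fitted to the remaining n - 1 cities;
#' the specification is held fixed across folds (selection is not nested).
#' PRESS is the exact sum of squared held-out errors on the response scale;
#' MAE and MDAE are the mean and median absolute held-out errors. For the
#' beta family, standardised held-out errors (logit scale, variance from the
#' trigamma function) are summarised as mean and median absolute values.
#'
#' @param spec A [model_spec()].
#' @param data City-level data frame with at least 3 rows.
#' @return An object of class `sc_cv`: list with `predictions` (data frame of
#'   per-city observed/predicted/converged), `press`, `mae`, `mdae`, and for
#'   the beta family `mse_std`, `mdse_std`. Non-convergent folds are flagged
#'   and excluded from the summaries with a warning.
#' @export
loocv <- function(spec, data) {
  n <- nrow(data)
  if (n < 3) stop("LOOCV needs at least 3 cities", call. = FALSE)
  obs <- data[[spec$outcome]]
  if (spec$percent) obs <- obs / 100
  pred <- rep(NA_real_, n)
  conv <- rep(FALSE, n)
  std_err <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      withCallingHandlers(
        fit_model(spec, data[-i, , drop = FALSE]),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit)) next
    pred[i] <- predict(fit, data[i, , drop = FALSE])
    conv[i] <- fit$converged
    if (spec$family == "beta" && fit$converged)
      std_err[i] <- beta_heldout_std_error(obs[i], pred[i], fit$phi)
  }
  if (!all(conv))
    warning(sum(!conv), " non-convergent fold(s); summaries use the ",
            sum(conv), " converged folds", call. = FALSE)
  ok <- conv
  err <- obs - pred
  res <- list(
    predictions = data.frame(
      city = if (!is.null(data$city_id)) data$city_id else seq_len(n),
      observed = obs, predicted = pred, converged = conv),
    press = sum(err[ok]^2),
    mae = mean(abs(err[ok])),
    mdae = stats::median(abs(err[ok])),
    n = n
  )
  if (spec$family == "beta") {
    res$mse_std <- mean(abs(std_err[ok]))
    res$mdse_std <- stats::median(abs(std_err[ok]))
  }
  structure(res, class = "sc_cv")
}

#' @export
print.sc_cv <- function(x, ...) {
  cat("LOOCV over", x$n, "cities\n")
  cat("  PRESS:", signif(x$press, 5), "  MAE:", signif(x$mae, 4),
      "  MDAE:", signif(x$mdae, 4), "\n")
  if (!is.null(x$mse_std))
    cat("  MSR:", signif(x$mse_std, 4), "  MDSR:", signif(x$mdse_std, 4), "\n")
  invisible(x)
}

#' Pearson correlation matrix over pairwise-complete observations
#'
#' @param data City-level data frame.
#' @param cols Columns to include (default: all numeric columns).
#' @return Symmetric correlation matrix with unit diagonal; zero-variance
#'   columns get `NA` in their whole row and column.
#' @export
correlation_matrix <- function(data, cols = NULL) {
  if (is.null(cols))
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  M <- as.matrix(data[cols])
  suppressWarnings(R <- stats::cor(M, use = "pairwise.complete.obs"))
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  degenerate <- !is.na(sds) & sds == 0
  R[degenerate, ] <- NA_real_
  R[, degenerate] <- NA_real_
  diag(R)[!degenerate] <- 1
  R
}

#' Build the maximal model for an outcome
#'
#' Includes every mode-count feature whose absolute Pearson correlation with
#' the outcome is at least `r_min`, plus every monthly-proportion variable
#' whose largest absolute correlation with any mode-count feature is at least
#' `r_min` ("months correlated with the imagery outputs").
#'
#' @param outcome Outcome column name.
#' @param data City-level data frame.
#' @param family Model family for the resulting spec.
#' @param gsv_cols Candidate mode-count features.
#' @param month_cols Candidate monthly-proportion variables.
#' @param r_min Screening threshold for "near-zero" correlation.
#' @param transforms Optional transforms passed through to the spec.
#' @param percent Percent-outcome flag passed through to the spec.
#' @return A [model_spec()]; intercept-only (with a warning) if no predictor
#'   survives screening.
#' @export
build_maximal_spec <- function(outcome, data,
                               family = "beta",
                               gsv_cols = gsv_predictor_cols(),
                               month_cols = gsv_month_cols(),
                               r_min = 0.1,
                               transforms = NULL,
                               percent = FALSE) {
  month_cols <- intersect(month_cols, names(data))
  R <- correlation_matrix(data, cols = unique(c(outcome, gsv_cols, month_cols)))
  keep_gsv <- gsv_cols[!is.na(R[outcome, gsv_cols]) &
                         abs(R[outcome, gsv_cols]) >= r_min]
  keep_month <- month_cols[vapply(month_cols, function(mc) {
    r <- abs(R[mc, gsv_cols])
    any(!is.na(r) & r >= r_min)
  }, logical(1))]
  predictors <- c(keep_gsv, keep_month)
  if (length(predictors) == 0)
    warning("no predictor survives correlation screening; intercept-only model",
            call. = FALSE)
  tr <- if (!is.null(transforms))
    transforms[intersect(names(transforms), predictors)] else NULL
  model_spec(outcome, predictors, transforms = tr, family = family,
             percent = percent)
}

#' Sequential PRESS-minimising backward elimination
#'
#' Starting from a maximal specification, repeatedly considers the least
#' statistically significant predictor (largest Wald p-value above `alpha`):
#' if removing it lowers the LOOCV PRESS, the removal is accepted and the
#' search restarts; otherwise the next-least-significant candidate is tried.
#' The process stops when no candidate removal lowers PRESS (or no predictor
#' has p-value above `alpha`). Candidates with numerically tied p-values are
#' tried in the order of larger PRESS reduction.
#'
#' @param maximal A [model_spec()] to start from.
#' @param data City-level data frame.
#' @param alpha Significance threshold defining "low statistical significance".
#' @return List of class `sc_selection`: `final` spec, `final_press`,
#'   `final_cv`, and `trace` — a data frame of attempted removals with
#'   p-value, PRESS before/after and the accepted flag. Every accepted step
#'   strictly reduced PRESS.
#' @export
sequential_elimination <- function(maximal, data, alpha = 0.05) {
  current <- maximal
  cv <- suppressWarnings(loocv(current, data))
  press <- cv$press
  trace <- list()
  repeat {
    if (length(current$predictors) == 0) break
    fit <- tryCatch(suppressWarnings(fit_model(current, data)),
                    error = function(e) NULL)
    if (is.null(fit)) break
    p <- wald_pvalues(fit)[-1]  # drop intercept
    names(p) <- current$predictors
    cand <- names(sort(p[p > alpha], decreasing = TRUE))
    if (length(cand) == 0) break
    # evaluate candidates lazily in decreasing-p order; numeric p ties are
    # broken by the larger PRESS reduction
    tied <- abs(p[cand] - p[cand[1]]) < 1e-12
    if (sum(tied) > 1) {
      presses <- vapply(cand[tied], function(nm)
        suppressWarnings(loocv(drop_predictor(current, nm), data))$press,
        numeric(1))
      cand <- c(names(sort(presses)), cand[!tied])
    }
    accepted <- FALSE
    for (nm in cand) {
      spec2 <- drop_predictor(current, nm)
      cv2 <- suppressWarnings(loocv(spec2, data))
      trace[[length(trace) + 1]] <- data.frame(
        removed = nm, p_value = unname(p[nm]), press_before = press,
        press_after = cv2$press, accepted = cv2$press < press)
      if (cv2$press < press) {
        current <- spec2; press <- cv2$press; cv <- cv2
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  structure(list(final = current, final_press = press, final_cv = cv,
                 trace = if (length(trace) > 0) do.call(rbind, trace)
                 else data.frame(removed = character(), p_value = numeric(),
                                 press_before = numeric(),
                                 press_after = numeric(),
                                 accepted = logical())),
            class = "sc_selection")
}

#' The ten final model specifications
#'
#' The published specifications for the four commute-share outcomes (beta),
#' the four past-month prevalence outcomes (beta), and the two days-per-week
#' outcomes (robust linear for utility cycling, OLS for utility walking).
#' The cycle-share model uses the square root of the cyclist count; monthly
#' proportions enter on the percent scale.
#'
#' @return Named list of [model_spec()] objects `M1` ... `M10`.
#' @export
final_model_specs <- function() {
  list(
    M1 = model_spec("Census_PTWalk", c("GSV_Cycle", "GSV_Bus", "GSV_Mar"),
                    family = "beta", percent = TRUE),
    M2 = model_spec("Census_Cycle", "GSV_Cycle",
                    transforms = c(GSV_Cycle = "sqrt"),
                    family = "beta", percent = TRUE),
    M3 = model_spec("Census_MC", c("GSV_Cycle", "GSV_MC", "GSV_Bus"),
                    family = "beta", percent = TRUE),
    M4 = model_spec("Census_Car", c("GSV_Cycle", "GSV_Bus", "GSV_Mar"),
                    family = "beta", percent = TRUE),
    M5 = model_spec("APS_Prev_All_Cycle", c("GSV_Cycle", "GSV_Bus"),
                    family = "beta", percent = TRUE),
    M6 = model_spec("APS_Prev_Utly_Cycle", c("GSV_Walk", "GSV_Cycle"),
                    family = "beta", percent = TRUE),
    M7 = model_spec("APS_Prev_All_Walk", c("GSV_Cycle", "GSV_Feb", "GSV_Mar"),
                    family = "beta", percent = TRUE),
    M8 = model_spec("APS_Prev_Utly_Walk", "GSV_Cycle",
                    family = "beta", percent = TRUE),
    M9 = model_spec("APS_Days_Utly_Cycle", "GSV_Cycle",
                    family = "robust_linear"),
    M10 = model_spec("APS_Days_Utly_Walk", "GSV_Walk", family = "ols")
  )
}

#' Fit the ten final models and assemble a report table
#'
#' Fits each published specification on the full data and evaluates it by
#' LOOCV. Survey-outcome models are restricted to cities with the survey
#' block; if no such city exists, only the four commute-share models are
#' fitted.
#'
#' @param data City-level data frame (features merged with outcomes; an
#'   optional `aps_available` logical column restricts the survey models).
#' @return List of class `sc_final_models` with `fits`, `cv` (per-model
#'   [loocv()] results) and `table` (one row per model: outcome, family,
#'   n, MAE, MDAE, MSR, MDSR, PRESS).
#' @export
fit_final_models <- function(data) {
  specs <- final_model_specs()
  aps_ok <- if (!is.null(data$aps_available)) data$aps_available
  else rep(TRUE, nrow(data))
  fits <- list(); cvs <- list(); rows <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    d <- if (startsWith(spec$outcome, "APS_"))
      data[aps_ok & !is.na(data[[spec$outcome]]), , drop = FALSE] else data
    if (nrow(d) < 3) next
    fit <- tryCatch(suppressWarnings(fit_model(spec, d)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      # a degenerate design (e.g. a month column with no images in any
      # city) makes the published spec inestimable on this dataset
      rows[[nm]] <- data.frame(
        model = nm, outcome = spec$outcome, family = spec$family,
        n = nrow(d), converged = FALSE, MAE = NA_real_, MDAE = NA_real_,
        MSR = NA_real_, MDSR = NA_real_, PRESS = NA_real_,
        note = conditionMessage(fit))
      next
    }
    cv <- suppressWarnings(loocv(spec, d))
    fits[[nm]] <- fit
    cvs[[nm]] <- cv
    rows[[nm]] <- data.frame(
      model = nm, outcome = spec$outcome, family = spec$family,
      n = nrow(d), converged = fit$converged,
      MAE = cv$mae, MDAE = cv$mdae,
      MSR = if (!is.null(cv$mse_std)) cv$mse_std else NA_real_,
      MDSR = if (!is.null(cv$mdse_std)) cv$mdse_std else NA_real_,
      PRESS = cv$press, note = "")
  }
  structure(list(fits = fits, cv = cvs, table = do.call(rbind, rows)),
            class = "sc_final_models")
}

#' @export
print.sc_final_models <- function(x, ...) {
  cat("Final regression models\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' R-squared of a simple linear relationship, optionally on the log scale
#'
#' Squared Pearson correlation between two city-level variables; with
#' `log = TRUE` both are log-transformed first, the convention used for
#' right-skewed cycling variables dominated by a few high-cycling cities.
#'
#' @param x,y Numeric vectors (strictly positive when `log = TRUE`).
#' @param log Use log-transformed variables?
#' @return The R-squared value.
#' @export
linear_r2 <- function(x, y, log = FALSE) {
  if (log) {
    if (any(x <= 0 | y <= 0))
      stop("log-scale R-squared needs strictly positive values", call. = FALSE)
    x <- base::log(x); y <- base::log(y)
  }
  stats::cor(x, y)^2
}
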