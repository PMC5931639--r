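# Beta regression with a logit mean link and a single constant precision,
# estimated by maximum likelihood in the mean-precision parameterisation:
#   y ~ Beta(mu * phi, (1 - mu) * phi),  logit(mu) = x' beta,  phi > 0.

#' Beta log-likelihood in the mean-precision parameterisation
#'
#' Density f(y; mu, phi) = Gamma(phi) / (Gamma(mu phi) Gamma((1-mu) phi)) *
#' y^(mu phi - 1) (1-y)^((1-mu) phi - 1), with logit(mu) = X beta.
#'
#' @param y Responses strictly inside (0, 1).
#' @param X Design matrix (intercept included).
#' @param beta Coefficient vector on the logit scale.
#' @param phi Positive precision.
#' @return The log-likelihood (a finite scalar).
#' @export
beta_loglik <- function(y, X, beta, phi) {
  if (any(y <= 0 | y >= 1))
    stop("beta regression requires responses strictly inside (0, 1); ",
         "apply the boundary squeeze y' = (y*(n-1) + 0.5)/n first",
         call. = FALSE)
  if (phi <= 0) stop("precision 'phi' must be positive", call. = FALSE)
  eta <- pmin(30, pmax(-30, drop(X %*% beta)))
  mu <- plogis(eta)
  sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
        (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log(1 - y))
}

#' Squeeze boundary proportions into the open unit interval
#'
#' `y' = (y * (n - 1) + 0.5) / n`, applied only when boundary values occur.
#'
#' @param y Proportions in `[0, 1]`.
#' @return Proportions in `(0, 1)`.
#' @export
boundary_squeeze <- function(y) {
  if (any(y <= 0 | y >= 1)) {
    n <- length(y)
    (y * (n - 1) + 0.5) / n
  } else y
}

# Gradient of the log-likelihood wrt (beta, log phi).
beta_loglik_grad <- function(y, X, beta, phi) {
  eta <- pmin(30, pmax(-30, drop(X %*% beta)))
  mu <- plogis(eta)
  ystar <- qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gbeta <- phi * drop(crossprod(X, (ystar - mustar) * mu * (1 - mu)))
  gphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                (1 - mu) * digamma((1 - mu) * phi) +
                mu * log(y) + (1 - mu) * log(1 - y))
  c(gbeta, gphi * phi)  # chain rule for the log-phi parameterisation
}

#' Fit a beta regression by maximum likelihood
#'
#' Maximises the beta log-likelihood over (beta, log phi) by quasi-Newton
#' (BFGS) with an analytic gradient. Starting values are OLS on logit(y) for
#' the coefficients and a method-of-moments estimate for the precision. The
#' `converged` flag is honest: non-convergence returns the best iterate with
#' `converged = FALSE` and a warning.
#'
#' @param spec A [model_spec()] with `family = "beta"`.
#' @param data City-level data frame; the outcome must lie strictly in (0, 1)
#'   after any percent conversion.
#' @param max_iter Iteration cap for the optimiser.
#' @return An `sc_fit` with coefficients, precision `phi`, fitted means,
#'   response residuals, log-likelihood and a Wald covariance matrix for
#'   (beta, log phi).
#' @export
fit_beta <- function(spec, data, max_iter = 500) {
  d <- build_design(spec, data)
  X <- d$X; y <- d$y
  if (any(y <= 0 | y >= 1))
    stop("outcome '", spec$outcome,
         "' must be strictly inside (0, 1) after percent conversion; ",
         "see boundary_squeeze()", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix", call. = FALSE)
  z <- qlogis(y)
  b0 <- qr.solve(X, z)
  # method-of-moments start for phi from the logit-scale residual variance
  e <- z - drop(X %*% b0)
  s2 <- sum(e^2) / max(1, length(y) - ncol(X))
  mu0 <- plogis(drop(X %*% b0))
  phi0 <- max(0.5, mean(1 / (s2 * mu0 * (1 - mu0))) - 1)
  start <- c(b0, log(phi0))
  negll <- function(par) {
    -beta_loglik(y, X, par[-length(par)], exp(par[length(par)]))
  }
  neggr <- function(par) {
    -beta_loglik_grad(y, X, par[-length(par)], exp(par[length(par)]))
  }
  opt <- stats::optim(start, negll, neggr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12),
                      hessian = TRUE)
  k <- ncol(X)
  beta <- opt$par[seq_len(k)]
  names(beta) <- colnames(X)
  phi <- unname(exp(opt$par[k + 1]))
  grad_norm <- sqrt(sum(neggr(opt$par)^2))
  converged <- opt$convergence == 0 && grad_norm < 1e-3 * (1 + abs(opt$value))
  if (!converged)
    warning("beta regression did not converge (gradient norm ",
            signif(grad_norm, 3), ")", call. = FALSE)
  vcov <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, k + 1, k + 1)
  })
  dimnames(vcov) <- list(c(colnames(X), "log(phi)"),
                         c(colnames(X), "log(phi)"))
  mu <- plogis(drop(X %*% beta))
  new_fit(spec, beta, fitted = mu, residuals = y - mu,
          converged = converged, iterations = opt$counts[["function"]],
          X = X, y = y, vcov = vcov, phi = phi, loglik = -opt$value)
}

#' Standardised weighted residuals for a beta regression
#'
#' The diagnostic residual on the logit scale:
#' r_t = (y*_t - mu*_t) / sqrt(v_t (1 - h_tt)) with y* = logit(y),
#' mu* = psi(mu phi) - psi((1 - mu) phi), v = psi'(mu phi) + psi'((1-mu) phi)
#' (psi the digamma, psi' the trigamma), and h_tt the leverage from the
#' weighted hat matrix with weights phi * v * (mu (1 - mu))^2.
#'
#' @param fit A converged beta-family `sc_fit`.
#' @return Numeric vector of standardised residuals; observations with
#'   leverage >= 1 are returned as `NA` with attribute `high_leverage` giving
#'   their indices.
#' @export
beta_std_residuals <- function(fit) {
  stopifnot(fit$spec$family == "beta")
  if (!fit$converged)
    stop("standardised residuals require a converged fit", call. = FALSE)
  X <- fit$X; y <- fit$y; phi <- fit$phi
  mu <- fit$fitted
  ystar <- qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  v <- trigamma(mu * phi) + trigamma((1 - mu) * phi)
  w <- phi * v * (mu * (1 - mu))^2
  sw <- sqrt(w)
  Xw <- X * sw
  H <- Xw %*% solve(crossprod(Xw)) %*% t(Xw)
  h <- pmin(diag(H), 1)
  high <- which(h >= 1 - 1e-12)
  r <- (ystar - mustar) / sqrt(v * (1 - h))
  r[high] <- NA_real_
  attr(r, "high_leverage") <- high
  r
}

# Held-out standardised error for a beta prediction: the test point is not in
# the training hat matrix, so no leverage term applies.
beta_heldout_std_error <- function(obs, mu, phi) {
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  v <- trigamma(mu * phi) + trigamma((1 - mu) * phi)
  (qlogis(obs) - mustar) / sqrt(v)
}
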