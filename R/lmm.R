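#' Random-intercept linear mixed model by profiled maximum likelihood
#'
#' Fits y = b0 + b1 x + a_g + e with a_g ~ N(0, sigma_a^2) per group
#' (animal / donor / classifier) and e ~ N(0, sigma_e^2), by maximum
#' likelihood. Because measurements from the same animal share its
#' idiosyncrasies, treating cells as independent inflates false positives
#' for any predictor that is constant within animals (such as a genotype
#' label); the random intercept absorbs that shared variation.
#'
#' The likelihood is profiled analytically down to a one-dimensional
#' optimization over the variance ratio lambda = sigma_a^2 / sigma_e^2:
#' for fixed lambda the GLS estimate of the fixed effects and the residual
#' variance are closed-form (the per-group inverse of I + lambda * J is
#' I - lambda / (1 + n_g * lambda) * J), and lambda is optimized on a log
#' scale with the lambda = 0 boundary checked explicitly. The p-value for
#' the predictor is a likelihood-ratio chi-square test (df = 1) against
#' the model without x, both fitted by ML (REML logliks are not comparable
#' across fixed-effect structures).
#'
#' With a single group the random intercept is unidentifiable and the fit
#' falls back to ordinary least squares with a warning.
#'
#' @param y Numeric response vector (e.g. per-cell component scores).
#' @param x Numeric or 0/1 predictor vector, or `NULL` for the
#'   intercept-only null model.
#' @param groups Grouping vector (coerced to factor), same length as `y`.
#' @return An object of class `lmm_fit` with elements `beta_fixed`,
#'   `sigma_a2`, `sigma_e2`, `lambda`, `loglik`, `loglik_null`, `p_value`,
#'   `n`, `n_groups`.
#' @export
fit_random_intercept_lmm <- function(y, x = NULL, groups) {
  y <- as.numeric(y)
  g <- factor(groups)
  n <- length(y)
  if (length(g) != n) abort("`groups` must have the same length as `y`.")
  if (!is.null(x)) {
    x <- as.numeric(x)
    if (length(x) != n) abort("`x` must have the same length as `y`.")
    if (sd(x) == 0) abort("Singular design: `x` is constant.")
    X <- cbind(`(Intercept)` = 1, x = x)
  } else {
    X <- cbind(`(Intercept)` = rep(1, n))
  }
  if (nlevels(g) < 2L) {
    warn("Only one group: falling back to ordinary least squares.")
    fit <- lmm_profile_fit(y, X, g, lambda = 0)
  } else {
    fit <- lmm_optimize(y, X, g)
  }

  loglik_null <- NA_real_
  p_value <- NA_real_
  if (!is.null(x)) {
    X0 <- cbind(`(Intercept)` = rep(1, n))
    fit0 <- if (nlevels(g) < 2L) {
      lmm_profile_fit(y, X0, g, lambda = 0)
    } else {
      lmm_optimize(y, X0, g)
    }
    loglik_null <- fit0$loglik
    lrt <- max(0, 2 * (fit$loglik - loglik_null))
    p_value <- pchisq(lrt, df = 1L, lower.tail = FALSE)
  }

  structure(
    list(
      beta_fixed = fit$beta, sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2,
      lambda = fit$lambda, loglik = fit$loglik, loglik_null = loglik_null,
      p_value = p_value, n = n, n_groups = nlevels(g)
    ),
    class = "lmm_fit"
  )
}

# Profiled ML at a fixed variance ratio lambda. Group sums make every
# quantity O(n): V_g^{-1} = I - lambda/(1 + n_g lambda) * J.
lmm_profile_fit <- function(y, X, g, lambda) {
  n <- length(y)
  ng <- tabulate(g)
  cg <- lambda / (1 + ng * lambda)           # per-group shrinkage
  Xg <- rowsum(X, g)                          # group column sums
  yg <- rowsum(y, g)[, 1L]
  A <- crossprod(X) - crossprod(Xg * sqrt(cg))
  b <- drop(crossprod(X, y)) - drop(crossprod(Xg, cg * yg))
  beta <- drop(solve(A, b))
  e <- y - drop(X %*% beta)
  eg <- rowsum(e, g)[, 1L]
  rss_v <- sum(e^2) - sum(cg * eg^2)
  sigma_e2 <- rss_v / n
  logdet <- sum(log1p(ng * lambda))
  loglik <- -0.5 * (n * (log(2 * pi) + log(sigma_e2) + 1) + logdet)
  list(
    beta = setNames(beta, colnames(X)), lambda = lambda,
    sigma_e2 = sigma_e2, sigma_a2 = lambda * sigma_e2, loglik = loglik
  )
}

lmm_optimize <- function(y, X, g) {
  obj <- function(loglam) -lmm_profile_fit(y, X, g, exp(loglam))$loglik
  opt <- optimize(obj, interval = c(-12, 12), tol = 1e-8)
  cand <- list(
    lmm_profile_fit(y, X, g, exp(opt$minimum)),
    lmm_profile_fit(y, X, g, 0)
  )
  cand[[which.max(map_dbl(cand, "loglik"))]]
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> random-intercept linear mixed model (ML)\n")
  print(round(x$beta_fixed, 4))
  cat(sprintf("sigma_a^2 = %.4g, sigma_e^2 = %.4g, loglik = %.3f\n",
              x$sigma_a2, x$sigma_e2, x$loglik))
  if (!is.na(x$p_value)) cat(sprintf("LRT p (predictor) = %.3g\n", x$p_value))
  invisible(x)
}

#' @describeIn fit_random_intercept_lmm Coefficient tibble.
#' @param x An `lmm_fit`.
#' @param ... Unused.
#' @export
tidy.lmm_fit <- function(x, ...) {
  tibble(term = names(x$beta_fixed), estimate = unname(x$beta_fixed))
}

#' @describeIn fit_random_intercept_lmm One-row model summary.
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble(
    sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2, loglik = x$loglik,
    p_value = x$p_value, n = x$n, n_groups = x$n_groups
  )
}
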