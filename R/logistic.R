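#' L2-penalized logistic regression by iteratively reweighted least squares
#'
#' The label-dependent linear classifier: cells labeled by tissue origin
#' (disease-mutant vs control) and fitted on standardized measurements.
#' Maximizes the log-likelihood minus `lambda / 2 * sum(beta_j^2)` with the
#' intercept unpenalized, by damped Newton (IRLS) steps until the
#' penalized-gradient max-norm drops below `tol`. On standardized inputs
#' the coefficient magnitudes are comparable across measurements, which is
#' what the downstream contribution decomposition relies on.
#'
#' @param x Numeric matrix, cells x measurements (standardized).
#' @param y 0/1 labels (1 = disease origin / sick).
#' @param lambda L2 penalty strength (>= 0). With `lambda = 0` and
#'   separable data the optimum does not exist and the fit aborts after
#'   `max_iter` with an actionable error.
#' @param max_iter,tol Newton iteration cap and gradient tolerance.
#' @return An object of class `lr_model`: `beta` (intercept first, then
#'   one coefficient per measurement), `lambda`, `n_iter`, `feature_names`.
#' @export
fit_logistic <- function(x, y, lambda = 1, max_iter = 100L, tol = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("`y` must be 0/1 labels.")
  if (length(unique(y)) < 2L) abort("Both classes must be present.")
  if (nrow(x) != length(y)) abort("`x` and `y` lengths differ.")
  n <- nrow(x); p <- ncol(x)
  X <- cbind(1, x)
  pen <- c(0, rep(lambda, p))
  beta <- numeric(p + 1L)

  pll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta))) - sum(pen * b^2) / 2
  }
  obj <- pll(beta)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    if (max(abs(grad)) < tol) {
      # with no penalty, a vanishing gradient can also mean diverging
      # coefficients on separated classes (every fitted probability
      # saturated at its label), in which case no finite maximum exists
      if (lambda == 0 && all((2 * y - 1) * eta > -log(1e-6))) break
      return(new_lr_model(beta, lambda, iter - 1L, colnames(x)))
    }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    step <- solve(H, grad)
    # damped Newton: halve until the penalized log-likelihood improves
    t <- 1
    repeat {
      cand <- beta + t * step
      if (pll(cand) >= obj - 1e-12 || t < 1e-8) break
      t <- t / 2
    }
    beta <- beta + t * step
    obj <- pll(beta)
  }
  eta <- drop(X %*% beta)
  grad <- drop(crossprod(X, y - plogis(eta))) - pen * beta
  separated <- lambda == 0 && all((2 * y - 1) * eta > -log(1e-6))
  if (max(abs(grad)) < tol && !separated) {
    return(new_lr_model(beta, lambda, max_iter, colnames(x)))
  }
  abort(paste(
    "Logistic regression did not converge;",
    "with lambda = 0 and separable classes no finite optimum exists -",
    "set lambda > 0."
  ))
}

new_lr_model <- function(beta, lambda, n_iter, feature_names) {
  feature_names <- feature_names %||% paste0("x", seq_along(beta[-1]))
  structure(
    list(
      beta = setNames(beta, c("(Intercept)", feature_names)),
      lambda = lambda, n_iter = n_iter, feature_names = feature_names
    ),
    class = "lr_model"
  )
}

#' @export
print.lr_model <- function(x, ...) {
  cat(sprintf("<lr_model> L2 logistic regression (lambda = %g, %d features)\n",
              x$lambda, length(x$feature_names)))
  invisible(x)
}

#' @describeIn fit_logistic Coefficient tibble (term, estimate).
#' @param x An `lr_model`.
#' @param ... Unused.
#' @export
tidy.lr_model <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta))
}
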