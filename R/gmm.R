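#' Two-component Gaussian mixture on selected principal components
#'
#' The label-independent subpopulation detector: cells are modeled as a
#' mixture of two multivariate Gaussians ("healthy" and "sick") in the
#' space of 1-3 disease-associated principal components. Fitted by EM with
#' full covariances, a small ridge on each covariance for numerical
#' stability, and `n_init` seeded k-means++-style restarts (best final
#' log-likelihood wins), so the fit is deterministic given `seed`.
#'
#' Condition labels play no role in fitting; they are only consulted
#' afterwards by [orient_sick_component()] to decide which mixture
#' component represents sick cells.
#'
#' @param scores Numeric matrix, cells x selected components (1-3 columns).
#' @param k Number of mixture components (2).
#' @param n_init Number of seeded restarts.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   falls below `tol` (absolute) or after `max_iter` iterations.
#' @param ridge Ridge added to covariance diagonals each M-step.
#' @param seed Integer seed for the restart stream.
#' @param pc_indices Optional component indices the columns correspond to
#'   (recorded for downstream contribution analysis).
#' @return An object of class `gmm_model`: `weights`, `means` (k x d),
#'   `covariances` (d x d x k), `loglik_trace`, `responsibilities`,
#'   `assignments`, `sick_component` (NA until oriented), `pc_indices`.
#' @export
fit_gmm <- function(scores, k = 2L, n_init = 10L, max_iter = 500L,
                    tol = 1e-6, ridge = 1e-6, seed = 0L, pc_indices = NULL) {
  x <- as.matrix(scores)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) abort("Non-finite values in `scores`.")
  n <- nrow(x); d <- ncol(x)
  if (n < 10L) abort("GMM fitting needs at least 10 cells.")
  if (d < 1L || d > 3L) abort("GMM is fitted on 1-3 selected components.")
  if (all(apply(x, 2L, sd) == 0)) abort("All points identical; mixture is degenerate.")

  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- with_private_seed(seed * 1000L + i, gmm_em_once(x, k, max_iter, tol, ridge))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (best$degenerate) {
    warn("Near-singular covariance encountered; fit is ridge-regularized and flagged.")
  }
  structure(
    list(
      weights = best$weights, means = best$means, covariances = best$covs,
      loglik = best$loglik, loglik_trace = best$trace,
      responsibilities = best$resp,
      assignments = max.col(best$resp),
      sick_component = NA_integer_,
      pc_indices = pc_indices, n = n, d = d,
      degenerate = best$degenerate,
      config = list(k = k, n_init = n_init, max_iter = max_iter,
                    tol = tol, ridge = ridge, seed = seed)
    ),
    class = "gmm_model"
  )
}

gmm_em_once <- function(x, k, max_iter, tol, ridge) {
  n <- nrow(x); d <- ncol(x)
  # k-means++-style init on the current RNG stream
  centers <- x[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(x, 1L, function(r) min(colSums((t(centers) - r)^2)))
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers <- rbind(centers, x[sample.int(n, 1L, prob = p), , drop = FALSE])
  }
  assign <- max.col(-vapply(
    seq_len(k), function(j) colSums((t(x) - centers[j, ])^2), numeric(n)
  ))
  weights <- pmax(tabulate(assign, k), 1) / n
  means <- do.call(rbind, lapply(seq_len(k), function(j) {
    if (any(assign == j)) colMeans(x[assign == j, , drop = FALSE]) else centers[j, ]
  }))
  covs <- array(0, c(d, d, k))
  overall <- stats::cov(x) + diag(ridge, d)
  for (j in seq_len(k)) {
    xj <- x[assign == j, , drop = FALSE]
    covs[, , j] <- if (nrow(xj) > d) stats::cov(xj) + diag(ridge, d) else overall
  }

  trace <- numeric(0)
  ll_prev <- -Inf
  degenerate <- FALSE
  resp <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j) {
      mvn_logdensity(x, means[j, ], covs[, , j])
    }, numeric(n))
    lw <- sweep(logd, 2L, log(weights), `+`)
    m <- apply(lw, 1L, max)
    lse <- m + log(rowSums(exp(lw - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(lw - lse)
    if (is.finite(ll_prev) && ll - ll_prev < tol) break
    ll_prev <- ll
    nk <- colSums(resp)
    weights <- nk / n
    for (j in seq_len(k)) {
      mu <- colSums(resp[, j] * x) / nk[j]
      xc <- sweep(x, 2L, mu)
      sigma <- crossprod(xc * sqrt(resp[, j])) / nk[j] + diag(ridge, d)
      if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < 10 * ridge) {
        degenerate <- TRUE
      }
      means[j, ] <- mu
      covs[, , j] <- sigma
    }
  }
  list(weights = weights, means = means, covs = covs,
       loglik = trace[length(trace)], trace = trace, resp = resp,
       degenerate = degenerate)
}

# Multivariate normal log-density via Cholesky.
mvn_logdensity <- function(x, mu, sigma) {
  x <- as.matrix(x)
  d <- ncol(x)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(z^2))
}

#' Decide which mixture component represents sick cells
#'
#' Hard-assigns every training cell to its maximum-posterior component and
#' declares sick the component whose members contain the larger fraction
#' of cells originating from disease tissue (mutant animals / ALS donors).
#' On an exact tie the smaller-weight component is chosen (sick cells are
#' expected to be the minority in mixed tissue) with a warning.
#'
#' @param m A fitted `gmm_model`.
#' @param cells A `feature_table`, its annotation tibble, or a character
#'   vector of per-cell conditions aligned with the training rows.
#' @return The model with `sick_component` set.
#' @export
orient_sick_component <- function(m, cells) {
  stopifnot(inherits(m, "gmm_model"))
  cond <- if (inherits(cells, "feature_table")) {
    cells$cells$condition
  } else if (is.data.frame(cells)) {
    cells$condition
  } else {
    as.character(cells)
  }
  if (length(cond) != m$n) abort("Condition labels must align with the training cells.")
  disease <- cond != "control"
  frac <- vapply(seq_along(m$weights), function(j) {
    members <- m$assignments == j
    if (!any(members)) return(0)
    mean(disease[members])
  }, numeric(1))
  if (abs(diff(range(frac))) < 1e-12) {
    warn("Components equally disease-occupied; taking the smaller-weight component as sick.")
    m$sick_component <- which.min(m$weights)
  } else {
    m$sick_component <- which.max(frac)
  }
  m
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> %d-component Gaussian mixture in %d dimension(s)\n",
              length(x$weights), x$d))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = ", "), "\n")
  if (!is.na(x$sick_component)) cat("sick component:", x$sick_component, "\n")
  invisible(x)
}

#' @describeIn fit_gmm Per-component tibble of weights and means.
#' @param x A `gmm_model`.
#' @param ... Unused.
#' @export
tidy.gmm_model <- function(x, ...) {
  tibble(
    component = seq_along(x$weights),
    weight = x$weights,
    sick = seq_along(x$weights) == (x$sick_component %||% NA_integer_)
  ) %>%
    dplyr::bind_cols(as_tibble(x$means, .name_repair = ~ paste0("mean_dim", seq_along(.x))))
}
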