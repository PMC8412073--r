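#' One-hidden-layer perceptron classifier
#'
#' The nonlinear label-dependent classifier: logistic hidden and output
#' units trained by full-batch gradient descent with Adam-style adaptive
#' steps on the cross-entropy loss plus an L2 penalty on the connection
#' weights (biases unpenalized). At the profiling scale — hundreds of
#' measurements, tens of hidden units, a few hundred cells — a full-batch
#' first-order trainer converges in seconds and, unlike quasi-Newton
#' methods whose workspace grows with the square of the weight count,
#' stays linear in the number of weights.
#'
#' Weight initialization and training run on a private, seeded RNG
#' stream: the same seed and config give bit-identical weights and
#' predictions.
#'
#' @param x Numeric matrix, cells x measurements (standardized).
#' @param y 0/1 labels.
#' @param hidden Hidden layer size (>= 1).
#' @param l2 L2 penalty on connection weights.
#' @param max_iter Maximum number of full-batch epochs.
#' @param learning_rate Adam base step size.
#' @param tol Stop when the relative loss improvement over an epoch falls
#'   below this (after a burn-in of 100 epochs).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mlp_model`: `W1` (measurements x hidden),
#'   `b1`, `W2` (hidden), `b2`, `hidden`, `seed`, `feature_names`,
#'   `loss`, `n_iter`, `converged`.
#' @export
fit_mlp <- function(x, y, hidden = 25L, l2 = 1e-4, max_iter = 2000L,
                    learning_rate = 0.05, tol = 1e-8, seed = 0L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("`y` must be 0/1 labels.")
  if (length(unique(y)) < 2L) abort("Both classes must be present.")
  if (!is.numeric(hidden) || hidden < 1L) abort("Invalid hidden layer size.")
  hidden <- as.integer(hidden)
  n <- nrow(x); p <- ncol(x)

  par <- with_private_seed(seed, list(
    W1 = matrix(rnorm(p * hidden, 0, 1 / sqrt(p)), p, hidden),
    b1 = numeric(hidden),
    W2 = rnorm(hidden, 0, 1 / sqrt(hidden)),
    b2 = 0
  ))
  # Adam state: first/second moment per parameter block
  m <- lapply(par, function(z) z * 0)
  v <- lapply(par, function(z) z * 0)
  b1_pow <- 1; b2_pow <- 1
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  # decay convention matches standard single-hidden-layer trainers:
  # summed cross-entropy + l2/2 * sum(weights^2), rescaled here to the
  # per-cell mean so the step size is independent of n
  decay <- l2 / n
  loss_of <- function(p_hat, par) {
    -mean(y * log(pmax(p_hat, 1e-12)) + (1 - y) * log(pmax(1 - p_hat, 1e-12))) +
      decay / 2 * (sum(par$W1^2) + sum(par$W2^2))
  }
  loss_prev <- Inf
  loss <- NA_real_
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    a1 <- plogis(sweep(x %*% par$W1, 2L, par$b1, `+`))
    p_hat <- plogis(drop(a1 %*% par$W2) + par$b2)
    loss <- loss_of(p_hat, par)
    if (iter > 100L && abs(loss_prev - loss) < tol * (1 + abs(loss))) {
      converged <- TRUE
      break
    }
    loss_prev <- loss
    ds <- (p_hat - y) / n
    grad <- list(
      W1 = NULL, b1 = NULL,
      W2 = drop(crossprod(a1, ds)) + decay * par$W2,
      b2 = sum(ds)
    )
    dz1 <- (ds %o% par$W2) * a1 * (1 - a1)
    grad$W1 <- crossprod(x, dz1) + decay * par$W1
    grad$b1 <- colSums(dz1)
    b1_pow <- b1_pow * beta1
    b2_pow <- b2_pow * beta2
    for (nm in names(par)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grad[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grad[[nm]]^2
      step <- learning_rate * (m[[nm]] / (1 - b1_pow)) /
        (sqrt(v[[nm]] / (1 - b2_pow)) + eps)
      par[[nm]] <- par[[nm]] - step
    }
  }

  structure(
    list(
      W1 = par$W1, b1 = par$b1, W2 = par$W2, b2 = par$b2,
      hidden = hidden, l2 = l2, seed = seed, max_iter = max_iter,
      feature_names = colnames(x) %||% paste0("x", seq_len(p)),
      loss = loss, n_iter = iter, converged = converged
    ),
    class = "mlp_model"
  )
}

mlp_forward <- function(m, x) {
  a <- plogis(sweep(x %*% m$W1, 2L, m$b1, `+`))
  drop(a %*% m$W2) + m$b2
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d-%d-1 perceptron (l2 = %g, seed = %d)\n",
              length(x$feature_names), x$hidden, x$l2, x$seed))
  invisible(x)
}
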