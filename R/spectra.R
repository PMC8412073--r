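#' Standardize a feature table
#'
#' Z-scores every measurement column: mean 0, sample standard deviation 1
#' (n - 1 denominator). Columns with zero variance carry no information on
#' that scale and are dropped with a warning; their names are recorded in
#' the returned table's `dropped` element.
#'
#' @param table An unscaled `feature_table` with at least 2 cells.
#' @return The table with standardized values and `scaled = TRUE`.
#' @export
standardize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (isTRUE(table$scaled)) abort("Table is already standardized.")
  x <- table$values
  if (nrow(x) < 2L) abort("Standardization needs at least 2 cells.")
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  constant <- s == 0
  if (all(constant)) abort("All measurement columns are constant.")
  if (any(constant)) {
    warn(sprintf("Dropping %d constant measurement(s): %s",
                 sum(constant),
                 paste(head(colnames(x)[constant], 5L), collapse = ", ")))
  }
  keep <- !constant
  z <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep]), 2L, s[keep], `/`)
  out <- table
  out$values <- z
  out$measurements <- table$measurements[keep, , drop = FALSE]
  out$scaled <- TRUE
  out$dropped <- c(table$dropped, colnames(x)[constant])
  out
}

#' Singular value decomposition of a standardized feature table
#'
#' Decomposes the cells-by-measurements matrix X = U D V' and reports, for
#' each of the r = min(cells, measurements) components: the unit-norm
#' loading vector (column of V), the per-cell component scores (X V, i.e.
#' U D), and the explained-variance fraction p_i = sigma_i^2 / sum sigma^2.
#' A principal component is thus a weighted sum of all measurements, read
#' here as one orthogonal morphological profile.
#'
#' Loadings are sign-fixed so that each column's largest-magnitude entry is
#' positive, making outputs deterministic across linear-algebra backends.
#'
#' @param table A standardized `feature_table`.
#' @param center Center columns before decomposing (a no-op after
#'   [standardize()], kept as an explicit flag because the spectrum and its
#'   entropy depend on the convention).
#' @return An object of class `decomposition`: `loadings` (measurements x
#'   r), `scores` (cells x r), `variance_fraction` (length r, non-increasing,
#'   sums to 1), `entropy` (normalized spectrum entropy, see
#'   [variance_entropy()]), `n_components`.
#' @export
decompose <- function(table, center = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  if (!isTRUE(table$scaled)) abort("Decompose expects a standardized table; call standardize() first.")
  x <- table$values
  if (any(!is.finite(x))) abort("Non-finite values in feature table.")
  if (center) x <- sweep(x, 2L, colMeans(x))
  r <- min(dim(x))
  sv <- svd(x, nu = r, nv = r)
  flip <- apply(sv$v, 2L, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  v <- sweep(sv$v, 2L, flip, `*`)
  scores <- sweep(sv$u, 2L, sv$d[seq_len(r)] * flip, `*`)
  d2 <- sv$d[seq_len(r)]^2
  p <- d2 / sum(d2)
  dimnames(v) <- list(colnames(x), paste0("PC", seq_len(r)))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(r)))
  out <- structure(
    list(
      loadings = v, scores = scores, variance_fraction = p,
      n_components = r, singular_values = sv$d[seq_len(r)],
      cells = table$cells, measurements = table$measurements
    ),
    class = "decomposition"
  )
  out$entropy <- variance_entropy(out)
  out
}

#' Normalized Shannon entropy of a variance spectrum
#'
#' H = -(1 / ln r) * sum over p_i > 0 of p_i ln p_i, where p are the
#' explained-variance fractions and r the reported component count. H = 1
#' when variance is spread uniformly over all components (information-rich
#' data) and H = 0 when a single component carries everything.
#'
#' @param d A `decomposition` (or a bare numeric vector of variance
#'   fractions summing to 1).
#' @return Entropy in \[0, 1\].
#' @export
variance_entropy <- function(d) {
  p <- if (inherits(d, "decomposition")) d$variance_fraction else d
  r <- length(p)
  if (r < 2L) abort("Entropy needs at least 2 components.")
  if (abs(sum(p) - 1) > 1e-6 || any(p < -1e-12)) {
    abort("Variance fractions must be nonnegative and sum to 1.")
  }
  pos <- p[p > 0]
  -sum(pos * log(pos)) / log(r)
}

#' Number of components reaching a cumulative variance fraction
#'
#' @param d A `decomposition`.
#' @param frac Target cumulative explained-variance fraction in (0, 1\].
#' @return The smallest k with cumulative variance >= `frac`.
#' @export
n_components_for <- function(d, frac) {
  stopifnot(inherits(d, "decomposition"))
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac > 1) {
    abort("`frac` must be a single number in (0, 1].")
  }
  unname(which(cumsum(d$variance_fraction) >= frac - 1e-12)[1L])
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf(
    "<decomposition> %d components (%d cells x %d measurements)\n",
    x$n_components, nrow(x$scores), nrow(x$loadings)
  ))
  cat(sprintf("  spectrum entropy %.3f; %d components reach 90%% variance\n",
              x$entropy, n_components_for(x, 0.9)))
  invisible(x)
}

#' @describeIn decompose Per-component tibble (component, variance
#'   fraction, cumulative fraction, singular value).
#' @param x A `decomposition`.
#' @param ... Unused.
#' @export
tidy.decomposition <- function(x, ...) {
  tibble(
    component = seq_len(x$n_components),
    variance_fraction = x$variance_fraction,
    cumulative = cumsum(x$variance_fraction),
    singular_value = x$singular_values
  )
}

#' @describeIn decompose One-row summary (n_components, entropy, k90).
#' @export
glance.decomposition <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    entropy = x$entropy,
    k90 = n_components_for(x, 0.9)
  )
}

#' @describeIn decompose Scree plot of the variance spectrum.
#' @param object A `decomposition`.
#' @param n_max Number of leading components to draw.
#' @export
autoplot.decomposition <- function(object, n_max = 50L, ...) {
  df <- tidy(object) %>% filter(.data$component <= n_max)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$variance_fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative / max(.data$cumulative)),
                       colour = "firebrick") +
    ggplot2::labs(
      x = "principal component", y = "explained variance fraction",
      title = sprintf("Variance spectrum (entropy %.3f)", object$entropy)
    ) +
    ggplot2::theme_minimal()
}
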