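#' Per-measurement relative contributions of a classifier
#'
#' Decomposes a fitted classifier into nonnegative per-measurement
#' contributions summing to 1 — which measurements carry the decision.
#' The formulas are exact for linear models and the standard path-weight
#' heuristic for one-hidden-layer networks:
#'
#' * LR: `c_j = |beta_j| / sum_k |beta_k|` (intercept excluded); valid
#'   because the inputs are standardized.
#' * MLP: `c_j` proportional to `sum_h |W1[j,h] * W2[h]|`, the total
#'   absolute input-to-output path weight through the hidden layer.
#' * GMM: the discriminant direction in component space,
#'   `w = pooled_cov^-1 (mu_sick - mu_healthy)`, is mapped back to
#'   measurement space through the selected loading columns, `v = L w`,
#'   and `c_j = |v_j| / sum |v|`.
#'
#' All three are invariant to rescaling the model weights by a positive
#' constant.
#'
#' @param m A fitted `lr_model`, `mlp_model`, or oriented `gmm_model`.
#' @param d For the GMM: the `decomposition` whose loadings map the
#'   model's components back to measurements.
#' @param classifier_id,classifier_group Labels recorded in the output
#'   (`classifier_group` is the phenotype the classifier targets, e.g.
#'   `"comALS"` or `"vcpALS"`).
#' @return A tibble of class `contribution_profile`: `classifier`,
#'   `classifier_group`, `measurement`, `contribution`.
#' @name contributions
NULL

new_contribution_profile <- function(c_vec, names, classifier_id, classifier_group) {
  if (all(c_vec == 0)) abort("All contributions are zero; model weights are degenerate.")
  out <- tibble(
    classifier = classifier_id,
    classifier_group = classifier_group,
    measurement = names %||% paste0("x", seq_along(c_vec)),
    contribution = unname(c_vec / sum(c_vec))
  )
  class(out) <- c("contribution_profile", class(out))
  out
}

#' @rdname contributions
#' @export
contributions_lr <- function(m, classifier_id = "LR", classifier_group = NA_character_) {
  stopifnot(inherits(m, "lr_model"))
  beta <- m$beta[-1L]
  new_contribution_profile(abs(beta), m$feature_names, classifier_id, classifier_group)
}

#' @rdname contributions
#' @export
contributions_mlp <- function(m, classifier_id = "MLP", classifier_group = NA_character_) {
  stopifnot(inherits(m, "mlp_model"))
  c_vec <- drop(abs(m$W1) %*% abs(m$W2))
  new_contribution_profile(c_vec, m$feature_names, classifier_id, classifier_group)
}

#' @rdname contributions
#' @export
contributions_gmm <- function(m, d, classifier_id = "GMM",
                              classifier_group = NA_character_) {
  stopifnot(inherits(m, "gmm_model"), inherits(d, "decomposition"))
  if (is.null(m$pc_indices)) abort("GMM model records no pc_indices.")
  if (max(m$pc_indices) > d$n_components) abort("pc_indices exceed the decomposition.")
  sick <- if (!is.na(m$sick_component)) m$sick_component else 2L
  healthy <- setdiff(seq_along(m$weights), sick)[1]
  pooled <- m$weights[healthy] * m$covariances[, , healthy] +
    m$weights[sick] * m$covariances[, , sick]
  w <- solve(pooled, m$means[sick, ] - m$means[healthy, ])
  v <- drop(d$loadings[, m$pc_indices, drop = FALSE] %*% w)
  new_contribution_profile(abs(v), rownames(d$loadings), classifier_id, classifier_group)
}

#' Top contributing measurements
#'
#' @param p A `contribution_profile`.
#' @param k Number of measurements to return (>= 1), ties broken by
#'   measurement name for determinism.
#' @return The `k` rows with the largest contributions, ranked.
#' @export
top_contributors <- function(p, k = 5L) {
  stopifnot(inherits(p, "contribution_profile"))
  if (!is.numeric(k) || k < 1L) abort("`k` must be >= 1.")
  if (k > nrow(p)) abort("`k` exceeds the number of measurements.")
  p %>%
    arrange(desc(.data$contribution), .data$measurement) %>%
    head(as.integer(k)) %>%
    mutate(rank = row_number())
}

#' Category-level mixed-model test of contribution differences
#'
#' Do comALS-type and vcpALS-type classifiers weight a measurement
#' category (area-shape / texture / intensity) differently? For each
#' category, fits a random-intercept LMM of the per-measurement
#' contribution on the classifier-group indicator, with classifiers as
#' groups — the random intercept absorbs idiosyncratic per-classifier
#' scale (see [fit_random_intercept_lmm()]).
#'
#' @param profiles A list of `contribution_profile`s (or their bound
#'   rows), each carrying a `classifier_group`; at least two classifiers
#'   per group.
#' @param categories Measurement taxonomy tibble with columns `name`,
#'   `category` (e.g. a feature table's `measurements`).
#' @return A tibble with one row per category: `category`, group mean
#'   contributions, LMM `effect` (vcpALS minus comALS) and `p_value`.
#' @export
category_lmm <- function(profiles, categories) {
  df <- if (is.data.frame(profiles)) profiles else bind_rows(profiles)
  df <- df %>%
    left_join(categories %>% select(measurement = "name", "category"),
              by = "measurement")
  counts <- df %>% distinct(.data$classifier, .data$classifier_group) %>%
    count(.data$classifier_group)
  if (nrow(counts) < 2L || any(counts$n < 2L)) {
    abort("category_lmm needs at least 2 classifiers per classifier group.")
  }
  df %>%
    group_by(.data$category) %>%
    dplyr::group_modify(function(sub, key) {
      if (dplyr::n_distinct(sub$measurement) < 2L) {
        abort(sprintf("Category '%s' has fewer than 2 measurements.", key$category))
      }
      x <- as.integer(sub$classifier_group == "vcpALS")
      fit <- fit_random_intercept_lmm(sub$contribution, x, sub$classifier)
      tibble(
        mean_comALS = mean(sub$contribution[x == 0]),
        mean_vcpALS = mean(sub$contribution[x == 1]),
        effect = fit$beta_fixed[["x"]],
        p_value = fit$p_value
      )
    }) %>%
    ungroup()
}

#' Permutation z-scores for category contributions
#'
#' Is the mean contribution of a measurement category larger than expected
#' if category labels were arbitrary? The observed statistic is the mean
#' contribution within the category; the null distribution comes from
#' `n_perm` random permutations of the category labels across
#' measurements; `z = (obs - mean_null) / sd_null`. Seeded and
#' reproducible. If the null distribution is degenerate (all contributions
#' equal) `z` is 0 with a warning.
#'
#' @param p A `contribution_profile` for one classifier.
#' @param categories Measurement taxonomy tibble (`name`, `category`).
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param seed Integer seed.
#' @return A tibble with one row per category: `category`, `observed`
#'   (mean contribution), `null_mean`, `null_sd`, `z`.
#' @export
category_permutation_z <- function(p, categories, n_perm = 10000L, seed = 0L) {
  stopifnot(inherits(p, "contribution_profile"))
  if (n_perm < 100L) abort("`n_perm` must be at least 100.")
  tax <- categories %>% select(measurement = "name", "category")
  df <- p %>% left_join(tax, by = "measurement")
  if (anyNA(df$category)) abort("Every measurement needs a category.")
  cats <- sort(unique(df$category))
  if (any(table(df$category) == 0L)) abort("Empty category.")
  cvec <- df$contribution
  M <- length(cvec)
  # indicator matrix (M x K) scaled to give means; one permutation of the
  # contribution vector serves all categories at once
  W <- vapply(cats, function(cc) (df$category == cc) / sum(df$category == cc),
              numeric(M))
  perms <- with_private_seed(seed, vapply(
    seq_len(n_perm), function(i) cvec[sample.int(M)], numeric(M)
  ))
  null_stats <- crossprod(W, perms)          # K x n_perm
  obs <- drop(crossprod(W, cvec))
  null_mean <- rowMeans(null_stats)
  null_sd <- apply(null_stats, 1L, sd)
  z <- ifelse(null_sd > 0, (obs - null_mean) / null_sd, 0)
  if (any(null_sd == 0)) {
    warn("Degenerate permutation null (all contributions equal); z set to 0.")
  }
  tibble(category = cats, observed = obs, null_mean = null_mean,
         null_sd = null_sd, z = z)
}

#' Relative contribution of a channel's N/C-ratio measurement
#'
#' @param p A `contribution_profile`.
#' @param table The `feature_table` the classifier was fitted on (used to
#'   resolve the channel's N/C-ratio measurement, see [select_nc_ratio()]).
#' @param channel Channel name, e.g. `"SFPQ"`.
#' @return The scalar contribution of that single measurement.
#' @export
nc_ratio_contribution <- function(p, table, channel) {
  stopifnot(inherits(p, "contribution_profile"))
  idx <- select_nc_ratio(table, channel)
  p$contribution[match(names(idx), p$measurement)]
}

#' Plot contribution distributions by measurement category
#'
#' @param profiles A list of `contribution_profile`s or their bound rows.
#' @param categories Measurement taxonomy tibble (`name`, `category`).
#' @return A ggplot object: box plots of per-measurement contributions by
#'   category, split by classifier group.
#' @export
plot_category_contributions <- function(profiles, categories) {
  df <- if (is.data.frame(profiles)) profiles else bind_rows(profiles)
  df <- df %>%
    left_join(categories %>% select(measurement = "name", "category"),
              by = "measurement")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$classifier_group, y = .data$contribution,
    fill = .data$classifier_group
  )) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.size = 0.4) +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = NULL, y = "relative contribution") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
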