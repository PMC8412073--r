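#' Aggregate per-cell disease profiles into per-animal scores
#'
#' For each animal/donor and classifier: the mean disease probability of
#' its cells, the mean severity score, and the percentage of cells called
#' sick (disMNs, `P` above `threshold`). Means are unweighted over the
#' sample's cells; `n_cells` is reported so sparsely sampled animals are
#' visible.
#'
#' @param profile A disease-profile tibble from [predict_profile()] (one
#'   row per cell x classifier, columns `cell_id`, `classifier`, `P`, `S`).
#' @param cells A `feature_table` or annotation tibble covering every
#'   profiled cell.
#' @param threshold Sick-call probability cutoff (default 0.5).
#' @return A tibble with one row per sample x classifier: `sample_id`,
#'   `condition`, `classifier`, `mean_P`, `mean_S`, `pct_sick`, `n_cells`.
#' @export
aggregate_samples <- function(profile, cells, threshold = 0.5) {
  ann <- if (inherits(cells, "feature_table")) cells$cells else as_tibble(cells)
  missing_ann <- setdiff(profile$cell_id, ann$cell_id)
  if (length(missing_ann)) {
    abort(sprintf("Profiled cell(s) without annotation: %s",
                  paste(head(missing_ann, 5L), collapse = ", ")))
  }
  profile %>%
    left_join(ann, by = "cell_id") %>%
    group_by(.data$sample_id, .data$condition, .data$classifier) %>%
    summarise(
      mean_P = mean(.data$P),
      mean_S = mean(.data$S),
      pct_sick = 100 * mean(.data$P > threshold),
      n_cells = dplyr::n(),
      .groups = "drop"
    )
}

#' Welch's unequal-variance two-sample t test
#'
#' Two-sided by default, with the Welch-Satterthwaite degrees of freedom.
#' Used for all animal- and donor-level group comparisons.
#'
#' @param a,b Numeric vectors (>= 2 finite values each).
#' @param alternative Passed to [stats::t.test()].
#' @return A one-row tibble: `statistic` (t), `df`, `p_value`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
welch_test <- function(a, b, alternative = "two.sided") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) abort("Each group needs at least 2 values.")
  if (!all(is.finite(c(a, b)))) abort("Non-finite values in input.")
  if (sd(a) == 0 && sd(b) == 0) {
    # t.test errors on two exactly-constant groups; the statistic is
    # well-defined by continuity: no evidence either way when means agree
    if (mean(a) == mean(b)) {
      return(tibble(statistic = 0, df = length(a) + length(b) - 2,
                    p_value = 1, mean_a = mean(a), mean_b = mean(b),
                    n_a = length(a), n_b = length(b)))
    }
    abort("Both groups are constant with different means; Welch variance is zero.")
  }
  tt <- t.test(a, b, alternative = alternative, var.equal = FALSE)
  tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
    n_a = length(a), n_b = length(b)
  )
}

#' Compare disease scores of each condition against control
#'
#' One Welch test per non-control condition, on a chosen per-animal
#' metric: does the mutant group carry higher disease probability /
#' severity / sick-cell percentage than controls?
#'
#' @param scores Output of [aggregate_samples()] (optionally filtered to
#'   one classifier; comparisons are run per classifier otherwise).
#' @param metric `"mean_P"`, `"mean_S"` or `"pct_sick"`.
#' @param control Name of the control condition.
#' @return A tibble with one row per classifier x condition: the compared
#'   condition, metric, Welch `statistic`, `df`, `p_value` and group means.
#' @export
compare_to_control <- function(scores, metric = c("mean_P", "mean_S", "pct_sick"),
                               control = "control") {
  metric <- arg_match(metric)
  if (!control %in% scores$condition) abort(sprintf("No '%s' samples present.", control))
  out <- scores %>%
    group_by(.data$classifier) %>%
    dplyr::group_modify(function(df, key) {
      ctrl <- df[[metric]][df$condition == control]
      if (length(ctrl) < 2L) abort("Need at least 2 control samples.")
      others <- setdiff(unique(df$condition), control)
      purrr::map_dfr(others, function(cc) {
        vals <- df[[metric]][df$condition == cc]
        if (length(vals) < 2L) {
          abort(sprintf("Need at least 2 samples in group '%s'.", cc))
        }
        welch_test(vals, ctrl) %>%
          mutate(condition = cc, metric = metric, .before = 1L)
      })
    }) %>%
    ungroup()
  out
}

#' Re-label cells by classifier verdict and re-test a measurement
#'
#' The signal-to-noise argument behind single-cell re-labeling: disease
#' tissue contains healthy cells, so grouping a measurement (e.g. a
#' protein's N/C ratio) by tissue origin dilutes the sick-cell signal.
#' This compares the Welch p-value of `measurement` grouped by tissue
#' origin (`p_origin`) against the p-value after re-grouping cells into
#' healthy vs sick by classifier probability (`p_relabel`). A classifier
#' that isolates the truly sick cells yields `p_relabel < p_origin`.
#'
#' @param table A `feature_table` holding the measurement.
#' @param measurement Column index or name of the measurement to test.
#' @param profile Disease-profile tibble covering the table's cells.
#' @param threshold Sick-call probability cutoff.
#' @return A one-row tibble: `measurement`, `p_origin`, `p_relabel`,
#'   `n_origin_pos`, `n_origin_neg`, `n_sick`, `n_healthy`.
#' @export
relabel_and_retest <- function(table, measurement, profile, threshold = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  if (is.character(measurement)) {
    idx <- match(measurement, colnames(table$values))
    if (is.na(idx)) abort(sprintf("No measurement named '%s'.", measurement))
  } else {
    idx <- as.integer(measurement)
    if (idx < 1L || idx > ncol(table$values)) abort("Measurement index out of range.")
  }
  v <- table$values[, idx]
  origin <- disease_labels(table) == 1L
  pr <- profile[match(rownames(table$values), profile$cell_id), ]
  if (anyNA(pr$P)) abort("Profile does not cover every cell in the table.")
  sick <- pr$P > threshold
  if (all(sick) || !any(sick)) {
    abort("Classifier assigns all cells to one class; re-labeled groups are empty.")
  }
  p_origin <- welch_test(v[origin], v[!origin])$p_value
  p_relabel <- welch_test(v[sick], v[!sick])$p_value
  tibble(
    measurement = colnames(table$values)[idx],
    p_origin = p_origin, p_relabel = p_relabel,
    n_origin_pos = sum(origin), n_origin_neg = sum(!origin),
    n_sick = sum(sick), n_healthy = sum(!sick)
  )
}

#' Plot per-animal disease scores by condition
#'
#' Box plots of a per-animal metric grouped by condition, one panel per
#' classifier; dots are animals.
#'
#' @param scores Output of [aggregate_samples()].
#' @param metric `"mean_P"`, `"mean_S"` or `"pct_sick"`.
#' @return A ggplot object.
#' @export
plot_sample_scores <- function(scores, metric = c("mean_P", "mean_S", "pct_sick")) {
  metric <- arg_match(metric)
  ggplot2::ggplot(scores, ggplot2::aes(
    x = .data$condition, y = .data[[metric]], fill = .data$condition
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 2) +
    ggplot2::facet_wrap(~classifier) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
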