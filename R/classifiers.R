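#' Tissue-origin disease labels
#'
#' Label-dependent classifiers take their training labels from tissue
#' origin: a cell is labeled sick when it comes from a disease-mutant
#' animal or an ALS donor, healthy when it comes from a control.
#'
#' @param cells A `feature_table` or its annotation tibble.
#' @return Integer 0/1 vector, 1 = disease origin.
#' @export
disease_labels <- function(cells) {
  ann <- if (inherits(cells, "feature_table")) cells$cells else as_tibble(cells)
  as.integer(ann$condition != "control")
}

#' Fit a classifier on condition-censored data
#'
#' Retrains an LR or MLP classifier on the subset of cells whose condition
#' is in `keep_conditions`, leaving everything else identical. Censoring
#' SOD1-mutant cells (keeping control + VCP) yields the sLR / sMLP
#' classifiers that learn the VCP-specific phenotype; the fitted model can
#' still score censored-condition cells at predict time.
#'
#' @param kind `"lr"` or `"mlp"`.
#' @param table A standardized `feature_table`.
#' @param keep_conditions Conditions retained for training.
#' @param ... Passed on to [fit_logistic()] or [fit_mlp()].
#' @return An `lr_model` or `mlp_model` with attribute `"censored"` naming
#'   the excluded conditions.
#' @export
fit_censored <- function(kind = c("lr", "mlp"), table, keep_conditions, ...) {
  kind <- arg_match(kind)
  stopifnot(inherits(table, "feature_table"))
  present <- unique(table$cells$condition)
  missing_cond <- setdiff(keep_conditions, present)
  if (length(missing_cond)) {
    abort(sprintf("Condition(s) not in the data: %s.",
                  paste(missing_cond, collapse = ", ")))
  }
  keep <- table$cells$condition %in% keep_conditions
  y <- disease_labels(table)[keep]
  if (length(unique(y)) < 2L) {
    abort("Censoring eliminated one of the classes; keep at least one control and one disease condition.")
  }
  x <- table$values[keep, , drop = FALSE]
  m <- switch(kind, lr = fit_logistic(x, y, ...), mlp = fit_mlp(x, y, ...))
  attr(m, "censored") <- setdiff(present, keep_conditions)
  m
}

#' Per-cell disease profile (probability and severity) from a classifier
#'
#' Every classifier yields, per cell, the pair forming its disease
#' profile: the disease probability `P` and a severity score `S` on the
#' raw log-odds scale (the pre-link linear predictor for LR, the output
#' pre-activation for the MLP, and the sick-vs-healthy weighted
#' log-density ratio for the GMM, whose posterior equals `plogis(S)` by
#' construction). `P = plogis(S)` is strictly increasing in `S`, but while
#' `P` saturates near 0/1, `S` keeps separating cells: two cells that are
#' both almost certainly sick can still differ widely in severity.
#'
#' @param model A fitted `lr_model`, `mlp_model` or oriented `gmm_model`.
#' @param newdata Cells x measurements matrix (LR/MLP) or cells x
#'   components score matrix (GMM; the full score matrix may be passed
#'   when the model records its `pc_indices`).
#' @param classifier_id Label recorded in the output.
#' @return A tibble with columns `cell_id`, `classifier`, `P`, `S`.
#' @export
predict_profile <- function(model, newdata, classifier_id = class(model)[1]) {
  UseMethod("predict_profile")
}

profile_tibble <- function(S, ids, classifier_id) {
  tibble(
    cell_id = ids %||% as.character(seq_along(S)),
    classifier = classifier_id,
    P = plogis(S),
    S = S
  )
}

#' @export
predict_profile.lr_model <- function(model, newdata, classifier_id = "LR") {
  x <- as.matrix(newdata)
  if (ncol(x) != length(model$feature_names)) {
    abort(sprintf("Model expects %d measurements, got %d.",
                  length(model$feature_names), ncol(x)))
  }
  S <- drop(cbind(1, x) %*% model$beta)
  profile_tibble(S, rownames(x), classifier_id)
}

#' @export
predict_profile.mlp_model <- function(model, newdata, classifier_id = "MLP") {
  x <- as.matrix(newdata)
  if (ncol(x) != nrow(model$W1)) {
    abort(sprintf("Model expects %d measurements, got %d.", nrow(model$W1), ncol(x)))
  }
  profile_tibble(mlp_forward(model, x), rownames(x), classifier_id)
}

#' @export
predict_profile.gmm_model <- function(model, newdata, classifier_id = "GMM") {
  if (is.na(model$sick_component)) {
    abort("GMM model is not oriented; call orient_sick_component() first.")
  }
  x <- as.matrix(newdata)
  if (ncol(x) != model$d && !is.null(model$pc_indices)) {
    if (max(model$pc_indices) <= ncol(x)) {
      x <- x[, model$pc_indices, drop = FALSE]
    }
  }
  if (ncol(x) != model$d) {
    abort(sprintf("Model expects %d component score column(s), got %d.",
                  model$d, ncol(x)))
  }
  sick <- model$sick_component
  healthy <- setdiff(seq_along(model$weights), sick)[1]
  S <- log(model$weights[sick]) +
    mvn_logdensity(x, model$means[sick, ], model$covariances[, , sick]) -
    log(model$weights[healthy]) -
    mvn_logdensity(x, model$means[healthy, ], model$covariances[, , healthy])
  profile_tibble(S, rownames(x), classifier_id)
}

#' ROC curve and AUC by pairwise concordance
#'
#' The AUC is the probability that a randomly chosen positive cell scores
#' above a randomly chosen negative one, ties counted one half — computed
#' exactly over all positive-negative pairs via midranks. The curve walks
#' the sorted unique score thresholds.
#'
#' @param scores Numeric classifier scores (any strictly monotone
#'   transform of `P` or `S` gives the same AUC).
#' @param labels 0/1 labels with both classes present.
#' @return An object of class `roc_result` with elements `auc` and `curve`
#'   (a tibble of threshold, fpr, tpr).
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("`labels` must be 0/1.")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("Both classes must be present.")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- tibble(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(scores[labels == 1L] >= t), numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(scores[labels == 0L] >= t), numeric(1)))
  )
  structure(list(auc = auc, curve = curve, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @describeIn roc_auc The ROC curve as a tibble.
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @describeIn roc_auc ROC curve plot.
#' @param object A `roc_result`.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Leave-one-animal-out cross-validated disease profiles
#'
#' The default evaluation is in-sample (one ROC over all cells); with few
#' cells and many measurements that estimate is optimistic. This variant
#' refits the classifier once per animal/donor, leaving all of that
#' animal's cells out, and scores them with the held-out model — honest
#' generalization across animals.
#'
#' @param table A standardized `feature_table`.
#' @param fit_fun Fitting function taking `(x, y, ...)` and returning a
#'   model with a [predict_profile()] method, e.g. [fit_logistic()].
#' @param ... Passed to `fit_fun`.
#' @param classifier_id Label recorded in the output.
#' @return A disease-profile tibble in the input cell order.
#' @export
loao_profile <- function(table, fit_fun, ..., classifier_id = "LOAO") {
  stopifnot(inherits(table, "feature_table"))
  y <- disease_labels(table)
  groups <- table$cells$sample_id
  out <- purrr::map_dfr(unique(groups), function(g) {
    train <- groups != g
    if (length(unique(y[train])) < 2L) {
      abort(sprintf("Holding out '%s' leaves a single class.", g))
    }
    m <- fit_fun(table$values[train, , drop = FALSE], y[train], ...)
    predict_profile(m, table$values[!train, , drop = FALSE],
                    classifier_id = classifier_id)
  })
  out[match(rownames(table$values), out$cell_id), ]
}
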