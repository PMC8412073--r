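#' Encode a phenotype contrast from cell annotations
#'
#' Three contrast schemes cover the study designs: `comALS` (all
#' disease-mutant cells, SOD1 and VCP, vs control — the phenotype shared
#' across genetic backgrounds), `vcpALS` (VCP-mutant cells vs everything
#' else — the dominant VCP-specific phenotype), and `sALS` (sporadic-ALS
#' donor cells vs control, for human post-mortem data).
#'
#' @param cells A `feature_table` or its `cells` annotation tibble.
#' @param scheme One of `"comALS"`, `"vcpALS"`, `"sALS"`.
#' @return An object of class `phenotype_contrast` with elements `scheme`
#'   and `indicator` (per-cell 0/1 vector).
#' @examples
#' ann <- tibble::tibble(
#'   cell_id = c("a", "b", "c"), sample_id = c("m1", "m2", "m3"),
#'   condition = c("control", "sod1", "vcp")
#' )
#' encode_phenotype(ann, "comALS")$indicator
#' @export
encode_phenotype <- function(cells, scheme = c("comALS", "vcpALS", "sALS")) {
  scheme <- arg_match(scheme)
  ann <- if (inherits(cells, "feature_table")) cells$cells else as_tibble(cells)
  cond <- ann$condition
  present <- unique(cond)
  need <- switch(scheme,
    comALS = list(pos = c("sod1", "vcp"), universe = c("control", "sod1", "vcp")),
    vcpALS = list(pos = "vcp", universe = c("control", "sod1", "vcp")),
    sALS = list(pos = "sals", universe = c("control", "sals"))
  )
  if (!any(need$pos %in% present)) {
    abort(sprintf("Scheme '%s' references condition(s) absent from the data: %s.",
                  scheme, paste(setdiff(need$pos, present), collapse = ", ")))
  }
  if (!all(present %in% need$universe)) {
    abort(sprintf("Scheme '%s' is incompatible with condition(s): %s.",
                  scheme, paste(setdiff(present, need$universe), collapse = ", ")))
  }
  ind <- as.integer(cond %in% need$pos)
  if (all(ind == 1L) || all(ind == 0L)) {
    abort(sprintf("Scheme '%s' yields a constant indicator.", scheme))
  }
  structure(list(scheme = scheme, indicator = ind), class = "phenotype_contrast")
}

#' Associate principal components with a phenotype contrast
#'
#' For each of the first `n_pcs` components, fits a random-intercept
#' linear mixed model of the per-cell component score on the phenotype
#' indicator, with animals/donors as groups
#' (see [fit_random_intercept_lmm()]), and flags components whose
#' likelihood-ratio p-value falls below `alpha`. Selected components carry
#' morphological profiles reproducibly associated with the contrast beyond
#' animal-level idiosyncrasy.
#'
#' @param d A `decomposition`.
#' @param contrast A `phenotype_contrast` (or a scheme name, encoded from
#'   the decomposition's own annotations).
#' @param groups Sample/animal id per cell; defaults to the decomposition's
#'   `sample_id` annotation.
#' @param n_pcs Number of leading components to test; defaults to the
#'   smallest number capturing 90% of variance.
#' @param alpha Significance level for selection (unadjusted by default).
#' @param adjust `"none"` or `"bh"` (Benjamini-Hochberg) across the
#'   `n_pcs` tests.
#' @return A tibble of class `pc_association` with one row per component:
#'   `component`, `scheme`, `estimate` (phenotype coefficient), `sigma_a2`,
#'   `sigma_e2`, `p_value`, `p_adj`, `selected`.
#' @export
associate_pcs <- function(d, contrast, groups = NULL, n_pcs = NULL,
                          alpha = 0.05, adjust = c("none", "bh")) {
  stopifnot(inherits(d, "decomposition"))
  adjust <- arg_match(adjust)
  if (is.character(contrast)) contrast <- encode_phenotype(d$cells, contrast)
  stopifnot(inherits(contrast, "phenotype_contrast"))
  groups <- groups %||% d$cells$sample_id
  n_pcs <- n_pcs %||% n_components_for(d, 0.9)
  if (!is.numeric(n_pcs) || n_pcs < 1L) abort("`n_pcs` must be >= 1.")
  if (n_pcs > d$n_components) abort("`n_pcs` exceeds the number of components.")

  fits <- map(seq_len(n_pcs), function(k) {
    fit_random_intercept_lmm(d$scores[, k], contrast$indicator, groups)
  })
  p <- map_dbl(fits, "p_value")
  p_adj <- if (adjust == "bh") stats::p.adjust(p, method = "BH") else p
  out <- tibble(
    component = seq_len(n_pcs),
    scheme = contrast$scheme,
    estimate = map_dbl(fits, ~ .x$beta_fixed[["x"]]),
    sigma_a2 = map_dbl(fits, "sigma_a2"),
    sigma_e2 = map_dbl(fits, "sigma_e2"),
    p_value = p,
    p_adj = p_adj,
    selected = p_adj < alpha
  )
  class(out) <- c("pc_association", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Plot component-phenotype association strengths
#'
#' Bar plot of -log10 likelihood-ratio p-values per component, with the
#' selection threshold drawn as a dashed line.
#'
#' @param object A `pc_association` table.
#' @param ... Unused.
#' @export
autoplot.pc_association <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$component), y = -log10(.data$p_value),
    fill = .data$selected
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "principal component", y = expression(-log[10](p)),
      title = sprintf("Component association with %s phenotype",
                      object$scheme[[1]])
    ) +
    ggplot2::theme_minimal()
}
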