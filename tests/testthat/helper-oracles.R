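# Independent reference implementations used as oracles. Deliberately
# naive and self-contained; they never call the package code paths they
# check.

# AUC as explicit mean over all positive-negative score pairs.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  grid <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(grid)
}

# Welch's t from the closed-form formulas.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# O(n^3) agglomerative UPGMA on a raw distance matrix: average linkage
# as the mean of all original pairwise distances between the two groups.
naive_upgma_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Small feature table fixture: n cells over two conditions / four samples.
toy_feature_table <- function(n = 12L, p = 6L, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- c(
    paste0("AreaShape_Shape", seq_len(max(0, p - 3))),
    "Texture_Entropy_DAPI_1", "Intensity_NCRatio_SFPQ", "Intensity_NCRatio_FUS"
  )[seq_len(p)]
  rownames(x) <- sprintf("c%02d", seq_len(n))
  ann <- tibble::tibble(
    cell_id = rownames(x),
    sample_id = rep(c("m1", "m2", "m3", "m4"), length.out = n),
    condition = rep(c("control", "control", "vcp", "sod1"), length.out = n)
  )
  as_feature_table(x, ann)
}
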