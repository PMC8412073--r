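test_that("penalized logistic fits are finite and monotone on separable data", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  m <- fit_logistic(x, y, lambda = 1)
  expect_true(all(is.finite(m$beta)))
  p <- predict_profile(m, x)$P
  expect_false(is.unsorted(p))
  # unpenalized separable data has no optimum
  expect_error(fit_logistic(x, y, lambda = 0, max_iter = 50), "lambda")
})

test_that("a near-unpenalized fit matches glm", {
  set.seed(30)
  x <- matrix(rnorm(400), ncol = 2)
  colnames(x) <- c("a", "b")
  y <- rbinom(200, 1, plogis(0.5 + x[, 1] - 0.8 * x[, 2]))
  m <- fit_logistic(x, y, lambda = 1e-10)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(m$beta), unname(coef(ref)), tolerance = 1e-6)
})

test_that("mirror-symmetric data has a vanishing intercept", {
  set.seed(31)
  x <- matrix(rnorm(100), ncol = 1)
  y <- as.integer(x[, 1] + rnorm(100, 0, 0.5) > 0)
  xs <- rbind(x, -x)
  ys <- c(y, 1L - y)
  m <- fit_logistic(xs, ys, lambda = 1)
  expect_lt(abs(m$beta[["(Intercept)"]]), 1e-6)
})

test_that("the MLP captures XOR structure that LR cannot", {
  set.seed(32)
  n <- 400
  x <- matrix(runif(2 * n, -1, 1), ncol = 2)
  colnames(x) <- c("a", "b")
  y <- as.integer(x[, 1] * x[, 2] > 0)
  mlp <- fit_mlp(x, y, hidden = 8, seed = 1)
  lr <- fit_logistic(x, y, lambda = 1)
  auc_mlp <- roc_auc(predict_profile(mlp, x)$S, y)$auc
  auc_lr <- roc_auc(predict_profile(lr, x)$S, y)$auc
  expect_gt(auc_mlp, 0.95)
  expect_lt(abs(auc_lr - 0.5), 0.15)

  # on linearly separable data the MLP is not materially worse than LR
  y_lin <- as.integer(x[, 1] + 0.5 * x[, 2] > 0)
  mlp2 <- fit_mlp(x, y_lin, hidden = 8, seed = 1)
  lr2 <- fit_logistic(x, y_lin, lambda = 1)
  expect_gte(
    roc_auc(predict_profile(mlp2, x)$S, y_lin)$auc,
    roc_auc(predict_profile(lr2, x)$S, y_lin)$auc - 0.02
  )
})

test_that("the MLP matches an independent single-hidden-layer trainer", {
  skip_if_not_installed("nnet")
  set.seed(36)
  n <- 300
  x <- matrix(rnorm(2 * n), ncol = 2)
  colnames(x) <- c("a", "b")
  y <- rbinom(n, 1, plogis(1.5 * x[, 1] - x[, 2]))
  mine <- fit_mlp(x, y, hidden = 5, seed = 2)
  ref <- nnet::nnet(x = x, y = y, size = 5, decay = 1e-4, maxit = 500,
                    entropy = TRUE, trace = FALSE)
  auc_mine <- roc_auc(predict_profile(mine, x)$S, y)$auc
  auc_ref <- roc_auc(drop(predict(ref, x)), y)$auc
  expect_equal(auc_mine, auc_ref, tolerance = 0.03)
})

test_that("MLP training is bit-reproducible given the seed", {
  set.seed(33)
  x <- matrix(rnorm(120), ncol = 2)
  y <- as.integer(x[, 1] > 0)
  m1 <- fit_mlp(x, y, hidden = 4, seed = 7)
  m2 <- fit_mlp(x, y, hidden = 4, seed = 7)
  expect_identical(m1$W1, m2$W1)
  expect_identical(predict_profile(m1, x)$S, predict_profile(m2, x)$S)
  expect_error(fit_mlp(x, y, hidden = 0), "hidden")
})

test_that("condition censoring subsets training but not prediction", {
  sim <- generate_cells(synthetic_config(
    seed = 40, n_features = c(area_shape = 6L, texture = 4L, intensity = 4L),
    k_com = 3L, k_vcp = 3L, cells_mean = 20
  ))
  s <- standardize(sim$table)
  m <- fit_censored("lr", s, c("control", "vcp"), lambda = 1)
  expect_s3_class(m, "lr_model")
  expect_equal(attr(m, "censored"), "sod1")
  # the censored model matches a manual refit on the row subset
  keep <- s$cells$condition %in% c("control", "vcp")
  ref <- fit_logistic(s$values[keep, ], disease_labels(s)[keep], lambda = 1)
  expect_equal(m$beta, ref$beta)
  # sod1 cells are scored without error
  sod1 <- s$values[s$cells$condition == "sod1", , drop = FALSE]
  expect_equal(nrow(predict_profile(m, sod1)), nrow(sod1))

  expect_error(fit_censored("lr", s, "control"), "eliminated")
  expect_error(fit_censored("lr", s, "sals"), "not in the data")
})

test_that("severity preserves distinctions that probability saturates away", {
  m <- structure(
    list(beta = c("(Intercept)" = 0, x = 1), lambda = 1, n_iter = 1L,
         feature_names = "x"),
    class = "lr_model"
  )
  prof <- predict_profile(m, matrix(c(0, 30, 40), ncol = 1,
                                    dimnames = list(NULL, "x")))
  expect_equal(prof$P[1], 0.5)            # S = 0 maps to P = 0.5
  expect_lt(abs(prof$P[2] - 1), 1e-12)
  expect_lt(abs(prof$P[3] - 1), 1e-12)
  expect_gt(prof$S[3] - prof$S[2], 5)     # severities stay distinct
})

test_that("AUC equals pairwise concordance and honors its invariances", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "Both classes")

  set.seed(34)
  for (i in 1:20) {
    s <- round(rnorm(30), 1)              # rounding forces ties
    l <- rbinom(30, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l)$auc, brute_force_auc(s, l))
    # strictly monotone transforms leave the AUC unchanged
    expect_equal(roc_auc(exp(s), l)$auc, roc_auc(s, l)$auc)
  }
})

test_that("AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(35)
  s <- rnorm(80)
  l <- rbinom(80, 1, 0.5)
  expect_equal(
    roc_auc(s, l)$auc,
    as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE, direction = "<")))
  )
})

test_that("leave-one-animal-out profiles score every cell with held-out models", {
  sim <- generate_cells(synthetic_config(
    seed = 41, n_features = c(area_shape = 4L, texture = 3L, intensity = 3L),
    k_com = 3L, k_vcp = 3L, cells_mean = 15
  ))
  s <- standardize(sim$table)
  prof <- loao_profile(s, fit_logistic, lambda = 1, classifier_id = "LR-cv")
  expect_equal(prof$cell_id, rownames(s$values))
  expect_true(all(prof$P > 0 & prof$P < 1))
})
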