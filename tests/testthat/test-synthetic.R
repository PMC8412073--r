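test_that("generation is bit-identical under the seed and obeys the config", {
  cfg <- synthetic_config(seed = 80, n_features = c(area_shape = 12L, texture = 8L,
                                                    intensity = 6L),
                          k_com = 5L, k_vcp = 5L)
  s1 <- generate_cells(cfg)
  s2 <- generate_cells(cfg)
  expect_identical(s1$table$values, s2$table$values)
  expect_identical(s1$truth, s2$truth)
  expect_equal(ncol(s1$table$values), 26L)
  expect_setequal(unique(s1$truth$condition), c("control", "sod1", "vcp"))
  # sample -> condition mapping is single-valued, >= 2 cells per sample
  expect_true(all(table(s1$truth$sample_id) >= 2L))
  # control cells are healthy under the default contamination of zero
  expect_false(any(s1$truth$sick[s1$truth$condition == "control"]))
  # a different seed moves the values
  s3 <- generate_cells(synthetic_config(seed = 81,
                                        n_features = c(area_shape = 12L, texture = 8L,
                                                       intensity = 6L),
                                        k_com = 5L, k_vcp = 5L))
  expect_false(identical(s1$table$values, s3$table$values))
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(pi_sick = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(d_com = -1), "nonnegative")
  expect_error(synthetic_config(k_com = 800L), "exceed")
  expect_error(
    synthetic_config(n_samples = c(control = 0L, sod1 = 0L, vcp = 0L)),
    "Zero"
  )
})

test_that("null effects give chance-level discrimination, strong effects near-perfect", {
  aucs <- vapply(1:20, function(seed) {
    sim <- generate_cells(synthetic_config(
      seed = seed, d_com = 0, d_vcp = 0, k_com = 2L, k_vcp = 2L,
      n_features = c(area_shape = 2L, texture = 2L, intensity = 2L),
      cells_mean = 120, sigma_sample = 0
    ))
    s <- standardize(sim$table)
    y <- disease_labels(s)
    m <- fit_logistic(s$values, y, lambda = 1)
    roc_auc(predict_profile(m, s$values)$S, y)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.07)

  sim <- generate_cells(synthetic_config(
    seed = 99, d_com = 3, d_vcp = 0, pi_sick = 1, k_com = 10L, k_vcp = 2L,
    n_features = c(area_shape = 15L, texture = 10L, intensity = 10L)
  ))
  s <- standardize(sim$table)
  y <- disease_labels(s)
  m <- fit_logistic(s$values, y, lambda = 1)
  expect_gt(roc_auc(predict_profile(m, s$values)$S, y)$auc, 0.95)
})

test_that("recovery reports grade classifiers against ground truth", {
  set.seed(82)
  sim <- generate_cells(synthetic_config(
    seed = 83, n_features = c(area_shape = 6L, texture = 4L, intensity = 4L),
    k_com = 4L, k_vcp = 4L
  ))
  truth <- sim$truth
  oracle <- tibble::tibble(
    cell_id = truth$cell_id, classifier = "oracle",
    P = ifelse(truth$sick, 0.99, 0.01), S = ifelse(truth$sick, 5, -5)
  )
  rep1 <- recovery_report(oracle, truth)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$sick_fraction_error, 0)

  # uniform random probabilities: accuracy near the majority baseline
  acc <- replicate(30, {
    rnd <- oracle
    rnd$P <- runif(nrow(rnd))
    recovery_report(rnd, truth)$accuracy
  })
  base <- max(mean(truth$sick), 1 - mean(truth$sick))
  expect_lt(abs(mean(acc) - 0.5), 0.08)
  expect_lte(mean(acc), base + 0.05)

  # contribution mass on the true support
  p <- tibble::tibble(
    classifier = "LR", classifier_group = "comALS",
    measurement = colnames(sim$table$values),
    contribution = as.numeric(colnames(sim$table$values) %in%
                                sim$supports$com$measurement)
  )
  p$contribution <- p$contribution / sum(p$contribution)
  class(p) <- c("contribution_profile", class(p))
  rep2 <- recovery_report(oracle, truth, contributions = p,
                          support = sim$supports$com$measurement)
  expect_equal(rep2$support_mass, 1)
})

test_that("a GMM on the leading component recovers the planted sick fraction", {
  sim <- generate_cells(synthetic_config(
    seed = 84, n_samples = c(control = 5L, sod1 = 5L, vcp = 0L),
    cells_mean = 100, d_com = 3, d_vcp = 0, k_com = 20L, k_vcp = 2L,
    n_features = c(area_shape = 30L, texture = 15L, intensity = 15L),
    sigma_sample = 0.2
  ))
  s <- standardize(sim$table)
  d <- decompose(s)
  g <- orient_sick_component(fit_gmm(d$scores[, 1, drop = FALSE],
                                     pc_indices = 1L, seed = 1), s)
  prof <- predict_profile(g, d$scores)
  rep <- recovery_report(prof, sim$truth)
  expect_lt(rep$sick_fraction_error, 0.05)
  expect_gt(rep$accuracy, 0.9)
})

test_that("written datasets round-trip through the reader", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 85, n_features = c(area_shape = 5L, texture = 4L,
                                                    intensity = 4L),
                          k_com = 3L, k_vcp = 3L)
  sim <- simulate_dataset(cfg, dir)
  expect_true(all(file.exists(file.path(
    dir, c("measurements.csv", "annotations.csv", "truth.csv", "config.json")
  ))))
  back <- read_feature_table(file.path(dir, "measurements.csv"),
                             file.path(dir, "annotations.csv"))
  expect_equal(back$values, sim$table$values)
})
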