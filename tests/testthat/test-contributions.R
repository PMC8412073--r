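lr_stub <- function(beta, names = paste0("f", seq_along(beta))) {
  structure(
    list(beta = setNames(c(0.3, beta), c("(Intercept)", names)),
         lambda = 1, n_iter = 1L, feature_names = names),
    class = "lr_model"
  )
}

mlp_stub <- function(W1, W2, names = paste0("f", seq_len(nrow(W1)))) {
  structure(
    list(W1 = W1, b1 = rep(0, ncol(W1)), W2 = W2, b2 = 0,
         hidden = ncol(W1), l2 = 0, seed = 0L, feature_names = names),
    class = "mlp_model"
  )
}

test_that("LR contributions are normalized absolute coefficients", {
  expect_equal(contributions_lr(lr_stub(c(2, 0, 0)))$contribution, c(1, 0, 0))
  expect_equal(contributions_lr(lr_stub(c(1, -1)))$contribution, c(0.5, 0.5))
  expect_error(contributions_lr(lr_stub(c(0, 0))), "degenerate")
  # positive rescaling of the weights changes nothing
  expect_equal(contributions_lr(lr_stub(c(3, -1, 2)))$contribution,
               contributions_lr(lr_stub(10 * c(3, -1, 2)))$contribution)
})

test_that("a duplicated measurement splits its contribution without losing mass", {
  set.seed(60)
  n <- 300
  x <- cbind(sig = rnorm(n), other = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * x[, 1] + 0.8 * x[, 2]))
  m1 <- fit_logistic(x, y, lambda = 1)
  c1 <- contributions_lr(m1)
  x_dup <- cbind(x, sig_copy = x[, 1])
  m2 <- fit_logistic(x_dup, y, lambda = 1)
  c2 <- contributions_lr(m2)
  mass1 <- c1$contribution[c1$measurement == "sig"] /
    c1$contribution[c1$measurement == "other"]
  mass2 <- sum(c2$contribution[c2$measurement %in% c("sig", "sig_copy")]) /
    c2$contribution[c2$measurement == "other"]
  expect_equal(mass2, mass1, tolerance = 0.05)
})

test_that("GMM contributions map the discriminant through the loadings", {
  # identity loadings: a single selected PC is a single measurement
  L <- diag(4)
  rownames(L) <- paste0("f", 1:4)
  d <- structure(list(loadings = L, n_components = 4L), class = "decomposition")
  g <- structure(
    list(weights = c(0.5, 0.5), means = matrix(c(0, 2), 2, 1),
         covariances = array(1, c(1, 1, 2)), pc_indices = 3L,
         sick_component = 2L),
    class = "gmm_model"
  )
  cc <- contributions_gmm(g, d)
  expect_equal(cc$contribution, c(0, 0, 1, 0))

  # 2-D fixture against the brute-force pooled-covariance formula
  set.seed(61)
  Lr <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:2]
  rownames(Lr) <- paste0("f", 1:5)
  d2 <- structure(list(loadings = Lr, n_components = 2L), class = "decomposition")
  S0 <- matrix(c(1.2, 0.3, 0.3, 0.8), 2, 2)
  S1 <- matrix(c(0.9, -0.2, -0.2, 1.1), 2, 2)
  mu <- matrix(c(0, 0, 1.5, -1), 2, 2, byrow = TRUE)
  g2 <- structure(
    list(weights = c(0.6, 0.4), means = mu,
         covariances = array(c(S0, S1), c(2, 2, 2)), pc_indices = 1:2,
         sick_component = 2L),
    class = "gmm_model"
  )
  got <- contributions_gmm(g2, d2)
  v <- abs(Lr %*% solve(0.6 * S0 + 0.4 * S1, mu[2, ] - mu[1, ]))
  expect_equal(got$contribution, drop(v / sum(v)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # a zero-weight second component leaves only the first PC's pattern
  g1 <- g2
  g1$means <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  g1$covariances <- array(c(diag(2), diag(2)), c(2, 2, 2))
  c_both <- contributions_gmm(g1, d2)
  gA <- structure(
    list(weights = c(0.6, 0.4), means = matrix(c(0, 2), 2, 1),
         covariances = array(1, c(1, 1, 2)), pc_indices = 1L,
         sick_component = 2L),
    class = "gmm_model"
  )
  c_one <- contributions_gmm(gA, d2)
  expect_equal(c_both$contribution, c_one$contribution, tolerance = 1e-9)
})

test_that("MLP contributions sum absolute input-output path weights", {
  # hand-built 2-2-1 network: enumerate the four paths
  W1 <- matrix(c(1, -2, 0.5, 3), 2, 2)
  W2 <- c(2, -1)
  cc <- contributions_mlp(mlp_stub(W1, W2))
  manual <- c(abs(1 * 2) + abs(0.5 * -1), abs(-2 * 2) + abs(3 * -1))
  expect_equal(cc$contribution, manual / sum(manual))

  # single nonzero input weight concentrates everything
  cc2 <- contributions_mlp(mlp_stub(matrix(c(0, 4), 2, 1), c(1)))
  expect_equal(cc2$contribution, c(0, 1))

  # permutation equivariance over input order
  set.seed(62)
  W1r <- matrix(rnorm(8), 4, 2)
  perm <- c(3, 1, 4, 2)
  a <- contributions_mlp(mlp_stub(W1r, c(1, -2)))
  b <- contributions_mlp(mlp_stub(W1r[perm, ], c(1, -2),
                                  names = paste0("f", seq_len(4))[perm]))
  expect_equal(b$contribution, a$contribution[perm])
})

test_that("top contributors rank deterministically with lexicographic ties", {
  p <- contributions_lr(lr_stub(c(0.7, 0.2, 0.1), c("b", "a", "c")))
  expect_equal(top_contributors(p, 1)$measurement, "b")
  expect_equal(nrow(top_contributors(p, 3)), 3L)
  tie <- contributions_lr(lr_stub(c(0.5, 0.5), c("zeta", "alpha")))
  expect_equal(top_contributors(tie, 1)$measurement, "alpha")
  expect_error(top_contributors(p, 0), ">= 1")
  expect_error(top_contributors(p, 9), "exceeds")
})

test_that("the category mixed model recovers a planted category preference", {
  set.seed(63)
  tax <- tibble::tibble(
    name = paste0("f", 1:30),
    category = rep(c("area_shape", "texture", "intensity"), each = 10)
  )
  mk_profile <- function(id, grp, area_boost) {
    w <- abs(rnorm(30, 1, 0.1))
    w[1:10] <- w[1:10] * area_boost
    new_p <- tibble::tibble(
      classifier = id, classifier_group = grp,
      measurement = tax$name, contribution = w / sum(w)
    )
    class(new_p) <- c("contribution_profile", class(new_p))
    new_p
  }
  profiles <- list(
    mk_profile("LR", "comALS", 2), mk_profile("MLP", "comALS", 2),
    mk_profile("GMM-com", "comALS", 2),
    mk_profile("sLR", "vcpALS", 1), mk_profile("sMLP", "vcpALS", 1),
    mk_profile("GMM-vcp", "vcpALS", 1)
  )
  res <- category_lmm(profiles, tax)
  area <- res[res$category == "area_shape", ]
  expect_lt(area$effect, 0)             # vcpALS minus comALS
  expect_lt(area$p_value, 0.05)
  expect_gt(area$mean_comALS, area$mean_vcpALS)

  # identical profiles across groups carry no category signal
  same <- list(
    mk_profile("LR", "comALS", 1), mk_profile("MLP", "comALS", 1),
    mk_profile("sLR", "vcpALS", 1), mk_profile("sMLP", "vcpALS", 1)
  )
  res0 <- category_lmm(same, tax)
  expect_true(all(res0$p_value > 0.05))

  expect_error(
    category_lmm(list(mk_profile("LR", "comALS", 1),
                      mk_profile("sLR", "vcpALS", 1),
                      mk_profile("sMLP", "vcpALS", 1)), tax),
    "2 classifiers"
  )
})

test_that("permutation z-scores flag planted enrichment and stay calibrated", {
  tax <- tibble::tibble(
    name = paste0("f", 1:100),
    category = rep(c("area_shape", "texture", "intensity", "other"), each = 25)
  )
  loaded <- tibble::tibble(
    classifier = "LR", classifier_group = "comALS",
    measurement = tax$name,
    contribution = c(rep(0.099, 10), rep(1e-4, 90))
  )
  loaded$contribution <- loaded$contribution / sum(loaded$contribution)
  class(loaded) <- c("contribution_profile", class(loaded))
  z <- category_permutation_z(loaded, tax, n_perm = 1000, seed = 1)
  expect_gt(z$z[z$category == "area_shape"], 5)

  # determinism under the seed
  z2 <- category_permutation_z(loaded, tax, n_perm = 1000, seed = 1)
  expect_identical(z, z2)
  expect_error(category_permutation_z(loaded, tax, n_perm = 50), "at least 100")

  # an exactly uniform profile has a degenerate (zero-variance) null
  unif <- loaded
  unif$contribution <- rep(1 / 100, 100)
  expect_warning(z3 <- category_permutation_z(unif, tax, n_perm = 200, seed = 2),
                 "Degenerate")
  expect_true(all(z3$z == 0))
})

test_that("the N/C-ratio contribution is the designated single column", {
  ft <- toy_feature_table(n = 8L, p = 6L)
  set.seed(64)
  y <- rep(c(0, 1), 4)
  m <- fit_logistic(standardize(ft)$values, y, lambda = 1)
  p <- contributions_lr(m)
  got <- nc_ratio_contribution(p, ft, "SFPQ")
  expect_equal(got, p$contribution[p$measurement == "Intensity_NCRatio_SFPQ"])
  expect_equal(sum(p$contribution), 1, tolerance = 1e-9)
  expect_error(nc_ratio_contribution(p, ft, "ChAT"), "No N/C-ratio")
})
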