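#' Configuration for the synthetic feature-table generator
#'
#' The generator emulates the statistical structure the analysis assumes
#' in a cohort of spinal-cord sections: animal-level random intercepts
#' (each animal shifts all its cells' measurements), a mixture of healthy
#' and sick cells *within* disease tissue, measurement-category block
#' structure (area-shape / texture / intensity named in the CellProfiler
#' dialect, including designated SFPQ and FUS N/C-ratio columns), a
#' dominant VCP-specific effect direction nested with a subtle effect
#' shared by both disease genotypes, and unit Gaussian noise. A sick
#' cell's value is
#' `x = a_sample + d_com * u_com + [vcp] * d_vcp * u_vcp + noise`,
#' with `u` sign vectors supported on `k_com` / `k_vcp` measurements, so
#' `d_*` is the per-affected-measurement shift in noise-sd units. The
#' N/C-ratio entries of the support carry negative sign (mislocalization
#' lowers the ratio).
#'
#' Defaults mirror the study scale: 3 control, 4 SOD1-mutant and 3
#' VCP-mutant animals, ~12 cells per animal (~120 cells), 750 measurements
#' split 300/250/200 across categories, dominant `d_vcp = 2`, subtle
#' `d_com = 0.8`, 70% sick cells in disease tissue, animal-intercept sd
#' 0.5.
#'
#' @param n_samples Named vector of animals per condition.
#' @param cells_mean,cells_dispersion Negative-binomial cell count per
#'   animal (mean and size; large size approaches Poisson); at least 2
#'   cells per animal are kept.
#' @param n_features Named vector of measurements per category.
#' @param d_com,d_vcp Per-measurement effect sizes (noise-sd units).
#' @param k_com,k_vcp Number of measurements carrying each effect.
#' @param pi_sick Sick-cell fraction in disease animals.
#' @param pi_sick_control Sick-cell contamination in control animals.
#' @param sigma_sample Animal random-intercept standard deviation.
#' @param seed Integer seed; the whole table is reproducible from it.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = c(control = 3L, sod1 = 4L, vcp = 3L),
                             cells_mean = 12, cells_dispersion = 50,
                             n_features = c(area_shape = 300L, texture = 250L,
                                            intensity = 200L),
                             d_com = 0.8, d_vcp = 2.0,
                             k_com = 40L, k_vcp = 60L,
                             pi_sick = 0.7, pi_sick_control = 0,
                             sigma_sample = 0.5, seed = 1L) {
  # tolerate list-valued or name-stripped inputs (e.g. configs
  # round-tripped through YAML, which drops vector names)
  n_samples <- unlist(n_samples)
  n_features <- unlist(n_features)
  if (is.null(names(n_samples))) {
    if (length(n_samples) != 3L) abort("`n_samples` must be named or length 3.")
    names(n_samples) <- c("control", "sod1", "vcp")
  }
  if (is.null(names(n_features))) {
    if (length(n_features) != 3L) abort("`n_features` must be named or length 3.")
    names(n_features) <- c("area_shape", "texture", "intensity")
  }
  if (sum(n_samples) < 1L) abort("Zero samples or features.")
  n_samples <- n_samples[n_samples > 0L]
  cfg <- list(
    n_samples = n_samples, cells_mean = cells_mean,
    cells_dispersion = cells_dispersion, n_features = n_features,
    d_com = d_com, d_vcp = d_vcp, k_com = as.integer(k_com),
    k_vcp = as.integer(k_vcp), pi_sick = pi_sick,
    pi_sick_control = pi_sick_control, sigma_sample = sigma_sample,
    seed = as.integer(seed)
  )
  if (sum(n_samples) < 1L || sum(n_features) < 1L) abort("Zero samples or features.")
  for (f in c(cfg$pi_sick, cfg$pi_sick_control)) {
    if (f < 0 || f > 1) abort("Sick fractions must lie in [0, 1].")
  }
  if (cfg$d_com < 0 || cfg$d_vcp < 0 || cfg$sigma_sample < 0) {
    abort("Effect sizes and variance components must be nonnegative.")
  }
  if (cfg$k_com > sum(n_features) || cfg$k_vcp > sum(n_features)) {
    abort("Support sizes exceed the number of measurements.")
  }
  structure(cfg, class = "synthetic_config")
}

synthetic_feature_names <- function(n_features) {
  zern <- expand.grid(m = 0:9, n = 0:9)
  zern <- zern[zern$m <= zern$n, ]
  area <- c(
    paste0("AreaShape_Zernike_", zern$n, "_", zern$m),
    paste0("AreaShape_Shape", seq_len(max(0, n_features[["area_shape"]])))
  )[seq_len(n_features[["area_shape"]])]
  chans <- c("FUS", "SFPQ", "ChAT", "DAPI")
  tex <- paste0(
    "Texture_Entropy_",
    rep(chans, length.out = n_features[["texture"]]), "_",
    seq_len(n_features[["texture"]])
  )
  n_int <- n_features[["intensity"]]
  if (n_int < 2L) abort("Need at least 2 intensity measurements (the N/C ratios).")
  intens <- c(
    "Intensity_NCRatio_SFPQ", "Intensity_NCRatio_FUS",
    paste0(
      "Intensity_MeanIntensity_",
      rep(chans, length.out = max(0L, n_int - 2L)), "_",
      seq_len(max(0L, n_int - 2L))
    )
  )[seq_len(n_int)]
  list(area_shape = area, texture = tex, intensity = intens)
}

#' Generate a synthetic feature table with ground truth
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `table` (a `feature_table`), `truth`
#'   (per-cell tibble: `cell_id`, `sample_id`, `condition`, `sick`,
#'   `sample_intercept`) and `supports` (per-direction tibbles of
#'   measurement names and signed weights).
#' @examples
#' sim <- generate_cells(synthetic_config(seed = 7))
#' dim(sim$table)
#' mean(sim$truth$sick[sim$truth$condition != "control"])
#' @export
generate_cells <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_private_seed(config$seed, generate_cells_impl(config))
}

generate_cells_impl <- function(config) {
  nm <- synthetic_feature_names(config$n_features)
  feats <- unlist(nm, use.names = FALSE)
  M <- length(feats)

  conditions <- rep(names(config$n_samples), config$n_samples)
  sample_ids <- unlist(lapply(names(config$n_samples), function(cc) {
    paste0(cc, "_m", seq_len(config$n_samples[[cc]]))
  }))
  n_cells_per <- pmax(2L, rnbinom(length(sample_ids),
                                  mu = config$cells_mean,
                                  size = config$cells_dispersion))
  cell_sample <- rep(sample_ids, n_cells_per)
  cell_cond <- rep(conditions, n_cells_per)
  n <- length(cell_sample)
  cell_ids <- sprintf("cell_%04d", seq_len(n))

  # effect supports: the shared (com) direction lives on area-shape
  # measurements plus the SFPQ N/C ratio; the dominant vcp direction on
  # texture/intensity plus both N/C ratios
  idx_sfpq <- match("Intensity_NCRatio_SFPQ", feats)
  idx_fus <- match("Intensity_NCRatio_FUS", feats)
  area_idx <- match(nm$area_shape, feats)
  ti_idx <- setdiff(c(match(nm$texture, feats), match(nm$intensity, feats)),
                    c(idx_sfpq, idx_fus))
  com_sup <- c(idx_sfpq, sample(area_idx, min(config$k_com - 1L, length(area_idx))))
  vcp_sup <- c(idx_fus, idx_sfpq,
               sample(ti_idx, min(config$k_vcp - 2L, length(ti_idx))))
  u_com <- numeric(M)
  u_com[com_sup] <- sample(c(-1, 1), length(com_sup), replace = TRUE)
  u_com[idx_sfpq] <- -1           # mislocalization lowers the N/C ratio
  u_vcp <- numeric(M)
  u_vcp[vcp_sup] <- sample(c(-1, 1), length(vcp_sup), replace = TRUE)
  u_vcp[c(idx_sfpq, idx_fus)] <- -1

  intercepts <- setNames(rnorm(length(sample_ids), 0, config$sigma_sample),
                         sample_ids)
  pi_cell <- ifelse(cell_cond == "control", config$pi_sick_control, config$pi_sick)
  sick <- rbinom(n, 1L, pi_cell) == 1L

  x <- matrix(rnorm(n * M), n, M, dimnames = list(cell_ids, feats))
  x <- x + intercepts[cell_sample]
  shift <- outer(as.numeric(sick), config$d_com * u_com) +
    outer(as.numeric(sick & cell_cond == "vcp"), config$d_vcp * u_vcp)
  x <- x + shift

  ann <- tibble(
    cell_id = cell_ids, sample_id = cell_sample, condition = cell_cond,
    stain_panel = NA_character_
  )
  table <- suppressWarnings(as_feature_table(x, ann))
  list(
    table = table,
    truth = tibble(
      cell_id = cell_ids, sample_id = cell_sample, condition = cell_cond,
      sick = sick, sample_intercept = unname(intercepts[cell_sample])
    ),
    supports = list(
      com = tibble(measurement = feats[com_sup], weight = u_com[com_sup]),
      vcp = tibble(measurement = feats[vcp_sup], weight = u_vcp[vcp_sup])
    ),
    config = config
  )
}

#' Write a synthetic dataset to disk
#'
#' Emits the measurement CSV, annotation CSV, per-cell truth CSV and the
#' resolved configuration as JSON.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return The [generate_cells()] result, invisibly.
#' @export
simulate_dataset <- function(config = synthetic_config(), out_dir) {
  sim <- generate_cells(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(
    sim$table,
    file.path(out_dir, "measurements.csv"),
    file.path(out_dir, "annotations.csv")
  )
  readr::write_csv(sim$truth, file.path(out_dir, "truth.csv"))
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' Score a disease profile against generator ground truth
#'
#' @param profile Disease-profile tibble ([predict_profile()]) aligned by
#'   `cell_id` with the truth.
#' @param truth Ground-truth tibble from [generate_cells()].
#' @param threshold Sick-call probability cutoff.
#' @param contributions Optional `contribution_profile`; if given together
#'   with `support`, the fraction of contribution mass landing on the true
#'   effect support is reported.
#' @param support Character vector of truly affected measurement names.
#' @return A one-row tibble: `accuracy` (cell-status), `true_sick_fraction`,
#'   `estimated_sick_fraction`, `sick_fraction_error`, and
#'   `support_mass` when contributions are supplied.
#' @export
recovery_report <- function(profile, truth, threshold = 0.5,
                            contributions = NULL, support = NULL) {
  m <- match(truth$cell_id, profile$cell_id)
  if (anyNA(m)) abort("Profile does not cover every truth cell.")
  P <- profile$P[m]
  called <- P > threshold
  out <- tibble(
    accuracy = mean(called == truth$sick),
    true_sick_fraction = mean(truth$sick),
    estimated_sick_fraction = mean(called),
    sick_fraction_error = abs(mean(called) - mean(truth$sick))
  )
  if (!is.null(contributions) && !is.null(support)) {
    out$support_mass <- sum(
      contributions$contribution[contributions$measurement %in% support]
    )
  }
  out
}
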