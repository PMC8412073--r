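#' Run the end-to-end disease-profiling pipeline
#'
#' Config-driven orchestration of the full analysis graph on any
#' conforming dataset: ingest (or simulate) -> standardize -> decompose ->
#' associate components with phenotype contrasts -> train classifiers ->
#' per-cell disease profiles -> per-animal scores and Welch group tests ->
#' contribution decomposition -> hierarchical clustering. Every stage
#' writes its tables under `out_dir` and the run ends with a manifest
#' echoing all parameters and seeds, so the run is reproducible and
#' resumable from its serialized artifacts. Given the same config and
#' seed, result tables are byte-identical across reruns.
#'
#' @param config A named list (or path to a YAML/JSON file) with keys:
#'   * `simulate`: arguments for [synthetic_config()], or `input`: list
#'     with `values`, `annotations` (file paths) and optional `dialect`;
#'   * `schemes`: phenotype contrasts to test (default `comALS`, `vcpALS`);
#'   * `classifiers`: roster among `"gmm"`, `"lr"`, `"mlp"`, `"slr"`,
#'     `"smlp"` (default all five; censored variants need SOD1 cells);
#'   * `alpha`, `sick_threshold`, `variance_fraction`, `n_pcs`,
#'     `lambda` (LR penalty), `hidden`, `l2` (MLP), `seed`, `out_dir`.
#' @return A list with the main result objects (`table`, `decomposition`,
#'   `associations`, `models`, `profiles`, `sample_scores`, `comparisons`,
#'   `contributions`, `clusters`, `manifest`), invisibly writing all
#'   tables under `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- modifyList(list(
    schemes = c("comALS", "vcpALS"),
    classifiers = c("gmm", "lr", "mlp", "slr", "smlp"),
    alpha = 0.05, sick_threshold = 0.5, variance_fraction = 0.9,
    n_pcs = NULL, lambda = 1, hidden = 25L, l2 = 1e-4,
    seed = 0L, out_dir = tempfile("mnprofile_run_")
  ), config)
  known <- c("gmm", "lr", "mlp", "slr", "smlp")
  bad <- setdiff(cfg$classifiers, known)
  if (length(bad)) {
    abort(sprintf("Unknown classifier(s) in config: %s (known: %s).",
                  paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  run_stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    stages <<- c(stages, name)
    res
  }

  table <- run_stage("ingest", {
    if (!is.null(cfg$input)) {
      read_feature_table(cfg$input$values, cfg$input$annotations,
                         dialect = cfg$input$dialect %||% "cellprofiler")
    } else {
      sim_cfg <- do.call(synthetic_config, c(
        cfg$simulate %||% list(),
        if (is.null(cfg$simulate$seed)) list(seed = cfg$seed)
      ))
      sim <- generate_cells(sim_cfg)
      readr::write_csv(sim$truth, file.path(cfg$out_dir, "truth.csv"))
      sim$table
    }
  })

  scaled <- run_stage("standardize", {
    s <- standardize(table)
    write_feature_table(
      s, file.path(cfg$out_dir, "measurements_scaled.csv"),
      file.path(cfg$out_dir, "annotations.csv")
    )
    s
  })

  dec <- run_stage("decompose", {
    d <- decompose(scaled)
    readr::write_csv(tidy(d), file.path(cfg$out_dir, "spectrum.csv"))
    jsonlite::write_json(
      as.list(glance(d)), file.path(cfg$out_dir, "spectrum_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
    d
  })

  assoc <- run_stage("associate", {
    schemes <- intersect(cfg$schemes, compatible_schemes(scaled$cells))
    if (!length(schemes)) abort("No configured contrast scheme fits the conditions present.")
    a <- map(schemes, function(sc) {
      associate_pcs(dec, sc, n_pcs = cfg$n_pcs, alpha = cfg$alpha)
    }) %>% setNames(schemes)
    readr::write_csv(bind_rows(a), file.path(cfg$out_dir, "pc_associations.csv"))
    a
  })

  models <- run_stage("train", {
    train_roster(scaled, dec, assoc, cfg)
  })

  profiles <- run_stage("score", {
    prof <- bind_rows(imap(models, function(m, id) {
      newdata <- if (inherits(m, "gmm_model")) dec$scores else scaled$values
      predict_profile(m, newdata, classifier_id = id)
    }))
    readr::write_csv(prof, file.path(cfg$out_dir, "disease_profiles.csv"))
    prof
  })

  sample_scores <- run_stage("aggregate", {
    ss <- aggregate_samples(profiles, scaled, threshold = cfg$sick_threshold)
    readr::write_csv(ss, file.path(cfg$out_dir, "sample_scores.csv"))
    ss
  })

  comparisons <- run_stage("compare", {
    cmp <- compare_to_control(sample_scores, metric = "mean_P")
    auc <- profiles %>%
      group_by(.data$classifier) %>%
      summarise(auc = roc_auc(.data$S, disease_labels(scaled))$auc)
    readr::write_csv(cmp, file.path(cfg$out_dir, "group_comparisons.csv"))
    readr::write_csv(auc, file.path(cfg$out_dir, "auc.csv"))
    list(welch = cmp, auc = auc)
  })

  contribs <- run_stage("contribute", {
    cp <- imap(models, function(m, id) {
      grp <- classifier_group_of(id)
      if (inherits(m, "gmm_model")) contributions_gmm(m, dec, id, grp)
      else if (inherits(m, "lr_model")) contributions_lr(m, id, grp)
      else contributions_mlp(m, id, grp)
    })
    readr::write_csv(bind_rows(cp), file.path(cfg$out_dir, "contributions.csv"))
    top <- map(cp, top_contributors, k = min(5L, nrow(cp[[1]])))
    jsonlite::write_json(top, file.path(cfg$out_dir, "top_contributors.json"),
                         auto_unbox = TRUE, digits = NA)
    cp
  })

  clusters <- run_stage("cluster", {
    wide <- profiles %>%
      tidyr::pivot_wider(names_from = "classifier", values_from = c("P", "S")) %>%
      as.data.frame()
    cell_dend <- hclust_average(wide)
    cmat <- bind_rows(contribs) %>%
      tidyr::pivot_wider(
        id_cols = "classifier", names_from = "measurement",
        values_from = "contribution"
      ) %>% as.data.frame()
    clf_dend <- if (nrow(cmat) >= 2L) hclust_average(cmat) else NULL
    labels <- cut_k(cell_dend, k = min(3L, cell_dend$n))
    comp <- cluster_composition(labels, scaled)
    readr::write_csv(comp, file.path(cfg$out_dir, "cell_cluster_composition.csv"))
    readr::write_csv(tidy(cell_dend), file.path(cfg$out_dir, "cell_dendrogram.csv"))
    list(cells = cell_dend, classifiers = clf_dend, labels = labels,
         composition = comp)
  })

  manifest <- list(
    package = "mnprofile",
    version = as.character(utils::packageVersion("mnprofile")),
    stages = stages,
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    n_cells = nrow(table$values),
    n_measurements = ncol(table$values)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    table = scaled, decomposition = dec, associations = assoc,
    models = models, profiles = profiles, sample_scores = sample_scores,
    comparisons = comparisons, contributions = contribs, clusters = clusters,
    manifest = manifest, out_dir = cfg$out_dir
  ))
}

compatible_schemes <- function(ann) {
  present <- unique(ann$condition)
  out <- character()
  if ("control" %in% present && any(c("sod1", "vcp") %in% present) &&
      !"sals" %in% present) out <- c(out, "comALS", if ("vcp" %in% present) "vcpALS")
  if (all(c("control", "sals") %in% present) &&
      !any(c("sod1", "vcp") %in% present)) out <- c(out, "sALS")
  out
}

classifier_group_of <- function(id) {
  if (grepl("^(slr|smlp|sLR|sMLP|GMM-vcp)", id)) "vcpALS" else "comALS"
}

# Assign each component to the contrast scheme where it is most
# significant: a component associated with both comALS and vcpALS (the
# vcp-dominant direction correlates with both indicators) belongs to the
# scheme with the smaller p-value.
exclusive_selection <- function(assoc) {
  if (length(assoc) == 1L) {
    a <- assoc[[1]]
    a$owner <- a$scheme
    return(setNames(list(a), names(assoc)))
  }
  pmat <- vapply(assoc, function(a) a$p_value, numeric(nrow(assoc[[1]])))
  owner <- names(assoc)[max.col(-pmat, ties.method = "first")]
  lapply(assoc, function(a) {
    a$owner <- owner
    a
  })
}

# Fit the configured classifier roster. GMM classifiers are fitted on the
# phenotype-selected principal components (up to the 2 most significant
# per scheme, after exclusive scheme assignment; the scheme's
# smallest-p component if none passes alpha).
train_roster <- function(scaled, dec, assoc, cfg) {
  y <- disease_labels(scaled)
  models <- list()
  for (cl in cfg$classifiers) {
    if (cl == "lr") {
      models[["LR"]] <- fit_logistic(scaled$values, y, lambda = cfg$lambda)
    } else if (cl == "mlp") {
      models[["MLP"]] <- fit_mlp(scaled$values, y, hidden = cfg$hidden,
                                 l2 = cfg$l2, seed = cfg$seed)
    } else if (cl %in% c("slr", "smlp")) {
      if (!all(c("control", "vcp") %in% scaled$cells$condition)) next
      keep <- c("control", "vcp")
      id <- if (cl == "slr") "sLR" else "sMLP"
      models[[id]] <- if (cl == "slr") {
        fit_censored("lr", scaled, keep, lambda = cfg$lambda)
      } else {
        fit_censored("mlp", scaled, keep, hidden = cfg$hidden, l2 = cfg$l2,
                     seed = cfg$seed)
      }
    } else if (cl == "gmm") {
      owned <- exclusive_selection(assoc)
      for (sc in names(owned)) {
        sel <- owned[[sc]] %>%
          filter(.data$owner == sc) %>%
          arrange(.data$p_value)
        pcs <- sel$component[sel$selected]
        if (!length(pcs)) pcs <- sel$component[1L]
        if (!length(pcs) || all(is.na(pcs))) {
          pcs <- owned[[sc]]$component[which.min(owned[[sc]]$p_value)]
        }
        pcs <- sort(head(pcs, 2L))
        id <- paste0("GMM-", sc, "-PC", paste(pcs, collapse = ","))
        m <- fit_gmm(dec$scores[, pcs, drop = FALSE], pc_indices = pcs,
                     seed = cfg$seed)
        models[[id]] <- orient_sick_component(m, scaled)
      }
    }
  }
  if (!length(models)) abort("No classifier could be trained under this config.")
  models
}
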