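#' Per-cell morphological feature tables
#'
#' A `feature_table` bundles the three pieces every downstream stage needs:
#' a numeric cells-by-measurements matrix, a measurement taxonomy
#' (category / compartment / channel for every column, see
#' [classify_measurement()]), and per-cell annotations (animal or donor id,
#' condition label, stain panel). Cells are always rows and measurements
#' always columns.
#'
#' `as_feature_table()` builds one from in-memory data frames;
#' [read_feature_table()] from delimited files. Validation rejects missing
#' or non-numeric values, duplicated cell ids, and cells without an
#' annotation.
#'
#' @param values A data frame whose first (or `cell_id`-named) column holds
#'   cell identifiers and whose remaining columns are numeric measurements,
#'   or a numeric matrix with rownames.
#' @param annotations A data frame with columns `cell_id`, `sample_id`,
#'   `condition` and optionally `stain_panel`.
#' @param dialect Measurement-naming dialect, see [classify_measurement()].
#' @param scaled Whether the values are already standardized.
#'
#' @return An object of class `feature_table` with elements `values`
#'   (numeric matrix), `measurements` (tibble taxonomy), `cells` (tibble
#'   annotations), `scaled` (flag) and `dropped` (names of columns removed
#'   by [standardize()]).
#' @examples
#' vals <- data.frame(
#'   cell_id = c("c1", "c2", "c3"),
#'   AreaShape_Area = c(100, 120, 90),
#'   Intensity_MeanIntensity_FUS = c(0.2, 0.4, 0.1)
#' )
#' ann <- data.frame(
#'   cell_id = c("c1", "c2", "c3"),
#'   sample_id = c("m1", "m1", "m2"),
#'   condition = c("control", "control", "vcp")
#' )
#' ft <- as_feature_table(vals, ann)
#' dim(ft)
#' @export
as_feature_table <- function(values, annotations, dialect = "cellprofiler",
                             scaled = FALSE) {
  if (is.matrix(values)) {
    if (nrow(values) == 0L || ncol(values) == 0L) abort("Empty feature table.")
    if (is.null(rownames(values))) abort("Matrix `values` must have cell-id rownames.")
    mat <- values
  } else {
    values <- as.data.frame(values)
    idcol <- if ("cell_id" %in% names(values)) "cell_id" else names(values)[[1]]
    ids <- as.character(values[[idcol]])
    mat <- as.matrix(values[setdiff(names(values), idcol)])
    rownames(mat) <- ids
  }
  if (nrow(mat) == 0L || ncol(mat) == 0L) abort("Empty feature table.")
  if (!is.numeric(mat)) {
    bad <- colnames(mat)[!apply(mat, 2L, function(z) is.numeric(z) || !anyNA(suppressWarnings(as.numeric(z))))]
    abort(sprintf(
      "Non-numeric measurement column(s): %s",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  storage.mode(mat) <- "double"
  if (anyNA(mat) || any(!is.finite(mat))) {
    abort("Feature table contains missing or non-finite values; rows must be complete.")
  }
  ids <- rownames(mat)
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate cell id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }

  ann <- as_tibble(annotations)
  req <- c("cell_id", "sample_id", "condition")
  if (!all(req %in% names(ann))) {
    abort(sprintf("Annotations must have columns %s.", paste(req, collapse = ", ")))
  }
  ann <- ann %>% mutate(
    cell_id = as.character(.data$cell_id),
    sample_id = as.character(.data$sample_id),
    condition = as.character(.data$condition),
    stain_panel = if ("stain_panel" %in% names(ann)) as.character(.data$stain_panel) else NA_character_
  ) %>%
    select("cell_id", "sample_id", "condition", "stain_panel")
  if (anyDuplicated(ann$cell_id)) abort("Duplicate cell id(s) in annotations.")
  orphan <- setdiff(ids, ann$cell_id)
  if (length(orphan)) {
    abort(sprintf("Cell(s) present in values but missing from annotations: %s",
                  paste(head(orphan, 5L), collapse = ", ")))
  }
  bad_cond <- ann %>%
    filter(.data$cell_id %in% ids) %>%
    distinct(.data$sample_id, .data$condition) %>%
    count(.data$sample_id) %>%
    filter(.data$n > 1L)
  if (nrow(bad_cond)) {
    abort(sprintf("Sample(s) mapped to more than one condition: %s",
                  paste(bad_cond$sample_id, collapse = ", ")))
  }
  cells <- ann[match(ids, ann$cell_id), , drop = FALSE]

  structure(
    list(
      values = mat,
      measurements = measurement_taxonomy(colnames(mat), dialect = dialect),
      cells = cells,
      scaled = isTRUE(scaled),
      dropped = character()
    ),
    class = "feature_table"
  )
}

#' Read a feature table from delimited files
#'
#' Reads a cells-by-measurements values file and a cell annotation file
#' (comma- or tab-delimited, auto-detected) and returns a validated
#' [feature table][as_feature_table]. Column order of the values file is
#' preserved.
#'
#' @param values_path Path to the measurement table; first column (or a
#'   column named `cell_id`) holds cell identifiers.
#' @param annotations_path Path to the annotation table with columns
#'   `cell_id`, `sample_id`, `condition` and optionally `stain_panel`.
#' @inheritParams as_feature_table
#' @return A `feature_table`.
#' @export
read_feature_table <- function(values_path, annotations_path,
                               dialect = "cellprofiler") {
  for (p in c(values_path, annotations_path)) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p))
  }
  vals <- readr::read_delim(
    values_path, delim = sniff_delim(values_path),
    show_col_types = FALSE, progress = FALSE
  )
  ann <- readr::read_delim(
    annotations_path, delim = sniff_delim(annotations_path),
    show_col_types = FALSE, progress = FALSE
  )
  as_feature_table(vals, ann, dialect = dialect)
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) >
      lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))) "\t" else ","
}

#' Write a feature table to CSV with a JSON schema sidecar
#'
#' Writes the values (cell_id + measurement columns, order preserved), the
#' annotations, and a sidecar JSON describing the measurement taxonomy and
#' scaling state.
#'
#' @param table A `feature_table`.
#' @param values_path,annotations_path Output CSV paths.
#' @param schema_path Optional JSON sidecar path (default: `values_path`
#'   with extension `.schema.json`).
#' @return `table`, invisibly.
#' @export
write_feature_table <- function(table, values_path, annotations_path,
                                schema_path = NULL) {
  stopifnot(inherits(table, "feature_table"))
  df <- tibble(cell_id = rownames(table$values)) %>%
    dplyr::bind_cols(as_tibble(table$values))
  readr::write_csv(df, values_path)
  readr::write_csv(table$cells, annotations_path)
  schema_path <- schema_path %||% sub("(\\.[a-zA-Z]+)?$", ".schema.json", values_path)
  jsonlite::write_json(
    list(
      n_cells = nrow(table$values),
      n_measurements = ncol(table$values),
      scaled = table$scaled,
      dropped = table$dropped,
      measurements = table$measurements
    ),
    schema_path, auto_unbox = TRUE, digits = NA
  )
  invisible(table)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d cells x %d measurements%s\n",
    nrow(x$values), ncol(x$values), if (x$scaled) " (standardized)" else ""
  ))
  cat("conditions:",
      paste(sprintf("%s (%d)", names(table(x$cells$condition)),
                    table(x$cells$condition)), collapse = ", "), "\n")
  print(count(x$measurements, .data$category), n = Inf)
  invisible(x)
}

#' @describeIn as_feature_table Long tibble (cell_id, sample_id, condition,
#'   measurement, category, value) view of a feature table.
#' @param x A `feature_table`.
#' @param ... Unused.
#' @export
tidy.feature_table <- function(x, ...) {
  as_tibble(x$values) %>%
    mutate(cell_id = rownames(x$values)) %>%
    tidyr::pivot_longer(-"cell_id", names_to = "measurement", values_to = "value") %>%
    left_join(x$cells, by = "cell_id") %>%
    left_join(
      x$measurements %>% rename(measurement = "name"),
      by = "measurement"
    ) %>%
    select("cell_id", "sample_id", "condition", "measurement",
           "category", "compartment", "channel", "value")
}

#' Locate the nuclear/cytoplasmic intensity-ratio measurement of a channel
#'
#' The N/C ratio of an RNA-binding protein (reduced in ALS motor neurons,
#' indicating nucleus-to-cytoplasm mislocalization) is a single designated
#' intensity measurement per channel. Under the default dialect it is a
#' column whose name contains an `NCRatio` token together with the channel
#' name, e.g. `Intensity_NCRatio_SFPQ`.
#'
#' @param table A `feature_table`.
#' @param channel Channel name, e.g. `"SFPQ"` or `"FUS"`.
#' @return The matching column index (named by the measurement).
#' @export
select_nc_ratio <- function(table, channel) {
  stopifnot(inherits(table, "feature_table"))
  nm <- table$measurements$name
  hit <- which(
    grepl("NC[_]?Ratio", nm, ignore.case = TRUE) &
      toupper(table$measurements$channel %||% "") == toupper(channel) &
      !is.na(table$measurements$channel)
  )
  if (length(hit) == 0L) {
    abort(sprintf("No N/C-ratio measurement found for channel '%s'.", channel))
  }
  if (length(hit) > 1L) {
    abort(sprintf("Ambiguous N/C-ratio measurement for channel '%s': %s",
                  channel, paste(nm[hit], collapse = ", ")))
  }
  setNames(hit, nm[hit])
}
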