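#' Measurement-naming dialects
#'
#' High-content profiling software exports measurement columns whose names
#' encode what was measured (shape, texture, staining intensity), in which
#' cellular compartment, and for which fluorescence channel. A *dialect* is a
#' small rule set that maps a measurement name to this taxonomy. The default
#' `"cellprofiler"` dialect understands CellProfiler-style names such as
#' `AreaShape_Zernike_4_2`, `Texture_Contrast_DAPI_3`, or
#' `Intensity_MeanIntensity_FUS_Nucleus`.
#'
#' Categories are `area_shape`, `texture`, `intensity`; anything unmatched
#' falls back to `other` with a warning. Compartments (`nucleus`,
#' `cytoplasm`, `whole_cell`, `unknown`) and channels (e.g. `FUS`, `SFPQ`,
#' `ChAT`, `DAPI`) are recovered from name tokens when present.
#'
#' @param name Measurement name (non-empty string).
#' @param dialect Dialect identifier; currently `"cellprofiler"`, or a data
#'   frame with columns `name`, `category` and optionally `compartment`,
#'   `channel`, used as an explicit lookup that overrides the rules.
#' @param quiet Suppress the unmatched-name warning.
#'
#' @return A one-row tibble with columns `name`, `category`, `compartment`,
#'   `channel`.
#' @examples
#' classify_measurement("AreaShape_Zernike_4_2")
#' classify_measurement("Intensity_MeanIntensity_FUS_Nucleus")
#' @export
classify_measurement <- function(name, dialect = "cellprofiler", quiet = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a single non-empty string.")
  }
  if (is.data.frame(dialect)) {
    hit <- dialect[dialect$name == name, , drop = FALSE]
    if (nrow(hit) == 1L) {
      return(tibble(
        name = name,
        category = as.character(hit$category),
        compartment = if ("compartment" %in% names(hit)) as.character(hit$compartment) else "unknown",
        channel = if ("channel" %in% names(hit)) as.character(hit$channel) else NA_character_
      ))
    }
    # fall through to the default rules for unmapped names
  } else if (!identical(dialect, "cellprofiler")) {
    abort(sprintf("Unknown naming dialect '%s'.", dialect))
  }

  category <- if (grepl("^(AreaShape|Neighbors)_", name)) {
    "area_shape"
  } else if (grepl("^(Texture|Granularity|RadialDistribution)_", name)) {
    "texture"
  } else if (grepl("^Intensity", name)) {
    "intensity"
  } else {
    if (!quiet) warn(sprintf("Measurement '%s' matched no category rule; set to 'other'.", name))
    "other"
  }
  toks <- strsplit(name, "_", fixed = TRUE)[[1]]
  compartment <- if (any(grepl("^nuc", toks, ignore.case = TRUE))) {
    "nucleus"
  } else if (any(grepl("^cyto", toks, ignore.case = TRUE))) {
    "cytoplasm"
  } else if (any(tolower(toks) %in% c("cell", "wholecell", "mn"))) {
    "whole_cell"
  } else {
    "unknown"
  }
  known_channels <- c("FUS", "SFPQ", "CHAT", "DAPI")
  chan <- toks[toupper(toks) %in% known_channels]
  tibble(
    name = name, category = category, compartment = compartment,
    channel = if (length(chan)) toupper(chan[[1]]) else NA_character_
  )
}

# Vectorized taxonomy for a whole name vector; single warning listing
# unmatched names.
measurement_taxonomy <- function(names, dialect = "cellprofiler") {
  info <- purrr::map(names, classify_measurement, dialect = dialect, quiet = TRUE) %>%
    bind_rows()
  unmatched <- info$name[info$category == "other"]
  if (length(unmatched)) {
    warn(sprintf(
      "%d measurement(s) matched no category rule (set to 'other'): %s",
      length(unmatched), paste(head(unmatched, 5L), collapse = ", ")
    ))
  }
  info
}
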