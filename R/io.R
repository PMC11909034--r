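#' Read a wide protein intensity table
#'
#' Parses a tab-separated proteins-by-samples table: first column protein
#' IDs, header row sample IDs, empty cells (or a configured sentinel) for
#' missing measurements. Values are raw-scale intensities.
#'
#' @param path Path to a TSV file.
#' @param platform `"TMT"` or `"LFQ"`.
#' @param na Strings to treat as missing, in addition to empty cells.
#' @return A raw-scale [intensity_matrix()].
#' @export
read_intensity_table <- function(path, platform = c("TMT", "LFQ"), na = c("", "NA")) {
  platform <- match.arg(platform)
  hdr <- names(readr::read_tsv(path, n_max = 0, show_col_types = FALSE,
                               name_repair = "minimal"))
  if (length(hdr) < 2) abort(sprintf("'%s': expected protein ID column plus >= 1 sample column.", path))
  if (anyDuplicated(hdr)) {
    abort(sprintf("Duplicate sample IDs in header of %s: %s.", path,
                  paste(unique(hdr[duplicated(hdr)]), collapse = ", ")))
  }
  spec <- do.call(readr::cols, c(
    setNames(list(readr::col_character()), hdr[1]),
    list(.default = readr::col_double())
  ))
  df <- readr::read_tsv(path, na = na, show_col_types = FALSE, col_types = spec)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("Duplicate protein IDs in ", path, ": ", paste(dup, collapse = ", ")))
  }
  values <- as.matrix(df[, -1])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    abort(sprintf("Negative intensity at protein '%s', sample '%s' in %s.",
                  ids[neg[1, 1]], colnames(values)[neg[1, 2]], path))
  }
  intensity_matrix(values, platform = platform, scale = "raw")
}

#' Write an intensity matrix as TSV
#'
#' Inverse of [read_intensity_table()]: missing entries become empty cells;
#' protein and sample order is preserved so a write/read round trip is
#' lossless.
#'
#' @param x An `intensity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(x, path) {
  df <- tibble::as_tibble(x$values, rownames = "protein_id")
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `patient_id`,
#'   `timepoint_months`, `platform`, `batch_id`.
#' @param schedule Allowed timepoints in months.
#' @return A validated tibble (see [sample_meta()]).
#' @export
read_sample_meta <- function(path, schedule = default_schedule()) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  sample_meta(df, schedule = schedule)
}

# Columns a clinical table may carry besides the keys; cytology percentages
# are any columns prefixed "pct_".
clinical_value_cols <- c("hfmse", "qalb", "lactate", "glucose",
                         "total_protein", "total_cells_per_100ul")

#' Read a long-format clinical table
#'
#' One row per patient-timepoint with the Hammersmith Functional Motor Scale
#' Expanded score (`hfmse`, 0-66), routine CSF chemistry (`qalb`, `lactate`,
#' `glucose`, `total_protein`), the total CSF cell count per 100 microlitre
#' (`total_cells_per_100ul`) and cytology percentages in `pct_<celltype>`
#' columns. Missing fields are allowed and kept as `NA`.
#'
#' @param path TSV path.
#' @return A validated tibble (see [clinical_records()]).
#' @export
read_clinical_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (nrow(df) == 0) {
    warn(sprintf("Clinical table '%s' is empty.", path))
    return(tibble::as_tibble(df))
  }
  clinical_records(df)
}

#' Validate clinical records
#'
#' @param df Data frame with `patient_id`, `timepoint_months` and any of the
#'   clinical value columns.
#' @return The validated tibble.
#' @export
clinical_records <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(c("patient_id", "timepoint_months") %in% names(df))) {
    abort("Clinical table needs `patient_id` and `timepoint_months` columns.")
  }
  if ("hfmse" %in% names(df)) {
    bad <- which(!is.na(df$hfmse) & (df$hfmse < 0 | df$hfmse > 66))
    if (length(bad)) {
      abort(sprintf("HFMSE outside [0, 66] for patient %s at month %s (value %s).",
                    df$patient_id[bad[1]], df$timepoint_months[bad[1]], df$hfmse[bad[1]]))
    }
  }
  for (col in intersect(c("qalb", "lactate", "glucose", "total_protein",
                          "total_cells_per_100ul"), names(df))) {
    if (any(df[[col]] < 0, na.rm = TRUE)) abort(sprintf("Negative values in `%s`.", col))
  }
  pct_cols <- grep("^pct_", names(df), value = TRUE)
  if (length(pct_cols)) {
    sums <- rowSums(df[pct_cols], na.rm = FALSE)
    bad <- which(!is.na(sums) & abs(sums - 100) > 0.5)
    if (length(bad)) {
      abort(sprintf("Cytology percentages sum to %.2f (not 100 +/- 0.5) for patient %s month %s.",
                    sums[bad[1]], df$patient_id[bad[1]], df$timepoint_months[bad[1]]))
    }
  }
  df
}

#' Absolute CSF cell counts from cytology percentages
#'
#' Differential cytology is reported as percentages per cell type; the
#' absolute number of each cell type per 100 microlitre CSF is the
#' percentage multiplied by the total cell count per 100 microlitre.
#'
#' @param cytology_percent Named numeric vector of percentages (>= 0).
#' @param total_cells_per_100ul Total cell count per 100 microlitre.
#' @return Named numeric vector of absolute counts per 100 microlitre.
#' @examples
#' absolute_cell_counts(c(lymphocyte = 80, monocyte = 20), 300)
#' @export
absolute_cell_counts <- function(cytology_percent, total_cells_per_100ul) {
  if (any(cytology_percent < 0)) abort("Cytology percentages must be >= 0.")
  if (sum(cytology_percent) > 100.5) {
    abort(sprintf("Cytology percentages sum to %.2f > 100.5.", sum(cytology_percent)))
  }
  if (total_cells_per_100ul < 0) abort("Total cell count must be >= 0.")
  cytology_percent / 100 * total_cells_per_100ul
}

#' Cross-check cohort tables
#'
#' Joins intensity matrix, sample metadata and clinical records and reports
#' inconsistencies (orphan samples, duplicate patient-timepoints, schedule
#' violations, clinical rows without any sample) without failing: the report
#' is a tibble with one row per issue and a severity level.
#'
#' @param matrix An `intensity_matrix`.
#' @param meta Sample metadata tibble.
#' @param clinical Clinical records tibble (optional).
#' @param schedule Allowed timepoints.
#' @return A tibble with columns `severity` (`"error"`/`"warning"`), `issue`
#'   and `detail`; zero rows for a consistent cohort.
#' @export
validate_cohort <- function(matrix, meta, clinical = NULL,
                            schedule = default_schedule()) {
  issues <- list()
  add <- function(severity, issue, detail) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      severity = severity, issue = issue, detail = detail)
  }
  orphan <- setdiff(sample_ids(matrix), meta$sample_id)
  for (s in orphan) add("error", "orphan sample", sprintf("sample '%s' in matrix but not metadata", s))
  unused <- setdiff(meta$sample_id[meta$platform == matrix$platform], sample_ids(matrix))
  for (s in unused) add("warning", "unmatched metadata", sprintf("metadata sample '%s' absent from matrix", s))
  key <- paste(meta$patient_id, meta$timepoint_months, meta$platform, sep = "|")
  for (k in unique(key[duplicated(key)])) {
    add("error", "duplicate", sprintf("multiple samples for (patient, timepoint, platform) = (%s)", gsub("\\|", ", ", k)))
  }
  bad_tp <- setdiff(unique(meta$timepoint_months), schedule)
  for (tp in bad_tp) add("error", "schedule violation", sprintf("timepoint %s months not in schedule", tp))
  if (!is.null(clinical) && nrow(clinical)) {
    ckey <- paste(clinical$patient_id, clinical$timepoint_months, sep = "|")
    for (k in unique(ckey[duplicated(ckey)])) {
      add("error", "duplicate clinical", sprintf("multiple clinical rows for (patient, timepoint) = (%s)", gsub("\\|", ", ", k)))
    }
    mkey <- unique(paste(meta$patient_id, meta$timepoint_months, sep = "|"))
    for (k in setdiff(ckey, mkey)) {
      add("warning", "clinical without sample", sprintf("clinical row (%s) has no sampled visit", gsub("\\|", ", ", k)))
    }
  }
  if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(severity = character(), issue = character(), detail = character())
  }
}
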