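#' Protein intensity matrix
#'
#' The central container of the pipeline: a proteins-by-samples numeric
#' matrix with missing values stored as `NA`, tagged with the quantification
#' platform and the scale the values live on. The scale tag tracks the
#' matrix through the pipeline: `"raw"` intensities come off the instrument
#' summaries, `"vst"` after the variance-stabilizing transformation (a
#' log2-compatible scale, so differences are log2 fold changes), and
#' `"zscore"` after per-protein standardization.
#'
#' @param values Numeric matrix, proteins in rows and samples in columns,
#'   with rownames (protein IDs) and colnames (sample IDs). `NA` marks a
#'   missing (undetected) measurement.
#' @param platform `"TMT"` or `"LFQ"`.
#' @param scale One of `"raw"`, `"log2"`, `"vst"`, `"zscore"`. Raw-scale
#'   values must be non-negative.
#' @return An `intensity_matrix` object.
#' @examples
#' m <- matrix(c(10, 20, 30, 40), nrow = 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' im <- intensity_matrix(m, platform = "TMT")
#' protein_ids(im)
#' @export
intensity_matrix <- function(values, platform = c("TMT", "LFQ"),
                             scale = c("raw", "log2", "vst", "zscore")) {
  platform <- match.arg(platform)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (nrow(values) > 0 && is.null(rownames(values)) ||
      ncol(values) > 0 && is.null(colnames(values))) {
    abort("`values` must carry protein IDs as rownames and sample IDs as colnames.")
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    abort(paste0("Duplicate protein IDs: ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    abort(paste0("Duplicate sample IDs: ", paste(dup, collapse = ", ")))
  }
  obs <- values[!is.na(values)]
  if (any(!is.finite(obs))) abort("Non-missing intensities must be finite.")
  if (scale == "raw" && any(obs < 0)) {
    abort("Raw-scale intensities must be non-negative.")
  }
  structure(list(values = values, platform = platform, scale = scale),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf(
    "<intensity_matrix> %d proteins x %d samples [%s, %s scale, %.1f%% missing]\n",
    nrow(x$values), ncol(x$values), x$platform, x$scale,
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @rdname intensity_matrix
#' @param x An `intensity_matrix`.
#' @export
protein_ids <- function(x) rownames(x$values)

#' @rdname intensity_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname intensity_matrix
#' @export
missing_mask <- function(x) is.na(x$values)

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Long-format view of an intensity matrix
#'
#' @param x An `intensity_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `protein_id`, `sample_id`, `intensity`
#'   (`NA` when missing), `platform` and `scale`.
#' @importFrom tibble as_tibble
#' @export
as_tibble.intensity_matrix <- function(x, ...) {
  tibble::tibble(
    protein_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    intensity = as.vector(x$values),
    platform = x$platform,
    scale = x$scale
  )
}

#' Subset an intensity matrix by protein and/or sample IDs
#'
#' @param x An `intensity_matrix`.
#' @param proteins,samples Character vectors of IDs to keep (default: all).
#' @return An `intensity_matrix` restricted to the requested rows/columns,
#'   in the requested order.
#' @export
subset_intensity <- function(x, proteins = NULL, samples = NULL) {
  proteins <- proteins %||% rownames(x$values)
  samples <- samples %||% colnames(x$values)
  miss_p <- setdiff(proteins, rownames(x$values))
  miss_s <- setdiff(samples, colnames(x$values))
  if (length(miss_p)) abort(paste0("Unknown proteins: ", paste(head(miss_p, 5), collapse = ", ")))
  if (length(miss_s)) abort(paste0("Unknown samples: ", paste(head(miss_s, 5), collapse = ", ")))
  intensity_matrix(x$values[proteins, samples, drop = FALSE], x$platform, x$scale)
}

# Internal: replace values while keeping tags, optionally retagging scale.
set_values <- function(x, values, scale = x$scale) {
  intensity_matrix(values, platform = x$platform, scale = scale)
}

#' Sample metadata table
#'
#' Validates the per-sample design table linking samples to patients,
#' timepoints, platform and batch (TMT plex or LFQ run).
#'
#' @param meta A data frame with columns `sample_id`, `patient_id`,
#'   `timepoint_months`, `platform`, `batch_id`.
#' @param schedule Allowed timepoints in months.
#' @return The validated metadata as a tibble.
#' @export
sample_meta <- function(meta, schedule = default_schedule()) {
  required <- c("sample_id", "patient_id", "timepoint_months", "platform", "batch_id")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort(paste0("Metadata is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  meta <- tibble::as_tibble(meta)
  if (anyDuplicated(meta$sample_id)) abort("Duplicate sample_id in metadata.")
  key <- paste(meta$patient_id, meta$timepoint_months, meta$platform)
  if (anyDuplicated(key)) {
    abort("Duplicate (patient_id, timepoint_months, platform) in metadata.")
  }
  if (!all(meta$platform %in% c("TMT", "LFQ"))) {
    abort("platform must be 'TMT' or 'LFQ'.")
  }
  bad_tp <- setdiff(unique(meta$timepoint_months), schedule)
  if (length(bad_tp)) {
    abort(paste0("Timepoints outside the schedule: ", paste(bad_tp, collapse = ", ")))
  }
  meta
}

#' Study visit schedule
#'
#' Months at which CSF was sampled: baseline (pre-treatment) and six
#' on-treatment visits.
#'
#' @return Integer vector of months.
#' @export
default_schedule <- function() c(0L, 2L, 10L, 18L, 26L, 34L, 42L)
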