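#' Baseline-to-timepoint changes of protein intensities
#'
#' For every protein and patient with data at both baseline and a later
#' visit, the change `value(t) - value(baseline)`. On the vst scale these
#' are per-patient log2 fold changes.
#'
#' @param matrix An [intensity_matrix()].
#' @param meta Sample metadata.
#' @param baseline Baseline timepoint (months).
#' @param include_baseline Keep the (identically zero) baseline rows;
#'   excluded by default because they are uninformative for correlation.
#' @return A tibble: `feature` (protein ID), `patient_id`,
#'   `timepoint_months`, `delta`.
#' @export
protein_deltas <- function(matrix, meta, baseline = 0, include_baseline = FALSE) {
  meta <- meta[match(sample_ids(matrix), meta$sample_id), ]
  long <- tibble::as_tibble(matrix) |>
    dplyr::inner_join(dplyr::select(meta, "sample_id", "patient_id",
                                    "timepoint_months"), by = "sample_id")
  base <- long |>
    dplyr::filter(.data$timepoint_months == baseline) |>
    dplyr::select("protein_id", "patient_id", base_intensity = "intensity")
  out <- long |>
    dplyr::inner_join(base, by = c("protein_id", "patient_id")) |>
    dplyr::mutate(delta = .data$intensity - .data$base_intensity) |>
    dplyr::filter(!is.na(.data$delta)) |>
    dplyr::transmute(feature = .data$protein_id, patient_id = .data$patient_id,
                     timepoint_months = .data$timepoint_months,
                     delta = .data$delta)
  if (!include_baseline) out <- dplyr::filter(out, .data$timepoint_months != baseline)
  out
}

#' Baseline-to-timepoint changes of a clinical variable
#'
#' @param clinical Clinical records tibble.
#' @param var Column to difference (e.g. `"hfmse"`).
#' @param baseline Baseline timepoint (months).
#' @param include_baseline See [protein_deltas()].
#' @return A tibble: `feature`, `patient_id`, `timepoint_months`, `delta`.
#' @export
clinical_deltas <- function(clinical, var = "hfmse", baseline = 0,
                            include_baseline = FALSE) {
  if (!var %in% names(clinical)) abort(sprintf("No column `%s` in clinical table.", var))
  base <- clinical |>
    dplyr::filter(.data$timepoint_months == baseline) |>
    dplyr::select("patient_id", base_value = dplyr::all_of(var))
  out <- clinical |>
    dplyr::inner_join(base, by = "patient_id") |>
    dplyr::mutate(delta = .data[[var]] - .data$base_value) |>
    dplyr::filter(!is.na(.data$delta)) |>
    dplyr::transmute(feature = var, patient_id = .data$patient_id,
                     timepoint_months = .data$timepoint_months,
                     delta = .data$delta)
  if (!include_baseline) out <- dplyr::filter(out, .data$timepoint_months != baseline)
  out
}

#' Per-patient regulation-direction consistency
#'
#' For each protein with a reference direction (typically the direction of
#' its cross-platform DEP call) and each post-baseline timepoint: the
#' fraction of evaluable patients (data at baseline and at that timepoint)
#' whose change from baseline has the reference sign. A change of exactly
#' zero counts as non-concordant.
#'
#' @param matrix A normalized [intensity_matrix()] including baseline
#'   samples.
#' @param meta Sample metadata.
#' @param reference_signs Named vector (protein ID -> +1/-1). Proteins of
#'   the matrix without a reference sign are skipped.
#' @param baseline Baseline timepoint (months).
#' @return A tibble: `protein_id`, `timepoint_months`, `n_evaluable`,
#'   `consistency` in `[0, 1]`.
#' @export
consistency_scores <- function(matrix, meta, reference_signs, baseline = 0) {
  keep <- intersect(names(reference_signs), protein_ids(matrix))
  if (length(keep) == 0) abort("No reference-signed protein is present in the matrix.")
  skipped <- setdiff(protein_ids(matrix), names(reference_signs))
  deltas <- protein_deltas(subset_intensity(matrix, proteins = keep), meta,
                           baseline = baseline)
  deltas$ref_sign <- unname(reference_signs[deltas$feature])
  deltas |>
    dplyr::group_by(protein_id = .data$feature, .data$timepoint_months) |>
    dplyr::summarise(
      n_evaluable = dplyr::n(),
      consistency = mean(sign(.data$delta) == .data$ref_sign),
      .groups = "drop"
    )
}

#' Correlate changes in one set of features with changes in another
#'
#' Joins two delta tables on (patient, timepoint) and, per feature of `x`,
#' computes the Pearson correlation with the `y` deltas, the two-sided p
#' value from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` df, and the
#' BH-adjusted FDR across features. This is the screen behind the
#' change-change volcano: `x` = per-protein intensity changes, `y` = HFMSE
#' changes.
#'
#' @param deltas_x Delta table with a `feature` column ([protein_deltas()]).
#' @param deltas_y Delta table for a single reference feature
#'   ([clinical_deltas()]).
#' @param min_n Minimum joined pairs per feature (features below are
#'   skipped, as are zero-variance features).
#' @return A tibble: `feature`, `n`, `r`, `t`, `p`, `fdr`, sorted by `p`.
#' @export
clinical_correlation <- function(deltas_x, deltas_y, min_n = 3) {
  y <- dplyr::select(deltas_y, "patient_id", "timepoint_months", y = "delta")
  joined <- dplyr::inner_join(deltas_x, y, by = c("patient_id", "timepoint_months"))
  res <- joined |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(n = dplyr::n(),
                     sx = sd(.data$delta), sy = sd(.data$y),
                     r = if (dplyr::n() >= 3 && sd(.data$delta) > 0 && sd(.data$y) > 0)
                       cor(.data$delta, .data$y) else NA_real_,
                     .groups = "drop")
  skipped <- res$feature[res$n < min_n | res$sx == 0 | res$sy == 0 | is.na(res$r)]
  if (length(skipped)) {
    inform(paste0("Skipping ", length(skipped),
                  " feature(s) with too few pairs or zero variance."))
  }
  res <- res |>
    dplyr::filter(!.data$feature %in% skipped) |>
    dplyr::mutate(
      t = .data$r * sqrt(.data$n - 2) / sqrt(pmax(1 - .data$r^2, 1e-300)),
      p = 2 * pt(-abs(.data$t), df = .data$n - 2),
      fdr = adjust_fdr(.data$p)
    ) |>
    dplyr::select("feature", "n", "r", "t", "p", "fdr") |>
    dplyr::arrange(.data$p)
  res
}

#' Correlate routine CSF parameter changes with HFMSE changes
#'
#' Applies the change-change Pearson machinery to the routine clinical
#' parameters: total protein, lactate, glucose, qAlb and the absolute
#' immune-cell counts per 100 microlitre (cytology percentage times total
#' cell count, see [absolute_cell_counts()]).
#'
#' @param clinical Clinical records tibble.
#' @param parameters Which parameters to test.
#' @param baseline Baseline timepoint (months).
#' @return A tibble as from [clinical_correlation()], one row per
#'   parameter.
#' @export
routine_parameter_correlations <- function(
    clinical,
    parameters = c("total_protein", "lactate", "glucose", "qalb",
                   "macrophages", "monocytes", "lymphocytes"),
    baseline = 0) {
  cell_types <- intersect(parameters, c("macrophages", "monocytes", "lymphocytes"))
  for (ct in cell_types) {
    pct_col <- paste0("pct_", ct)
    if (!pct_col %in% names(clinical)) abort(sprintf("No `%s` column.", pct_col))
    clinical[[ct]] <- clinical[[pct_col]] / 100 * clinical$total_cells_per_100ul
  }
  dx <- purrr::map_dfr(parameters, function(par) {
    clinical_deltas(clinical, var = par, baseline = baseline)
  })
  dy <- clinical_deltas(clinical, var = "hfmse", baseline = baseline)
  clinical_correlation(dx, dy)
}

#' Cutoff-based response classification for one protein
#'
#' Classifies patient-timepoints by the protein's change from baseline:
#' predicted improved-or-stable when `delta >= theta`, predicted
#' not-improved-or-worse when `delta <= -theta`, abstain otherwise. The
#' observed class is improved-or-stable iff the HFMSE change is >= 0.
#' Concordance is the agreement rate over non-abstained points.
#'
#' @param protein_deltas Delta table for a single protein.
#' @param hfmse_deltas Delta table for HFMSE.
#' @param theta Positive cutoff on the intensity change.
#' @return A `cutoff_rule` list: `theta`, `concordance`,
#'   `abstention_rate`, `n_evaluated`, `n_total` and the 2x2 `confusion`
#'   tibble over non-abstained points.
#' @export
cutoff_classifier <- function(protein_deltas, hfmse_deltas, theta) {
  if (theta <= 0) abort("`theta` must be > 0.")
  if (dplyr::n_distinct(protein_deltas$feature) > 1) {
    abort("cutoff_classifier expects deltas for a single protein; see scan_cutoffs().")
  }
  y <- dplyr::select(hfmse_deltas, "patient_id", "timepoint_months", dhfmse = "delta")
  joined <- dplyr::inner_join(protein_deltas, y,
                              by = c("patient_id", "timepoint_months"))
  pred <- ifelse(joined$delta >= theta, "improved_or_stable",
                 ifelse(joined$delta <= -theta, "not_improved_or_worse", NA))
  actual <- ifelse(joined$dhfmse >= 0, "improved_or_stable", "not_improved_or_worse")
  ok <- !is.na(pred)
  n_eval <- sum(ok)
  concordance <- if (n_eval > 0) mean(pred[ok] == actual[ok]) else NA_real_
  if (n_eval == 0) warn("All points abstained; concordance undefined.")
  confusion <- tibble::as_tibble(as.data.frame(table(
    predicted = factor(pred[ok], levels = c("improved_or_stable", "not_improved_or_worse")),
    actual = factor(actual[ok], levels = c("improved_or_stable", "not_improved_or_worse"))
  )))
  structure(list(
    feature = unique(protein_deltas$feature),
    theta = theta,
    concordance = concordance,
    abstention_rate = 1 - n_eval / nrow(joined),
    n_evaluated = n_eval,
    n_total = nrow(joined),
    confusion = confusion
  ), class = "cutoff_rule")
}

#' @export
print.cutoff_rule <- function(x, ...) {
  cat(sprintf("<cutoff_rule> %s: theta = %.3g, concordance = %.3f (n = %d evaluated, %.0f%% abstained)\n",
              x$feature, x$theta, x$concordance, x$n_evaluated,
              100 * x$abstention_rate))
  invisible(x)
}

#' @export
tidy.cutoff_rule <- function(x, ...) {
  tibble::tibble(feature = x$feature, theta = x$theta,
                 concordance = x$concordance,
                 abstention_rate = x$abstention_rate,
                 n_evaluated = x$n_evaluated, n_total = x$n_total)
}

#' Scan a cutoff grid and keep the best rule per protein
#'
#' Evaluates [cutoff_classifier()] over a grid of positive cutoffs and
#' returns, per protein, the cutoff maximizing concordance among cutoffs
#' whose non-abstained fraction is at least `min_evaluated_frac`; ties are
#' broken toward the smaller cutoff.
#'
#' @param protein_deltas Delta table (may contain several proteins).
#' @param hfmse_deltas Delta table for HFMSE.
#' @param grid Positive cutoff values.
#' @param min_evaluated_frac Minimum admissible non-abstained fraction.
#' @return A tibble with the best rule per protein (columns as
#'   [tidy.cutoff_rule()]); proteins with no admissible cutoff are
#'   omitted.
#' @export
scan_cutoffs <- function(protein_deltas, hfmse_deltas,
                         grid = seq(0.05, 1, by = 0.05),
                         min_evaluated_frac = 0.25) {
  if (length(grid) == 0) abort("Cutoff grid is empty.")
  if (any(grid <= 0)) abort("All grid cutoffs must be > 0.")
  grid <- sort(grid)
  purrr::map_dfr(split(protein_deltas, protein_deltas$feature), function(dp) {
    rules <- purrr::map_dfr(grid, function(th) {
      tidy(suppressWarnings(cutoff_classifier(dp, hfmse_deltas, th)))
    })
    rules <- dplyr::filter(rules, 1 - .data$abstention_rate >= min_evaluated_frac,
                           !is.na(.data$concordance))
    if (nrow(rules) == 0) return(NULL)
    # max concordance; ties toward smaller theta (grid is sorted)
    rules[which.max(rules$concordance), ]
  })
}

#' Hypergeometric set enrichment
#'
#' One-sided (upper tail) hypergeometric test of each annotation term's
#' overlap with a hit set against a background, BH-adjusted across terms.
#' Terms with no background member are skipped.
#'
#' @param hits Protein IDs of interest (must be a subset of `background`).
#' @param background All testable protein IDs.
#' @param annotation Either a named list (term -> protein IDs) or a
#'   two-column data frame `(term, protein)`.
#' @return A tibble: `term`, `k` (hit overlap), `K` (background term
#'   size), `expected`, `p`, `fdr`, sorted by `p`.
#' @export
enrichment_test <- function(hits, background, annotation) {
  hits <- unique(hits); background <- unique(background)
  extra <- setdiff(hits, background)
  if (length(extra)) {
    abort(paste0("Hits outside the background: ", paste(head(extra, 5), collapse = ", ")))
  }
  if (is.data.frame(annotation)) {
    annotation <- split(annotation[[2]], annotation[[1]])
  }
  N <- length(background); n <- length(hits)
  res <- purrr::imap_dfr(annotation, function(members, term) {
    K <- length(intersect(members, background))
    if (K == 0) return(NULL)
    k <- length(intersect(members, hits))
    tibble::tibble(term = term, k = k, K = K,
                   expected = n * K / N,
                   p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  if (nrow(res) == 0) return(tibble::tibble(term = character(), k = integer(),
                                            K = integer(), expected = numeric(),
                                            p = numeric(), fdr = numeric()))
  res$fdr <- adjust_fdr(res$p)
  dplyr::arrange(res, .data$p)
}
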