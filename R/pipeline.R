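#' Analysis configuration
#'
#' Bundles every pipeline threshold with its study default: DEP calling at
#' FDR < 0.05 and |log2FC| > 0.5, sample total-intensity minimum 225
#' (TMT only; arbitrary intensity units), detection in >= 2 samples within
#' a patient and >= 2 patients, k = 10 imputation neighbours.
#'
#' @param fdr_alpha DEP FDR threshold (strict `<`), in (0, 1).
#' @param log2fc_min DEP |log2FC| threshold (strict `>`), >= 0.
#' @param sample_min_total Minimum summed raw intensity per TMT sample.
#' @param min_within_patient,min_patients Detection-filter minimums.
#' @param knn_k Imputation neighbours (>= 1).
#' @param cutoff_grid Grid of candidate biomarker cutoffs (log2 units).
#' @param schedule Visit schedule in months.
#' @param fdr_scope `"per_contrast"` or `"global"` BH scope.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(fdr_alpha = 0.05, log2fc_min = 0.5,
                            sample_min_total = 225,
                            min_within_patient = 2, min_patients = 2,
                            knn_k = 10,
                            cutoff_grid = seq(0.05, 1, by = 0.05),
                            schedule = default_schedule(),
                            fdr_scope = "per_contrast") {
  if (fdr_alpha <= 0 || fdr_alpha >= 1) abort("`fdr_alpha` must be in (0, 1).")
  if (log2fc_min < 0) abort("`log2fc_min` must be >= 0.")
  if (knn_k < 1) abort("`knn_k` must be >= 1.")
  structure(as.list(environment()), class = "analysis_config")
}

#' Read a cohort from disk
#'
#' @param tmt_path,lfq_path Wide intensity TSVs (see
#'   [read_intensity_table()]).
#' @param meta_path Sample metadata TSV.
#' @param clinical_path Clinical table TSV (optional).
#' @param schedule Visit schedule.
#' @return A `sim_cohort`-shaped list (`tmt`, `lfq`, `meta`, `clinical`,
#'   `truth = NULL`).
#' @export
read_cohort <- function(tmt_path, lfq_path, meta_path, clinical_path = NULL,
                        schedule = default_schedule()) {
  for (p in c(tmt_path, lfq_path, meta_path, clinical_path)) {
    if (!file.exists(p)) abort(sprintf("Input file not found: %s", p))
  }
  structure(list(
    tmt = read_intensity_table(tmt_path, "TMT"),
    lfq = read_intensity_table(lfq_path, "LFQ"),
    meta = read_sample_meta(meta_path, schedule = schedule),
    clinical = if (!is.null(clinical_path)) read_clinical_table(clinical_path),
    truth = NULL
  ), class = "sim_cohort")
}

#' Write a cohort to a directory as plain-text tables
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_intensity_table(cohort$tmt, file.path(dir, "intensities_tmt.tsv"))
  write_intensity_table(cohort$lfq, file.path(dir, "intensities_lfq.tsv"))
  readr::write_tsv(cohort$meta, file.path(dir, "sample_meta.tsv"))
  if (!is.null(cohort$clinical)) {
    readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  }
  if (!is.null(cohort$truth)) {
    truth <- cohort$truth[c("deps", "coupled", "shifted", "dominant_protein",
                            "low_quality_samples", "missing")]
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

# Preprocess one platform: optional sample filter, detection filter, VST,
# imputation. Returns the imputed matrix plus a log of what was removed.
preprocess_platform <- function(matrix, meta, config, sample_filter = FALSE) {
  removed <- tibble::tibble(sample_id = character(), total_intensity = numeric())
  if (sample_filter) {
    f <- filter_low_intensity_samples(matrix, config$sample_min_total)
    matrix <- f$matrix
    removed <- f$removed
  }
  n_before <- nrow(matrix$values)
  matrix <- filter_detection(matrix, meta,
                             min_within_patient = config$min_within_patient,
                             min_patients = config$min_patients)
  vst <- vst_normalize(matrix)
  imputed <- knn_impute(vst$matrix, k = config$knn_k)
  list(matrix = imputed, vst_params = vst$params,
       removed_samples = removed,
       n_proteins_removed = n_before - nrow(imputed$values))
}

#' Run the full analysis pipeline
#'
#' Executes the whole analysis on a cohort (simulated when none is given):
#' per-platform preprocessing, patient-adjusted sample correlation and
#' clustering, patient-blocked moderated-t differential expression,
#' cross-platform overlap / abundance-rank / DEP-intersection analytics,
#' per-patient consistency scores, the protein-vs-HFMSE change-change
#' correlation screen, routine clinical correlations, and cutoff scans for
#' the top correlated proteins. A manifest with the configuration, seed
#' and per-stage content hashes makes reruns checkable.
#'
#' @param config An [analysis_config()].
#' @param cohort A cohort ([simulate_cohort()] or [read_cohort()]); when
#'   `NULL`, a cohort is simulated from `sim` and `seed`.
#' @param sim A [sim_config()] used when simulating.
#' @param seed Seed for the simulation.
#' @param n_cutoff_proteins Number of top-|r| screen proteins to run the
#'   cutoff scan on.
#' @return A `pipeline_result` list: `cohort`, `preprocess` (per
#'   platform), `correlation` (per platform, clustered), `deps` (per
#'   platform), `dep_counts`, `overlap`, `rank_table`, `top_ranks`,
#'   `shared_deps`, `consistency`, `protein_screen`, `clinical_screen`,
#'   `cutoff_rules`, `manifest`.
#' @export
run_pipeline <- function(config = analysis_config(), cohort = NULL,
                         sim = sim_config(), seed = 1L,
                         n_cutoff_proteins = 10) {
  if (is.null(cohort)) cohort <- simulate_cohort(sim, seed)
  meta <- cohort$meta

  pre_tmt <- preprocess_platform(cohort$tmt, meta, config, sample_filter = TRUE)
  pre_lfq <- preprocess_platform(cohort$lfq, meta, config, sample_filter = FALSE)

  correlation <- purrr::map(list(TMT = pre_tmt, LFQ = pre_lfq), function(pre) {
    pre$matrix |>
      remove_patient_effect(meta) |>
      zscore_rows() |>
      sample_correlation() |>
      hierarchical_cluster()
  })

  deps <- purrr::map(list(TMT = pre_tmt, LFQ = pre_lfq), function(pre) {
    dep_analysis(pre$matrix, meta, fdr_alpha = config$fdr_alpha,
                 log2fc_min = config$log2fc_min, scope = config$fdr_scope)
  })

  overlap <- overlap_identified(protein_ids(cohort$tmt), protein_ids(cohort$lfq))
  rank_table <- rank_intensity(pre_tmt$matrix, highlight = protein_ids(cohort$lfq))
  top_ranks <- top_rank_trajectory(pre_tmt$matrix, meta, k = 10)
  shared_deps <- intersect_deps(deps$TMT, deps$LFQ)

  ref_signs <- c(setNames(rep(1, length(shared_deps$up)), shared_deps$up),
                 setNames(rep(-1, length(shared_deps$down)), shared_deps$down))
  consistency <- if (length(ref_signs)) {
    consistency_scores(pre_tmt$matrix, meta, ref_signs)
  } else tibble::tibble(protein_id = character(), timepoint_months = numeric(),
                        n_evaluable = integer(), consistency = numeric())

  dx <- protein_deltas(pre_tmt$matrix, meta)
  protein_screen <- NULL
  clinical_screen <- NULL
  cutoff_rules <- NULL
  if (!is.null(cohort$clinical)) {
    dy <- clinical_deltas(cohort$clinical, "hfmse")
    protein_screen <- clinical_correlation(dx, dy)
    clinical_screen <- routine_parameter_correlations(cohort$clinical)
    top <- head(protein_screen$feature, n_cutoff_proteins)
    cutoff_rules <- scan_cutoffs(dplyr::filter(dx, .data$feature %in% top),
                                 dy, grid = config$cutoff_grid)
  }

  result <- list(
    cohort = cohort,
    preprocess = list(TMT = pre_tmt, LFQ = pre_lfq),
    correlation = correlation,
    deps = deps,
    dep_counts = purrr::map(deps, dep_counts),
    overlap = overlap,
    rank_table = rank_table,
    top_ranks = top_ranks,
    shared_deps = shared_deps,
    consistency = consistency,
    protein_screen = protein_screen,
    clinical_screen = clinical_screen,
    cutoff_rules = cutoff_rules
  )
  result$manifest <- build_manifest(result, config, seed)
  structure(result, class = "pipeline_result")
}

build_manifest <- function(result, config, seed) {
  hash_of <- function(x) rlang::hash(x)
  list(
    package_version = as.character(utils::packageVersion("csfmarkers")),
    seed = seed,
    config = unclass(config),
    timestamp = format(Sys.time(), tz = "UTC"),
    checksums = list(
      tmt_input = hash_of(result$cohort$tmt$values),
      lfq_input = hash_of(result$cohort$lfq$values),
      tmt_imputed = hash_of(result$preprocess$TMT$matrix$values),
      lfq_imputed = hash_of(result$preprocess$LFQ$matrix$values),
      deps_tmt = hash_of(result$deps$TMT),
      deps_lfq = hash_of(result$deps$LFQ),
      consistency = hash_of(result$consistency),
      protein_screen = hash_of(result$protein_screen),
      cutoff_rules = hash_of(result$cutoff_rules)
    )
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  nd <- purrr::map_int(x$deps, ~ dplyr::n_distinct(.x$protein_id[.x$is_dep]))
  cat("<pipeline_result>\n")
  cat(sprintf("  proteins: TMT %d (%d after filters), LFQ %d (%d after filters)\n",
              nrow(x$cohort$tmt$values), nrow(x$preprocess$TMT$matrix$values),
              nrow(x$cohort$lfq$values), nrow(x$preprocess$LFQ$matrix$values)))
  cat(sprintf("  shared identified proteins: %d\n", x$overlap$n_shared))
  cat(sprintf("  DEPs: TMT %d, LFQ %d; shared up %d / down %d\n",
              nd[["TMT"]], nd[["LFQ"]],
              length(x$shared_deps$up), length(x$shared_deps$down)))
  if (!is.null(x$protein_screen)) {
    cat(sprintf("  change-change screen: %d proteins, %d with FDR < 0.05\n",
                nrow(x$protein_screen), sum(x$protein_screen$fdr < 0.05)))
  }
  invisible(x)
}

#' Write pipeline outputs as a plain-text report bundle
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pl in c("TMT", "LFQ")) {
    readr::write_tsv(result$deps[[pl]],
                     file.path(dir, sprintf("deps_%s.tsv", tolower(pl))))
    ord <- result$correlation[[pl]]$order
    readr::write_tsv(tidy(result$correlation[[pl]]),
                     file.path(dir, sprintf("sample_correlation_%s.tsv", tolower(pl))))
  }
  readr::write_tsv(result$consistency, file.path(dir, "consistency.tsv"))
  if (!is.null(result$protein_screen)) {
    readr::write_tsv(result$protein_screen, file.path(dir, "protein_screen.tsv"))
    readr::write_tsv(result$clinical_screen, file.path(dir, "clinical_screen.tsv"))
    readr::write_tsv(result$cutoff_rules, file.path(dir, "cutoff_rules.tsv"))
  }
  readr::write_tsv(result$rank_table, file.path(dir, "rank_intensity_tmt.tsv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
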