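#' Configuration for the synthetic longitudinal cohort
#'
#' Defaults emulate the structure of a 24-patient adult SMA cohort sampled
#' at up to seven visits (months 0, 2, 10, 18, 26, 34, 42) with monotone
#' dropout (24, 24, 24, 20, 17, 14, 11 patients per visit), quantified on
#' two platforms: a deep TMT dataset (1,674 proteins) and a shallower LFQ
#' dataset (441 proteins) whose 429 shared proteins occupy the high end of
#' the TMT abundance range.
#'
#' The raw-scale intensity model is
#' `2^(mu_p + patient + batch + effect) * 2^eps_mult + eps_add`, i.e.
#' multiplicative noise on top of a log2-additive signal plus an additive
#' noise floor, so that per-protein variance grows with the mean on the raw
#' scale and a generalized-log transform is the appropriate stabilizer.
#'
#' Planted structure, all recorded in the returned ground truth:
#' * `n_dep` treatment-responsive proteins shifted by `dep_log2fc` (random
#'   sign) from `dep_onset_months` onwards, a fraction `dep_frac_shared` of
#'   them drawn from the LFQ-covered stratum;
#' * a broad compositional drift: a fraction `shift_frac` of proteins gets
#'   a small persistent shift (SD `shift_sd` log2 units) at every
#'   on-treatment visit, which is what makes pre-treatment samples cluster
#'   apart from on-treatment samples;
#' * `n_coupled` clinically coupled proteins whose log2 intensity tracks
#'   the patient's HFMSE change with slope `coupling_slope`;
#' * one dominant albumin-like protein pinned far above the rest;
#' * negative couplings of qAlb, lactate, glucose and lymphocyte
#'   percentages (and a positive macrophage coupling) to HFMSE change.
#'
#' @param n_patients Number of patients.
#' @param schedule Visit months.
#' @param visits_per_patient Integer vector (length `n_patients`): number of
#'   initial visits each patient completed (monotone dropout).
#' @param n_proteins_tmt,n_proteins_lfq,n_shared Platform depths and the
#'   size of the shared protein set.
#' @param baseline_log2_range Range of baseline log2 abundances.
#' @param dominant_log2 Log2 abundance of the dominant (albumin-like)
#'   protein, above `baseline_log2_range`.
#' @param patient_sd SD (log2) of protein-specific patient random effects.
#' @param n_modules,patient_effect_module_cor Co-regulation structure:
#'   proteins are assigned to `n_modules` modules and a fraction
#'   `patient_effect_module_cor` of the patient-effect variance is shared
#'   within a module, so biologically related proteins co-vary across
#'   patients (what makes neighbour-based imputation informative).
#' @param batch_sd SD (log2) of protein-specific TMT plex effects.
#' @param noise_log2_sd SD of multiplicative (log2-scale) measurement noise.
#' @param noise_additive_sd SD of the raw-scale additive noise floor.
#' @param missing_rate,missing_mechanism Fraction of masked cells and the
#'   masking mechanism (see [mask_missing()]).
#' @param n_dep,dep_log2fc,dep_onset_months,dep_frac_shared Planted
#'   treatment-responsive proteins.
#' @param shift_frac,shift_sd Broad on-treatment compositional drift.
#' @param n_coupled,coupling_slope,coupling_noise_sd Clinically coupled
#'   proteins (log2 units per HFMSE point; per-observation noise SD).
#' @param hfmse_baseline_mean,hfmse_baseline_sd Baseline HFMSE distribution
#'   (truncated to 0-66 and rounded).
#' @param hfmse_drift Mean HFMSE change from baseline at each visit.
#' @param hfmse_patient_sd SD of the per-patient response level.
#' @param hfmse_noise_sd SD of per-visit HFMSE measurement noise.
#' @param clinical_coupling Multiplier on all clinical couplings (0 turns
#'   them off).
#' @param plant_low_quality If `TRUE`, two TMT samples are scaled down by
#'   `low_quality_factor` to exercise the sample-intensity filter.
#' @param low_quality_factor Scaling factor for planted low-quality samples.
#' @param tmt_plex_size Samples per TMT plex.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 24,
                       schedule = default_schedule(),
                       visits_per_patient = c(rep(7L, 11), rep(6L, 3), rep(5L, 3),
                                              rep(4L, 3), rep(3L, 4)),
                       n_proteins_tmt = 1674,
                       n_proteins_lfq = 441,
                       n_shared = 429,
                       baseline_log2_range = c(10, 30),
                       dominant_log2 = 34,
                       patient_sd = 0.5,
                       n_modules = 25,
                       patient_effect_module_cor = 0.5,
                       batch_sd = 0.25,
                       noise_log2_sd = 0.25,
                       noise_additive_sd = 400,
                       missing_rate = 0.1,
                       missing_mechanism = c("MAR", "intensity_dependent"),
                       n_dep = 40,
                       dep_log2fc = 1.5,
                       dep_onset_months = 10,
                       dep_frac_shared = 0.5,
                       shift_frac = 0.5,
                       shift_sd = 0.5,
                       n_coupled = 10,
                       coupling_slope = 0.2,
                       coupling_noise_sd = 0.1,
                       hfmse_baseline_mean = 23,
                       hfmse_baseline_sd = 15,
                       hfmse_drift = c(0, 1.1, 2.2, 1.6, 1.4, 2.6, 2.1),
                       hfmse_patient_sd = 2,
                       hfmse_noise_sd = 2,
                       clinical_coupling = 1,
                       plant_low_quality = FALSE,
                       low_quality_factor = 1e-3,
                       tmt_plex_size = 10) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- as.list(environment())
  if (length(cfg$visits_per_patient) != n_patients) {
    abort("`visits_per_patient` must have one entry per patient.")
  }
  if (any(cfg$visits_per_patient < 1) ||
      any(cfg$visits_per_patient > length(schedule))) {
    abort("`visits_per_patient` entries must be in 1..length(schedule).")
  }
  if (n_shared > min(n_proteins_tmt, n_proteins_lfq)) {
    abort("`n_shared` cannot exceed either platform's protein count.")
  }
  if (length(cfg$hfmse_drift) != length(schedule)) {
    abort("`hfmse_drift` must match the schedule length.")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  if (n_dep + n_coupled + 1 > n_proteins_tmt) abort("Too many planted proteins.")
  structure(cfg, class = "sim_config")
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_sim_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a paired TMT/LFQ longitudinal cohort with ground truth
#'
#' Generates raw-scale intensity matrices for both platforms, sample
#' metadata, longitudinal clinical records and a ground-truth object
#' describing every planted effect. Deterministic given `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `sim_cohort` list with elements `tmt`, `lfq`
#'   ([intensity_matrix()]), `meta` (sample metadata for both platforms),
#'   `clinical` (one row per patient-visit) and `truth` (planted effects).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 4, n_proteins_tmt = 60,
#'                                      n_proteins_lfq = 30, n_shared = 25,
#'                                      visits_per_patient = rep(3L, 4),
#'                                      n_dep = 5, n_coupled = 2), seed = 1)
#' dim(cohort$tmt)
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(seed, simulate_cohort_impl(config, seed))
}

#' Simulate a null cohort (no planted effects)
#'
#' Same generative model as [simulate_cohort()] but with zero planted
#' differential expression, no compositional drift, no clinically coupled
#' proteins and clinical couplings switched off; the ground-truth effect
#' sets are empty. Used for type-I-error / false-discovery testing.
#'
#' @inheritParams simulate_cohort
#' @return A `sim_cohort` (see [simulate_cohort()]).
#' @export
simulate_null <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  config$n_dep <- 0L
  config$n_coupled <- 0L
  config$shift_frac <- 0
  config$clinical_coupling <- 0
  simulate_cohort(config, seed)
}

simulate_cohort_impl <- function(cfg, seed) {
  schedule <- cfg$schedule
  n_tp <- length(schedule)
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))

  ## --- protein universe -------------------------------------------------
  tmt_ids <- sprintf("PROT%04d", seq_len(cfg$n_proteins_tmt))
  mu_tmt <- runif(cfg$n_proteins_tmt, cfg$baseline_log2_range[1],
                  cfg$baseline_log2_range[2])
  dominant <- tmt_ids[1]
  mu_tmt[1] <- cfg$dominant_log2
  names(mu_tmt) <- tmt_ids

  shared_ids <- tmt_ids[order(mu_tmt, decreasing = TRUE)][seq_len(cfg$n_shared)]
  n_lfq_only <- cfg$n_proteins_lfq - cfg$n_shared
  lfq_only_ids <- if (n_lfq_only > 0) sprintf("LFQP%03d", seq_len(n_lfq_only)) else character()
  # platform-unique LFQ proteins sit in the upper abundance range too
  mu_lfq_only <- runif(n_lfq_only,
                       mean(cfg$baseline_log2_range),
                       cfg$baseline_log2_range[2])
  names(mu_lfq_only) <- lfq_only_ids
  lfq_ids <- c(shared_ids, lfq_only_ids)

  ## --- planted effects --------------------------------------------------
  assignable_shared <- setdiff(shared_ids, dominant)
  assignable_other <- setdiff(tmt_ids, c(shared_ids, dominant))
  n_dep_shared <- min(round(cfg$n_dep * cfg$dep_frac_shared), length(assignable_shared))
  n_dep_other <- min(cfg$n_dep - n_dep_shared, length(assignable_other))
  dep_ids <- c(sample(assignable_shared, n_dep_shared),
               sample(assignable_other, n_dep_other))
  dep_sign <- sample(c(-1, 1), length(dep_ids), replace = TRUE)
  deps <- tibble::tibble(
    protein_id = dep_ids,
    sign = dep_sign,
    log2fc = dep_sign * cfg$dep_log2fc,
    onset_months = cfg$dep_onset_months,
    shared = dep_ids %in% shared_ids
  )

  coupled_pool <- setdiff(assignable_shared, dep_ids)
  n_coupled <- min(cfg$n_coupled, length(coupled_pool))
  coupled_ids <- if (n_coupled > 0) sample(coupled_pool, n_coupled) else character()
  coupled_sign <- if (n_coupled > 0) {
    sample(c(1, -1), n_coupled, replace = TRUE, prob = c(0.7, 0.3))
  } else numeric()
  coupled <- tibble::tibble(protein_id = coupled_ids,
                            slope = coupled_sign * cfg$coupling_slope)

  shift_pool <- setdiff(tmt_ids, c(dominant, dep_ids, coupled_ids))
  n_shift <- round(cfg$shift_frac * cfg$n_proteins_tmt)
  n_shift <- min(n_shift, length(shift_pool))
  shift_ids <- if (n_shift > 0) sample(shift_pool, n_shift) else character()
  shifted <- tibble::tibble(protein_id = shift_ids,
                            shift = rnorm(n_shift, 0, cfg$shift_sd))

  # per-protein timepoint effect matrix (TMT protein space)
  tp_effect <- matrix(0, cfg$n_proteins_tmt, n_tp,
                      dimnames = list(tmt_ids, as.character(schedule)))
  on_treatment <- schedule >= schedule[2] & seq_len(n_tp) > 1
  post_onset <- schedule >= cfg$dep_onset_months
  if (nrow(deps)) tp_effect[deps$protein_id, post_onset] <-
    tp_effect[deps$protein_id, post_onset] + deps$log2fc
  if (nrow(shifted)) tp_effect[shifted$protein_id, on_treatment] <-
    tp_effect[shifted$protein_id, on_treatment] + shifted$shift

  ## --- clinical trajectories -------------------------------------------
  hf_base <- round(pmin(pmax(
    rnorm(cfg$n_patients, cfg$hfmse_baseline_mean, cfg$hfmse_baseline_sd), 0), 66))
  hf_patient <- rnorm(cfg$n_patients, 0, cfg$hfmse_patient_sd)
  hfmse <- matrix(NA_real_, cfg$n_patients, n_tp,
                  dimnames = list(patients, as.character(schedule)))
  for (j in seq_len(n_tp)) {
    raw <- hf_base + cfg$hfmse_drift[j] +
      if (j > 1) hf_patient + rnorm(cfg$n_patients, 0, cfg$hfmse_noise_sd) else 0
    hfmse[, j] <- round(pmin(pmax(raw, 0), 66))
  }
  dhfmse <- hfmse - hfmse[, 1]

  cc <- cfg$clinical_coupling
  clin_noise <- function(sd) rnorm(cfg$n_patients * n_tp, 0, sd)
  qalb <- pmax(rnorm(cfg$n_patients, 6e-3, 1e-3) +
                 cc * (-8e-5) * dhfmse + matrix(clin_noise(2e-4), cfg$n_patients), 1e-4)
  lactate <- pmax(rnorm(cfg$n_patients, 1.7, 0.15) +
                    cc * (-0.012) * dhfmse + matrix(clin_noise(0.01), cfg$n_patients), 0.1)
  glucose <- pmax(rnorm(cfg$n_patients, 60, 6) +
                    cc * (-0.5) * dhfmse + matrix(clin_noise(1.5), cfg$n_patients), 10)
  total_protein <- pmax(rnorm(cfg$n_patients, 450, 80) +
                          matrix(clin_noise(20), cfg$n_patients), 50)
  total_cells <- round(pmax(rlnorm(cfg$n_patients, log(150), 0.4) +
                              matrix(clin_noise(15), cfg$n_patients), 5))
  pct_macro <- pmax(rnorm(cfg$n_patients, 4, 1) +
                      cc * 0.4 * dhfmse + matrix(clin_noise(0.6), cfg$n_patients), 0.2)
  pct_lymph <- pmax(rnorm(cfg$n_patients, 82, 3) +
                      cc * (-0.6) * dhfmse + matrix(clin_noise(1.2), cfg$n_patients), 5)
  pct_mono <- pmax(100 - pct_macro - pct_lymph, 0.5)
  tot_pct <- pct_macro + pct_lymph + pct_mono
  pct_macro <- pct_macro / tot_pct * 100
  pct_lymph <- pct_lymph / tot_pct * 100
  pct_mono <- pct_mono / tot_pct * 100

  visit_idx <- lapply(seq_len(cfg$n_patients),
                      function(i) seq_len(cfg$visits_per_patient[i]))
  clinical <- purrr::map_dfr(seq_len(cfg$n_patients), function(i) {
    j <- visit_idx[[i]]
    tibble::tibble(
      patient_id = patients[i],
      timepoint_months = schedule[j],
      hfmse = unname(hfmse[i, j]),
      qalb = unname(qalb[i, j]),
      lactate = unname(lactate[i, j]),
      glucose = unname(glucose[i, j]),
      total_protein = unname(total_protein[i, j]),
      total_cells_per_100ul = unname(total_cells[i, j]),
      pct_lymphocytes = unname(pct_lymph[i, j]),
      pct_monocytes = unname(pct_mono[i, j]),
      pct_macrophages = unname(pct_macro[i, j])
    )
  })

  ## --- sample layout ----------------------------------------------------
  make_meta <- function(platform) {
    purrr::map_dfr(seq_len(cfg$n_patients), function(i) {
      j <- visit_idx[[i]]
      tibble::tibble(
        sample_id = sprintf("%s_%s_T%02d", platform, patients[i], schedule[j]),
        patient_id = patients[i],
        timepoint_months = schedule[j],
        platform = platform
      )
    })
  }
  meta_tmt <- make_meta("TMT")
  meta_lfq <- make_meta("LFQ")
  n_samp <- nrow(meta_tmt)
  # samples are randomized across plexes (standard isobaric block design),
  # so plex effects are not systematically aligned with time or patient
  plex <- character(n_samp)
  plex[sample.int(n_samp)] <- sprintf("plex%02d",
                                      ceiling(seq_len(n_samp) / cfg$tmt_plex_size))
  meta_tmt$batch_id <- plex
  meta_lfq$batch_id <- sprintf("run%03d", seq_len(nrow(meta_lfq)))
  meta <- sample_meta(dplyr::bind_rows(meta_tmt, meta_lfq), schedule = schedule)

  ## --- intensity matrices ----------------------------------------------
  # patient effects: a module-shared component (co-regulated proteins move
  # together across patients) plus a protein-unique component
  f_mod <- cfg$patient_effect_module_cor
  module_u <- matrix(rnorm(cfg$n_modules * cfg$n_patients, 0, cfg$patient_sd),
                     cfg$n_modules, cfg$n_patients)
  draw_patient_eff <- function(ids) {
    np <- length(ids)
    mod <- sample.int(cfg$n_modules, np, replace = TRUE)
    eff <- sqrt(f_mod) * module_u[mod, , drop = FALSE] +
      sqrt(1 - f_mod) * matrix(rnorm(np * cfg$n_patients, 0, cfg$patient_sd),
                               np, cfg$n_patients)
    dimnames(eff) <- list(ids, patients)
    eff
  }
  patient_eff <- draw_patient_eff(tmt_ids)
  plex_levels <- unique(meta_tmt$batch_id)
  batch_eff <- matrix(rnorm(cfg$n_proteins_tmt * length(plex_levels), 0, cfg$batch_sd),
                      cfg$n_proteins_tmt, length(plex_levels),
                      dimnames = list(tmt_ids, plex_levels))
  patient_eff_lfq_only <- draw_patient_eff(lfq_only_ids)

  coupled_slopes <- setNames(coupled$slope, coupled$protein_id)
  pat_index <- setNames(seq_len(cfg$n_patients), patients)
  tp_index <- setNames(seq_len(n_tp), as.character(schedule))

  build_signal <- function(ids, mu, pat_eff, meta_pl, use_batch) {
    np <- length(ids); ns <- nrow(meta_pl)
    pi <- pat_index[meta_pl$patient_id]
    ti <- tp_index[as.character(meta_pl$timepoint_months)]
    sig <- matrix(mu[ids], np, ns) + pat_eff[ids, pi, drop = FALSE]
    in_tmt <- ids %in% tmt_ids
    if (any(in_tmt)) {
      sig[in_tmt, ] <- sig[in_tmt, , drop = FALSE] +
        tp_effect[ids[in_tmt], ti, drop = FALSE]
    }
    if (use_batch) sig <- sig + batch_eff[ids, match(meta_pl$batch_id, plex_levels),
                                          drop = FALSE]
    cp <- intersect(ids, names(coupled_slopes))
    if (length(cp)) {
      d <- dhfmse[cbind(pi, ti)]
      sig[cp, ] <- sig[cp, , drop = FALSE] +
        outer(coupled_slopes[cp], d) +
        matrix(rnorm(length(cp) * ns, 0, cfg$coupling_noise_sd), length(cp), ns)
    }
    dimnames(sig) <- list(ids, meta_pl$sample_id)
    sig
  }

  to_raw <- function(sig) {
    np <- nrow(sig); ns <- ncol(sig)
    raw <- 2^(sig + matrix(rnorm(np * ns, 0, cfg$noise_log2_sd), np, ns)) +
      matrix(rnorm(np * ns, 0, cfg$noise_additive_sd), np, ns)
    pmax(raw, 0)
  }

  sig_tmt <- build_signal(tmt_ids, mu_tmt, patient_eff, meta_tmt, use_batch = TRUE)
  raw_tmt <- to_raw(sig_tmt)
  mu_all_lfq <- c(mu_tmt[shared_ids], mu_lfq_only)
  pat_eff_lfq <- rbind(patient_eff[shared_ids, , drop = FALSE], patient_eff_lfq_only)
  sig_lfq <- build_signal(lfq_ids, mu_all_lfq, pat_eff_lfq, meta_lfq, use_batch = FALSE)
  raw_lfq <- to_raw(sig_lfq)

  low_quality <- character()
  if (isTRUE(cfg$plant_low_quality) && ncol(raw_tmt) >= 4) {
    low_quality <- sample(colnames(raw_tmt), 2)
    raw_tmt[, low_quality] <- raw_tmt[, low_quality] * cfg$low_quality_factor
  }

  tmt <- intensity_matrix(raw_tmt, platform = "TMT", scale = "raw")
  lfq <- intensity_matrix(raw_lfq, platform = "LFQ", scale = "raw")
  if (cfg$missing_rate > 0) {
    tmt <- mask_missing(tmt, cfg$missing_rate, cfg$missing_mechanism,
                        seed = sample.int(.Machine$integer.max, 1))
    lfq <- mask_missing(lfq, cfg$missing_rate, cfg$missing_mechanism,
                        seed = sample.int(.Machine$integer.max, 1))
  }

  truth <- list(
    deps = deps,
    coupled = coupled,
    shifted = shifted,
    dominant_protein = dominant,
    shared_ids = shared_ids,
    low_quality_samples = low_quality,
    patient_effects = patient_eff,
    batch_effects = batch_eff,
    hfmse = hfmse,
    dhfmse = dhfmse,
    missing = list(rate = cfg$missing_rate, mechanism = cfg$missing_mechanism)
  )
  structure(list(tmt = tmt, lfq = lfq, meta = meta, clinical = clinical,
                 truth = truth, config = cfg, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d patients, %d visits max; TMT %d x %d, LFQ %d x %d; %d planted DEPs, %d coupled\n",
    x$config$n_patients, length(x$config$schedule),
    nrow(x$tmt$values), ncol(x$tmt$values),
    nrow(x$lfq$values), ncol(x$lfq$values),
    nrow(x$truth$deps), nrow(x$truth$coupled)))
  invisible(x)
}

#' Mask entries of an intensity matrix as missing
#'
#' Under `"MAR"` every cell is masked independently with probability
#' `rate`. Under `"intensity_dependent"` the masking probability is a
#' decreasing logistic function of standardized log2 intensity, with its
#' intercept calibrated so the expected overall missing fraction equals
#' `rate` (low-abundance measurements are masked preferentially).
#'
#' @param matrix An [intensity_matrix()] (raw scale for the
#'   intensity-dependent mechanism).
#' @param rate Target missing fraction in `[0, 1)`.
#' @param mechanism `"MAR"` or `"intensity_dependent"`.
#' @param seed Integer seed.
#' @param slope Steepness of the intensity dependence (logistic slope per
#'   SD of log2 intensity).
#' @return The matrix with additional entries set to missing.
#' @export
mask_missing <- function(matrix, rate, mechanism = c("MAR", "intensity_dependent"),
                         seed = 1L, slope = 1.5) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) abort("`rate` must be in [0, 1).")
  if (rate == 0) return(matrix)
  v <- matrix$values
  with_sim_seed(seed, {
    if (mechanism == "MAR") {
      drop <- matrix(runif(length(v)) < rate, nrow(v))
    } else {
      z <- log2(pmax(v, 1))
      z <- (z - mean(z, na.rm = TRUE)) / sd(z, na.rm = TRUE)
      z[is.na(z)] <- 0
      f <- function(a) mean(stats::plogis(a - slope * z)) - rate
      a <- stats::uniroot(f, c(-50, 50))$root
      drop <- matrix(runif(length(v)) < stats::plogis(a - slope * z), nrow(v))
    }
    v[drop] <- NA_real_
  })
  set_values(matrix, v)
}
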