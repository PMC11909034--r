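# Small simulated cohorts and independent brute-force oracles shared by the
# test files. Oracles deliberately use naive loops / direct formulas so they
# stay independent of the implementation paths they check.

small_sim_config <- function(...) {
  defaults <- list(
    n_patients = 12L,
    visits_per_patient = c(rep(5L, 6), rep(4L, 3), rep(3L, 3)),
    schedule = c(0L, 2L, 10L, 18L, 26L),
    hfmse_drift = c(0, 1.1, 2.2, 1.6, 1.4),
    n_proteins_tmt = 300L,
    n_proteins_lfq = 120L,
    n_shared = 110L,
    n_dep = 20L,
    n_coupled = 5L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# random small intensity matrix with metadata, for property tests
random_matrix_cohort <- function(n_prot, n_patients, n_tp, missing_rate = 0.3,
                                 platform = "TMT", scale = "raw") {
  schedule <- default_schedule()[seq_len(n_tp)]
  meta <- expand.grid(patient_id = sprintf("P%02d", seq_len(n_patients)),
                      timepoint_months = schedule, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("S_%s_T%02d", meta$patient_id, meta$timepoint_months)
  meta$platform <- platform
  meta$batch_id <- "b1"
  v <- matrix(2^runif(n_prot * nrow(meta), 5, 15), n_prot,
              dimnames = list(sprintf("PR%03d", seq_len(n_prot)), meta$sample_id))
  v[runif(length(v)) < missing_rate] <- NA
  list(matrix = intensity_matrix(v, platform = platform, scale = scale),
       meta = sample_meta(tibble::as_tibble(meta)))
}

# noise-free toy: 3 patients x 2 timepoints, known patient offsets and a
# planted timepoint effect
toy_adjust_cohort <- function(offsets = c(2, -1, 0), tp_effect = 1) {
  meta <- tibble::tibble(
    sample_id = c("a0", "a1", "b0", "b1", "c0", "c1"),
    patient_id = rep(c("A", "B", "C"), each = 2),
    timepoint_months = rep(c(0L, 10L), 3),
    platform = "TMT", batch_id = "b1"
  )
  v <- matrix(10 + rep(offsets, each = 2) +
                rep(c(0, tp_effect), 3), 1, byrow = TRUE,
              dimnames = list("PR1", meta$sample_id))
  list(matrix = intensity_matrix(v, "TMT", scale = "vst"), meta = meta)
}

# --- independent oracles ----------------------------------------------------

bf_detection_keep <- function(values, patient_of, min_within = 2, min_patients = 2) {
  keep <- logical(nrow(values))
  patients <- unique(patient_of)
  for (p in seq_len(nrow(values))) {
    max_within <- 0
    n_pat <- 0
    for (pat in patients) {
      n_det <- 0
      for (s in which(patient_of == pat)) {
        if (!is.na(values[p, s])) n_det <- n_det + 1
      }
      if (n_det > max_within) max_within <- n_det
      if (n_det >= 1) n_pat <- n_pat + 1
    }
    keep[p] <- (max_within >= min_within) && (n_pat >= min_patients)
  }
  keep
}

bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running_min <- Inf
  for (i in n:1) {
    running_min <- min(running_min, p[o[i]] * n / i)
    adj[o[i]] <- min(running_min, 1)
  }
  adj
}

bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

bf_hyper_upper <- function(k, K, N, n) {
  # P(X >= k), X ~ Hypergeom(N, K, n), by direct summation of choose() masses
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

bf_consistency <- function(values, patient_of, tp_of, ref_sign, baseline = 0) {
  tps <- sort(setdiff(unique(tp_of), baseline))
  out <- list()
  for (p in rownames(values)) {
    for (tp in tps) {
      hits <- 0; n <- 0
      for (pat in unique(patient_of)) {
        s0 <- which(patient_of == pat & tp_of == baseline)
        s1 <- which(patient_of == pat & tp_of == tp)
        if (length(s0) == 1 && length(s1) == 1 &&
            !is.na(values[p, s0]) && !is.na(values[p, s1])) {
          n <- n + 1
          d <- values[p, s1] - values[p, s0]
          if (sign(d) == ref_sign[[p]]) hits <- hits + 1
        }
      }
      if (n > 0) out[[length(out) + 1]] <-
          data.frame(protein_id = p, timepoint_months = tp,
                     n_evaluable = n, consistency = hits / n)
    }
  }
  do.call(rbind, out)
}

bf_best_cutoff <- function(dp, dh, grid, min_frac = 0.25) {
  best <- NULL
  for (th in sort(grid)) {
    pred <- ifelse(dp >= th, 1, ifelse(dp <= -th, -1, NA))
    actual <- ifelse(dh >= 0, 1, -1)
    ok <- !is.na(pred)
    if (sum(ok) / length(dp) < min_frac || sum(ok) == 0) next
    conc <- mean(pred[ok] == actual[ok])
    if (is.null(best) || conc > best$conc) best <- list(theta = th, conc = conc)
  }
  best
}
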