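#' Remove samples with low total intensity
#'
#' Samples whose summed non-missing raw intensity falls below `threshold`
#' are removed (the study's TMT quality filter; the threshold is in the
#' dataset's arbitrary intensity units and is configuration, not science).
#'
#' @param matrix A raw-scale [intensity_matrix()].
#' @param threshold Minimum summed intensity a sample must reach.
#' @return A list with `matrix` (filtered) and `removed` (tibble of removed
#'   sample IDs and their totals).
#' @export
filter_low_intensity_samples <- function(matrix, threshold = 225) {
  if (matrix$scale != "raw") abort("Sample-intensity filter expects a raw-scale matrix.")
  totals <- colSums(matrix$values, na.rm = TRUE)
  drop <- totals < threshold
  if (all(drop)) abort("All samples fall below the intensity threshold.")
  removed <- tibble::tibble(sample_id = names(totals)[drop],
                            total_intensity = unname(totals[drop]))
  if (nrow(removed)) {
    inform(sprintf("Removed %d low-intensity sample(s): %s",
                   nrow(removed), paste(removed$sample_id, collapse = ", ")))
  }
  list(matrix = set_values(matrix, matrix$values[, !drop, drop = FALSE]),
       removed = removed)
}

#' Detection filter
#'
#' A protein is kept iff it was detected (non-missing) in at least
#' `min_within_patient` samples of at least one patient AND detected in at
#' least `min_patients` distinct patients. Protein order is preserved.
#'
#' @param matrix An [intensity_matrix()].
#' @param meta Sample metadata covering every sample in `matrix`.
#' @param min_within_patient Minimum detections within a single patient.
#' @param min_patients Minimum number of patients with any detection.
#' @return The filtered [intensity_matrix()].
#' @export
filter_detection <- function(matrix, meta, min_within_patient = 2, min_patients = 2) {
  meta <- meta[match(sample_ids(matrix), meta$sample_id), ]
  if (anyNA(meta$sample_id)) abort("Every sample needs a metadata row.")
  detected <- !is.na(matrix$values)
  patients <- unique(meta$patient_id)
  # detections per (protein, patient)
  per_patient <- vapply(patients, function(p) {
    rowSums(detected[, meta$patient_id == p, drop = FALSE])
  }, numeric(nrow(detected)))
  if (is.null(dim(per_patient))) per_patient <- matrix(per_patient, nrow = 1)
  keep <- (apply(per_patient, 1, max) >= min_within_patient) &
    (rowSums(per_patient >= 1) >= min_patients)
  if (!any(keep)) warn("Detection filter removed every protein.")
  set_values(matrix, matrix$values[keep, , drop = FALSE])
}

glog2 <- function(x, lambda) log2((x + sqrt(x^2 + lambda^2)) / 2)

#' Variance-stabilizing transformation
#'
#' Two-step normalization of a raw-scale matrix: (1) a robust per-sample
#' affine calibration `a_s + b_s * x` with `b_s = median_ref / median_s`
#' and `a_s = 0` (reference: the median sample), so all sample medians
#' agree exactly after calibration; the gain correction is purely
#' multiplicative because instrument gain acts multiplicatively and a
#' raw-scale additive offset would distort the low-intensity range where
#' the additive noise floor lives; (2) a generalized
#' log transform `glog2(x) = log2((x + sqrt(x^2 + lambda^2)) / 2)`, which
#' tends to `log2(x)` for `x >> lambda` and is linear near zero. The global
#' `lambda` is chosen on a grid (quantiles of the calibrated data, plus 0)
#' to minimize the absolute Spearman correlation between per-protein mean
#' and SD — i.e. to flatten the mean-variance trend. Missing entries stay
#' missing. Differences on the returned scale are log2 fold changes.
#'
#' @param matrix A raw-scale [intensity_matrix()] with >= 2 samples.
#' @param lambda Optional fixed glog parameter (skips the grid search).
#' @param grid_size Number of candidate lambdas when searching.
#' @return A list with `matrix` (scale `"vst"`) and `params` (per-sample
#'   `offset`/`scale` tibble, chosen `lambda`, and the mean-SD Spearman
#'   correlation before and after).
#' @export
vst_normalize <- function(matrix, lambda = NULL, grid_size = 20) {
  if (matrix$scale != "raw") abort("vst_normalize expects a raw-scale matrix.")
  v <- matrix$values
  if (ncol(v) < 2) abort("Need at least 2 samples.")
  med <- apply(v, 2, median, na.rm = TRUE)
  if (any(med <= 0)) abort("A sample has non-positive median intensity; cannot calibrate.")
  ref <- order(med)[ceiling(ncol(v) / 2)]
  b <- med[ref] / med
  a <- rep(0, ncol(v))
  calib <- sweep(v, 2, b, `*`)

  mean_sd_rho <- function(m) {
    mu <- rowMeans(m, na.rm = TRUE)
    s <- apply(m, 1, sd, na.rm = TRUE)
    ok <- is.finite(mu) & is.finite(s)
    if (sum(ok) < 3) return(NA_real_)
    cor(mu[ok], s[ok], method = "spearman")
  }
  rho_raw <- mean_sd_rho(calib)

  if (is.null(lambda)) {
    rho_at <- function(l) {
      g <- glog2(calib, l)
      if (any(!is.finite(g[!is.na(g)]))) return(NA_real_)
      mean_sd_rho(g)
    }
    pos <- calib[!is.na(calib) & calib > 0]
    grid <- unique(unname(quantile(pos, probs = seq(0.001, 0.999,
                                                    length.out = grid_size))))
    # lambda = 0 (plain log2) is only admissible when everything is positive
    if (min(calib, na.rm = TRUE) > 0) grid <- c(0, grid)
    rho_grid <- vapply(grid, rho_at, numeric(1))
    best <- which.min(abs(rho_grid))
    lambda <- grid[best]
    best_rho <- abs(rho_grid[best])
    # rho(lambda) increases through its zero; bisect any sign change on
    # log-lambda to land close to the crossing
    flip <- which(diff(sign(rho_grid)) != 0 & !is.na(diff(rho_grid)))
    if (length(flip)) {
      i <- flip[1]
      lo <- max(grid[i], min(pos) * 1e-6); hi <- grid[i + 1]
      rlo <- rho_at(lo)
      for (iter in 1:30) {
        mid <- sqrt(lo * hi)
        rmid <- rho_at(mid)
        if (is.na(rmid)) break
        if (abs(rmid) < best_rho) {
          best_rho <- abs(rmid)
          lambda <- mid
        }
        if (sign(rmid) == sign(rlo)) {
          lo <- mid; rlo <- rmid
        } else hi <- mid
        if (best_rho < 1e-3 || hi / lo < 1.0001) break
      }
    }
  }
  out <- glog2(calib, lambda)
  params <- list(
    samples = tibble::tibble(sample_id = colnames(v), offset = unname(a),
                             scale = unname(b)),
    lambda = lambda,
    mean_sd_rho_raw = rho_raw,
    mean_sd_rho_vst = mean_sd_rho(out)
  )
  list(matrix = set_values(matrix, out, scale = "vst"), params = params)
}

#' Apply previously fitted VST parameters
#'
#' @param matrix A raw-scale [intensity_matrix()] whose samples appear in
#'   `params$samples`.
#' @param params The `params` element returned by [vst_normalize()].
#' @return The transformed [intensity_matrix()] (scale `"vst"`).
#' @export
vst_apply <- function(matrix, params) {
  if (matrix$scale != "raw") abort("vst_apply expects a raw-scale matrix.")
  idx <- match(sample_ids(matrix), params$samples$sample_id)
  if (anyNA(idx)) abort("Fitted VST parameters do not cover all samples.")
  calib <- sweep(sweep(matrix$values, 2, params$samples$scale[idx], `*`),
                 2, params$samples$offset[idx], `+`)
  set_values(matrix, glog2(calib, params$lambda), scale = "vst")
}

#' k-nearest-neighbour imputation
#'
#' For each missing entry `(p, s)`: among proteins observed at sample `s`,
#' find the `k` proteins whose profiles co-vary most closely with `p` and
#' impute the inverse-distance-weighted mean of their offset-adjusted
#' values at `s`. Each candidate neighbour `q` gets an intercept
#' `offset_q = mean(x_q - x_p)` over the samples observed in both
#' profiles, and the distance is the root mean square of the
#' offset-adjusted differences; two proteins with identical shapes at
#' different abundance levels are therefore distance zero, and a constant
#' abundance gap carries no penalty — it holds no information about
#' sample-specific deviations and would otherwise dominate the metric.
#' The imputed value is the weighted mean of `x_q[s] - offset_q` over the
#' `k` nearest neighbours. Distance ties are broken by protein ID
#' (lexicographic), so the result is deterministic. When fewer than `k`
#' candidate neighbours share any observed sample with `p`, the protein's
#' own observed mean is used instead. Observed entries are never altered.
#'
#' @param matrix A vst-scale [intensity_matrix()]; every protein must have
#'   at least one observed value.
#' @param k Number of neighbours.
#' @return A complete [intensity_matrix()] (no missing values).
#' @export
knn_impute <- function(matrix, k = 10) {
  if (k < 1) abort("`k` must be >= 1.")
  v <- matrix$values
  obs <- !is.na(v)
  none <- which(rowSums(obs) == 0)
  if (length(none)) {
    abort(paste0("Protein(s) with no observed values: ",
                 paste(rownames(v)[none], collapse = ", ")))
  }
  if (all(obs)) return(matrix)
  ids <- rownames(v)
  ord_rank <- rank(ids, ties.method = "first")  # lexicographic tie-break
  row_means <- rowSums(v, na.rm = TRUE) / rowSums(obs)
  out <- v
  need <- which(rowSums(!obs) > 0)
  for (p in need) {
    diffs <- v - matrix(v[p, ], nrow(v), ncol(v), byrow = TRUE)
    shared <- obs & matrix(obs[p, ], nrow(v), ncol(v), byrow = TRUE)
    diffs[!shared] <- 0
    nshared <- rowSums(shared)
    offset <- rowSums(diffs) / nshared
    # E[(diff - offset)^2] over shared samples = E[diff^2] - offset^2
    d <- sqrt(pmax(rowSums(diffs^2) / nshared - offset^2, 0))
    d[p] <- NA
    d[nshared == 0] <- NA
    ord <- order(d, ord_rank, na.last = NA)  # usable neighbours, nearest first
    miss_s <- which(!obs[p, ])
    for (s in miss_s) {
      nb <- ord[obs[ord, s]]
      if (length(nb) < k) {
        out[p, s] <- row_means[p]
        next
      }
      nb <- nb[seq_len(k)]
      w <- 1 / pmax(d[nb], .Machine$double.eps)
      out[p, s] <- sum(w * (v[nb, s] - offset[nb])) / sum(w)
    }
  }
  set_values(matrix, out)
}
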