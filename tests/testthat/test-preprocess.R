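test_that("low-intensity samples are removed by their summed intensity", {
  v <- matrix(c(50, 50, 150, 150, 200, 200), 2,
              dimnames = list(c("P1", "P2"), c("s1", "s2", "s3")))
  im <- intensity_matrix(v, "TMT")
  expect_message(filter_low_intensity_samples(im, 225), "s1")
  f <- suppressMessages(filter_low_intensity_samples(im, 225))
  expect_identical(f$removed$sample_id, "s1")
  expect_identical(sample_ids(f$matrix), c("s2", "s3"))

  f0 <- filter_low_intensity_samples(im, 0)
  expect_equal(nrow(f0$removed), 0)
  expect_error(filter_low_intensity_samples(im, 1e9), "All samples")
})

test_that("planted low-quality samples are exactly the ones filtered", {
  co <- simulate_cohort(small_sim_config(plant_low_quality = TRUE), seed = 9)
  totals <- colSums(co$tmt$values, na.rm = TRUE)
  f <- suppressMessages(
    filter_low_intensity_samples(co$tmt, threshold = 0.01 * median(totals)))
  expect_setequal(f$removed$sample_id, co$truth$low_quality_samples)
})

test_that("detection filter matches its rule on hand cases and random instances", {
  # 4 patients x 2 samples each; hand-built patterns
  co <- random_matrix_cohort(1, 4, 2, missing_rate = 0)
  meta <- co$meta
  pats <- meta$patient_id
  make <- function(present) {
    v <- matrix(NA_real_, 1, nrow(meta),
                dimnames = list("PR", meta$sample_id))
    v[1, present] <- 10
    intensity_matrix(v, "TMT")
  }
  in_pat <- function(p) which(pats == sprintf("P%02d", p))
  # seen twice in patient 1 only: fails the two-patient rule
  m1 <- suppressWarnings(filter_detection(make(in_pat(1)), meta))
  expect_equal(nrow(m1$values), 0)
  # seen twice in patient 1 and once in patient 2: kept
  m2 <- filter_detection(make(c(in_pat(1), in_pat(2)[1])), meta)
  expect_equal(nrow(m2$values), 1)
  # fully observed matrix passes unchanged
  full <- random_matrix_cohort(10, 3, 3, missing_rate = 0)
  expect_identical(filter_detection(full$matrix, full$meta)$values,
                   full$matrix$values)

  set.seed(21)
  for (i in 1:100) {
    n_prot <- sample(3:12, 1)
    co <- random_matrix_cohort(n_prot, sample(2:5, 1), sample(2:4, 1),
                               missing_rate = runif(1, 0.2, 0.8))
    meta <- co$meta[match(sample_ids(co$matrix), co$meta$sample_id), ]
    expected <- bf_detection_keep(co$matrix$values, meta$patient_id)
    got <- suppressWarnings(filter_detection(co$matrix, co$meta))
    if (!any(expected)) {
      expect_equal(nrow(got$values), 0)
    } else {
      expect_identical(rownames(got$values),
                       rownames(co$matrix$values)[expected])
    }
  }
})

test_that("glog2 reduces to log2 at lambda 0 and calibration equalizes medians", {
  v <- matrix(2^runif(200, 8, 20), 50,
              dimnames = list(sprintf("p%02d", 1:50), paste0("s", 1:4)))
  im <- intensity_matrix(v, "TMT")
  fit <- vst_normalize(im, lambda = 0)
  expect_lt(abs(fit$matrix$values[1, 1] -
                  log2(v[1, 1] * fit$params$samples$scale[1])), 1e-6)
  # direct limit check of the transform itself
  expect_lt(abs(csfmarkers:::glog2(1e6, 0) - log2(1e6)), 1e-6)

  scaled <- v
  scaled[, 2] <- v[, 2] * 4
  fit2 <- vst_normalize(intensity_matrix(scaled, "TMT"), lambda = 1)
  calib_med <- vapply(seq_len(4), function(s) {
    median(fit2$params$samples$offset[s] +
             fit2$params$samples$scale[s] * scaled[, s])
  }, numeric(1))
  expect_lt(max(calib_med) - min(calib_med), 1e-8)
})

test_that("the transform decouples mean and SD and is monotone per sample", {
  for (s in 1:2) {
    co <- simulate_cohort(small_sim_config(), seed = s)
    fit <- vst_normalize(filter_detection(co$tmt, co$meta))
    expect_gt(fit$params$mean_sd_rho_raw, 0.5)
    expect_lt(abs(fit$params$mean_sd_rho_vst), 0.1)
    # monotone: observed value order preserved within every sample
    v_in <- filter_detection(co$tmt, co$meta)$values
    v_out <- fit$matrix$values
    for (col in sample(ncol(v_in), 5)) {
      ok <- !is.na(v_in[, col])
      expect_identical(order(v_in[ok, col]), order(v_out[ok, col]))
    }
  }
  expect_error(vst_normalize(vst_normalize(simulate_cohort(
    small_sim_config(), 1)$tmt)$matrix), "raw-scale")
})

test_that("vst_apply reproduces the fitted transform on the same data", {
  co <- simulate_cohort(small_sim_config(), seed = 3)
  m <- filter_detection(co$tmt, co$meta)
  fit <- vst_normalize(m)
  again <- vst_apply(m, fit$params)
  expect_equal(again$values, fit$matrix$values, tolerance = 1e-12)
})

test_that("kNN imputation fills every gap without touching observed values", {
  # two identical proteins: the twin's value is copied in with k = 1
  v <- matrix(c(1, 2, 3, 1, 2, 3, 5, 6, 7), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  v["B", "s2"] <- NA
  im <- intensity_matrix(v, "TMT", scale = "vst")
  imp <- knn_impute(im, k = 1)
  expect_equal(imp$values["B", "s2"], 2)

  full <- intensity_matrix(matrix(rnorm(20, 10), 4,
                                  dimnames = list(letters[1:4], paste0("s", 1:5))),
                           "TMT", scale = "vst")
  expect_identical(knn_impute(full, k = 2)$values, full$values)

  co <- simulate_cohort(small_sim_config(), seed = 5)
  m <- vst_normalize(filter_detection(co$tmt, co$meta))$matrix
  imp2 <- knn_impute(m, k = 10)
  expect_false(anyNA(imp2$values))
  obs <- !is.na(m$values)
  expect_identical(imp2$values[obs], m$values[obs])

  allna <- v
  allna["C", ] <- NA
  expect_error(knn_impute(intensity_matrix(allna, "TMT", scale = "vst")), "C")
})

test_that("kNN beats protein-mean imputation on hidden entries", {
  for (s in 1:2) {
    co <- simulate_cohort(small_sim_config(missing_rate = 0), seed = s)
    m <- vst_normalize(filter_detection(co$tmt, co$meta))$matrix
    v <- m$values
    set.seed(s)
    hide <- which(runif(length(v)) < 0.05)
    truth <- v[hide]
    v[hide] <- NA
    masked <- intensity_matrix(v, "TMT", scale = "vst")
    knn <- knn_impute(masked, k = 10)$values[hide]
    rmeans <- rowMeans(v, na.rm = TRUE)
    mean_imp <- rmeans[((hide - 1) %% nrow(v)) + 1]
    rmse <- function(x) sqrt(mean((x - truth)^2))
    expect_lt(rmse(knn), rmse(mean_imp))
  }
})
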