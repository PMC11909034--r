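test_that("per-protein OLS matches the normal-equations solution", {
  meta <- tibble::tibble(sample_id = c("a0", "a1", "b0", "b1"),
                         patient_id = c("A", "A", "B", "B"),
                         timepoint_months = c(0L, 10L, 0L, 10L),
                         platform = "TMT", batch_id = "b")
  y <- c(3.1, 5.4, 2.0, 4.9)
  v <- matrix(y, 1, dimnames = list("PR1", meta$sample_id))
  fits <- fit_protein_models(intensity_matrix(v, "TMT", scale = "vst"), meta)
  X <- cbind(tp0 = c(1, 0, 1, 0), tp10 = c(0, 1, 0, 1), patB = c(0, 0, 1, 1))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fits$coefficients[1, ]), unname(drop(beta)), tolerance = 1e-10)
  res <- y - X %*% beta
  expect_equal(unname(fits$s2), sum(res^2) / (4 - 3), tolerance = 1e-10)
  expect_equal(fits$df_residual, 1)

  # random designs against the same oracle
  set.seed(13)
  for (i in 1:20) {
    co <- random_matrix_cohort(5, sample(3:5, 1), sample(2:3, 1), missing_rate = 0)
    meta_i <- co$meta[match(sample_ids(co$matrix), co$meta$sample_id), ]
    f <- fit_protein_models(co$matrix, co$meta)
    tp_f <- factor(meta_i$timepoint_months,
                   levels = sort(unique(meta_i$timepoint_months)))
    Xi <- cbind(stats::model.matrix(~ 0 + tp_f),
                stats::model.matrix(~ factor(meta_i$patient_id))[, -1, drop = FALSE])
    bi <- solve(t(Xi) %*% Xi, t(Xi) %*% t(co$matrix$values))
    expect_equal(unname(f$coefficients), unname(t(bi)), tolerance = 1e-10)
  }
})

test_that("noise-free planted effects and sample-order invariance behave exactly", {
  co <- toy_adjust_cohort(offsets = c(1, 2, 3), tp_effect = 1)
  fits <- fit_protein_models(co$matrix, co$meta)
  est <- fits$coefficients[1, "tp10"] - fits$coefficients[1, "tp0"]
  expect_equal(unname(est), 1, tolerance = 1e-12)
  expect_equal(unname(fits$s2), 0, tolerance = 1e-12)

  perm <- sample(ncol(co$matrix$values))
  shuffled <- intensity_matrix(co$matrix$values[, perm, drop = FALSE],
                               "TMT", scale = "vst")
  fits2 <- fit_protein_models(shuffled, co$meta)
  expect_equal(fits2$coefficients, fits$coefficients, tolerance = 1e-12)
})

test_that("moderated t collapses to the classical t when no shrinkage applies", {
  co <- random_matrix_cohort(40, 4, 3, missing_rate = 0)
  fits <- fit_protein_models(co$matrix, co$meta)

  m0 <- moderate_variances(fits, d0 = 0)
  tab0 <- test_contrasts(m0)
  # classical t computed directly from s2 and the contrast variance
  X <- fits$design$X
  cvec <- numeric(ncol(X)); cvec[2] <- 1; cvec[1] <- -1
  vc <- drop(t(cvec) %*% solve(t(X) %*% X) %*% cvec)
  est <- drop(fits$coefficients %*% cvec)
  t_classic <- est / sqrt(fits$s2 * vc)
  tp <- sort(unique(co$meta$timepoint_months))[1:2]
  sub <- dplyr::filter(tab0, t_from == tp[1], t_to == tp[2])
  expect_equal(sub$t, unname(t_classic), tolerance = 1e-9)
  expect_equal(sub$p, unname(2 * pt(-abs(t_classic), fits$df_residual)),
               tolerance = 1e-9)

  # equal residual variances: estimated prior is degenerate, t unchanged
  fits_eq <- fits
  fits_eq$s2[] <- 2.5
  meq <- moderate_variances(fits_eq)
  expect_true(is.infinite(meq$d0))
  expect_equal(meq$s2_post, setNames(rep(2.5, length(fits$s2)), fits$proteins),
               tolerance = 1e-9)
})

test_that("prior parameters are recovered from simulated variances", {
  d <- 8
  est <- t(vapply(1:10, function(s) {
    set.seed(s)
    sigma2 <- 4 * 2 / rchisq(2000, df = 4)        # scaled inv-chi2(d0=4, s02=2)
    s2 <- sigma2 * rchisq(2000, df = d) / d
    fake <- structure(list(s2 = s2, df_residual = d,
                           proteins = sprintf("p%04d", 1:2000)),
                      class = "protein_fits")
    m <- moderate_variances(fake)
    c(d0 = m$d0, s02 = m$s02)
  }, numeric(2)))
  expect_true(all(est[, "d0"] > 3 & est[, "d0"] < 5))
  expect_true(all(est[, "s02"] > 1.8 & est[, "s02"] < 2.2))
})

test_that("variance moderation agrees with limma's empirical Bayes", {
  skip_if_not_installed("limma")
  set.seed(7)
  s2 <- 2 * rchisq(500, df = 6) / 6 * (0.5 + rexp(500))
  fake <- structure(list(s2 = s2, df_residual = 6,
                         proteins = sprintf("p%03d", 1:500)),
                    class = "protein_fits")
  m <- moderate_variances(fake)
  ref <- limma::squeezeVar(s2, df = 6)
  expect_equal(m$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(m$s02, ref$var.prior, tolerance = 1e-6)
  expect_equal(unname(m$s2_post), ref$var.post, tolerance = 1e-8)
})

test_that("contrast enumeration, zero contrasts and direct CDF checks line up", {
  co <- simulate_cohort(sim_config(
    n_patients = 4, visits_per_patient = rep(7L, 4),
    n_proteins_tmt = 30, n_proteins_lfq = 20, n_shared = 15,
    n_dep = 2, n_coupled = 0, missing_rate = 0), seed = 1)
  m <- vst_normalize(co$tmt)$matrix
  tab <- test_contrasts(moderate_variances(fit_protein_models(m, co$meta)))
  expect_equal(dplyr::n_distinct(tab$contrast), choose(7, 2))
  expect_error(test_contrasts(moderate_variances(fit_protein_models(m, co$meta)),
                              timepoints = c(0, 99)), "99")

  # hand toy: known s2_post and estimate against a direct CDF evaluation
  mfit <- moderate_variances(fit_protein_models(m, co$meta), d0 = 3)
  tab2 <- test_contrasts(mfit)
  row <- tab2[17, ]
  cvec <- numeric(ncol(mfit$fits$coefficients))
  cvec[match(paste0("tp", row$t_to), colnames(mfit$fits$coefficients))] <- 1
  cvec[match(paste0("tp", row$t_from), colnames(mfit$fits$coefficients))] <- -1
  vc <- drop(t(cvec) %*% mfit$fits$xtx_inv %*% cvec)
  tt <- row$log2fc / sqrt(mfit$s2_post[[row$protein_id]] * vc)
  expect_equal(row$t, tt, tolerance = 1e-9)
  expect_equal(row$p, 2 * (1 - pt(abs(tt), mfit$df_total)), tolerance = 1e-9)

  # an exactly zero contrast estimate gives t = 0, p = 1
  meta <- tibble::tibble(sample_id = paste0("s", 1:8),
                         patient_id = rep(c("A", "B"), 4),
                         timepoint_months = rep(c(0L, 0L, 10L, 10L), 2),
                         platform = "TMT", batch_id = "b")
  vz <- matrix(c(1, 2, 1, 2, 1, 2, 1, 2), 1,
               dimnames = list("PR", meta$sample_id))
  fz <- fit_protein_models(intensity_matrix(vz, "TMT", scale = "vst"), meta)
  tz <- test_contrasts(moderate_variances(fz, d0 = 0))
  expect_equal(tz$t[1], 0)
  expect_equal(tz$p[1], 1)
})

test_that("BH adjustment matches hand values and a brute-force oracle", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_fdr(p), bf_bh(p), tolerance = 1e-12)
  }
})

test_that("DEP calling applies strict thresholds and is monotone in them", {
  tab <- tibble::tibble(
    protein_id = paste0("p", 1:4), contrast = "m10_vs_m0",
    t_from = 0, t_to = 10,
    log2fc = c(0.51, 0.51, -0.6, 0.5), t = 1, p = 0.01,
    fdr = c(0.049, 0.05, 0.01, 0.01)
  )
  called <- call_deps(tab)
  expect_identical(called$is_dep, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(called$direction, c("up", "up", "down", "up"))

  co <- simulate_cohort(small_sim_config(), seed = 2)
  m <- knn_impute(vst_normalize(filter_detection(co$tmt, co$meta))$matrix)
  tab2 <- add_fdr(test_contrasts(moderate_variances(fit_protein_models(m, co$meta))))
  n_dep <- function(a, fc) sum(call_deps(tab2, a, fc)$is_dep)
  expect_gte(n_dep(0.05, 0.5), n_dep(0.01, 0.5))
  expect_gte(n_dep(0.05, 0.5), n_dep(0.05, 1.0))
  expect_gte(n_dep(0.01, 0.5), n_dep(0.01, 1.0))
})
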