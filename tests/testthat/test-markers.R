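test_that("consistency scores equal the brute-force per-patient loop", {
  # all patients move with the reference direction
  co <- random_matrix_cohort(4, 5, 3, missing_rate = 0)
  v <- co$matrix$values
  meta <- co$meta[match(colnames(v), co$meta$sample_id), ]
  v[] <- rep(meta$timepoint_months, each = nrow(v))  # strictly increasing
  up <- intensity_matrix(v, "TMT", scale = "vst")
  refs <- setNames(rep(1, nrow(v)), rownames(v))
  cs <- consistency_scores(up, co$meta, refs)
  expect_true(all(cs$consistency == 1))

  # 3 of 4 patients up, reference up -> 0.75
  co2 <- random_matrix_cohort(1, 4, 2, missing_rate = 0)
  v2 <- co2$matrix$values
  meta2 <- co2$meta[match(colnames(v2), co2$meta$sample_id), ]
  v2[] <- 0
  v2[1, meta2$timepoint_months > 0] <- c(1, 1, 1, -1)
  cs2 <- consistency_scores(intensity_matrix(v2 + 10, "TMT", scale = "vst"),
                            co2$meta, c(PR001 = 1))
  expect_equal(cs2$consistency, 0.75)
  expect_equal(cs2$n_evaluable, 4L)

  set.seed(17)
  for (i in 1:30) {
    co3 <- random_matrix_cohort(sample(2:5, 1), sample(3:6, 1), sample(2:4, 1),
                                missing_rate = runif(1, 0, 0.5))
    meta3 <- co3$meta[match(sample_ids(co3$matrix), co3$meta$sample_id), ]
    refs3 <- setNames(sample(c(-1, 1), nrow(co3$matrix$values), TRUE),
                      protein_ids(co3$matrix))
    got <- consistency_scores(co3$matrix, co3$meta, refs3)
    want <- bf_consistency(co3$matrix$values, meta3$patient_id,
                           meta3$timepoint_months, refs3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got <- dplyr::arrange(got, protein_id, timepoint_months)
      want <- dplyr::arrange(tibble::as_tibble(want), protein_id, timepoint_months)
      expect_equal(got$consistency, want$consistency)
      expect_equal(got$n_evaluable, want$n_evaluable)
    }
  }
})

test_that("change-change correlation reproduces exact and null behaviour", {
  dx <- tibble::tibble(feature = "prot",
                       patient_id = rep(sprintf("P%02d", 1:10), 2),
                       timepoint_months = rep(c(10, 18), each = 10),
                       delta = rnorm(20))
  dy <- dx
  dy$feature <- "hfmse"
  res <- clinical_correlation(dx, dy)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-12)

  # independent: r near 0 and p matches cor.test
  set.seed(23)
  dy2 <- dy
  dy2$delta <- rnorm(20)
  res2 <- clinical_correlation(dx, dy2)
  ct <- cor.test(dx$delta, dy2$delta)
  expect_equal(res2$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res2$p, ct$p.value, tolerance = 1e-10)

  # zero-variance feature is skipped with a message
  dx0 <- dx
  dx0$delta <- 1
  expect_message(res3 <- clinical_correlation(dx0, dy2), "zero variance")
  expect_equal(nrow(res3), 0)
})

test_that("correlation p-values agree with a permutation test", {
  set.seed(5)
  x <- rnorm(8)
  y <- 0.8 * x + rnorm(8, 0, 0.8)
  dx <- tibble::tibble(feature = "f", patient_id = sprintf("P%d", 1:8),
                       timepoint_months = 10, delta = x)
  dy <- tibble::tibble(feature = "hfmse", patient_id = sprintf("P%d", 1:8),
                       timepoint_months = 10, delta = y)
  p_t <- clinical_correlation(dx, dy)$p
  r_obs <- abs(cor(x, y))
  perm <- replicate(10000, abs(cor(x, sample(y))))
  p_perm <- (1 + sum(perm >= r_obs)) / (1 + 10000)
  expect_lt(abs(p_t - p_perm), 0.05)
})

test_that("routine clinical correlations recover the planted coupling signs", {
  rs <- t(vapply(1:3, function(s) {
    co <- simulate_cohort(small_sim_config(), seed = s)
    res <- suppressMessages(routine_parameter_correlations(co$clinical))
    setNames(res$r[match(c("qalb", "lactate", "glucose", "macrophages",
                           "total_protein"), res$feature)],
             c("qalb", "lactate", "glucose", "macrophages", "total_protein"))
  }, numeric(5)))
  expect_true(all(rs[, "qalb"] < 0))
  expect_true(all(rs[, "lactate"] < 0))
  expect_true(all(rs[, "glucose"] < 0))
  expect_true(all(rs[, "macrophages"] > 0))
  expect_lt(mean(abs(rs[, "total_protein"])), 0.3)  # uncoupled stays weak

  const <- simulate_cohort(small_sim_config(), seed = 1)$clinical
  const$lactate <- 2
  expect_message(out <- routine_parameter_correlations(const), "zero variance")
  expect_false("lactate" %in% out$feature)
})

test_that("cutoff rules classify, abstain and respect monotone invariance", {
  dp <- tibble::tibble(feature = "prot", patient_id = sprintf("P%d", 1:6),
                       timepoint_months = 10,
                       delta = c(0.6, 0.4, -0.5, -0.7, 0.1, -0.05))
  dh <- dp
  dh$feature <- "hfmse"
  dh$delta <- c(3, 2, -2, -4, 1, -1)

  rule <- cutoff_classifier(dp, dh, 0.3)
  expect_equal(rule$concordance, 1)
  expect_equal(rule$n_evaluated, 4)
  expect_equal(rule$abstention_rate, 1 - 4 / 6)

  expect_warning(r2 <- cutoff_classifier(dp, dh, 10), "abstained")
  expect_equal(r2$abstention_rate, 1)
  expect_true(is.na(r2$concordance))
  expect_error(cutoff_classifier(dp, dh, -1), "theta")

  # only the sign of the HFMSE change matters
  dh_t <- dh
  dh_t$delta <- dh$delta^3 + sign(dh$delta) * 0.2
  rule_t <- cutoff_classifier(dp, dh_t, 0.3)
  expect_equal(rule_t$concordance, rule$concordance)
  expect_equal(rule_t$confusion, rule$confusion)
})

test_that("the cutoff scan matches brute-force enumeration and tie rules", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    dp <- tibble::tibble(feature = "prot", patient_id = sprintf("P%d", 1:n),
                         timepoint_months = 10, delta = round(rnorm(n, 0, 0.6), 2))
    dh <- dplyr::mutate(dp, feature = "hfmse", delta = round(rnorm(n, 0, 3)))
    grid <- seq(0.1, 0.8, by = 0.1)
    got <- scan_cutoffs(dp, dh, grid = grid, min_evaluated_frac = 0.25)
    want <- bf_best_cutoff(dp$delta, dh$delta, grid)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$theta, want$theta)
      expect_equal(got$concordance, want$conc)
    }
  }
  # explicit tie: equal concordance at two cutoffs returns the smaller
  dp <- tibble::tibble(feature = "p", patient_id = sprintf("P%d", 1:4),
                       timepoint_months = 10, delta = c(1, 1, -1, -1))
  dh <- dplyr::mutate(dp, feature = "hfmse", delta = c(2, 2, -2, -2))
  best <- scan_cutoffs(dp, dh, grid = c(0.25, 0.5))
  expect_equal(best$theta, 0.25)
  expect_error(scan_cutoffs(dp, dh, grid = numeric(0)), "empty")
})

test_that("hypergeometric enrichment equals direct tail summation", {
  bg <- sprintf("g%02d", 1:20)
  ann <- list(term1 = bg[1:5], term2 = bg[6:10], absent = c("x1", "x2"))
  hits <- bg[c(1:4, 11)]
  res <- enrichment_test(hits, bg, ann)
  expect_false("absent" %in% res$term)
  r1 <- res[res$term == "term1", ]
  expect_equal(r1$k, 4)
  expect_equal(r1$p, bf_hyper_upper(4, 5, 20, 5), tolerance = 1e-12)
  r2 <- res[res$term == "term2", ]
  expect_equal(r2$k, 0)
  expect_equal(r2$p, 1, tolerance = 1e-12)

  expect_error(enrichment_test(c(bg[1], "nope"), bg, ann), "background")

  # data-frame annotation input and full-overlap exactness
  df_ann <- tibble::tibble(term = rep("t", 3), protein = bg[1:3])
  res2 <- enrichment_test(bg[1:3], bg, df_ann)
  expect_equal(res2$p, bf_hyper_upper(3, 3, 20, 3), tolerance = 1e-12)

  set.seed(27)
  for (i in 1:50) {
    N <- sample(5:30, 1)
    bgx <- sprintf("g%02d", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    term <- sample(bgx, K)
    hit <- sample(bgx, N)[seq_len(n)]
    k <- length(intersect(term, hit))
    res <- enrichment_test(hit, bgx, list(t = term))
    expect_equal(res$p, bf_hyper_upper(k, K, N, n), tolerance = 1e-12)
  }
})
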