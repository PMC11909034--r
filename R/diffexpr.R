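#' Fit per-protein patient-blocked linear models
#'
#' Ordinary least squares per protein on the design
#' `~ 0 + timepoint + patient` (one indicator per timepoint, patient
#' indicators with the first patient dropped for identifiability). All
#' proteins share the design, so a single QR factorization serves the whole
#' matrix.
#'
#' @param matrix A complete (imputed) vst-scale [intensity_matrix()].
#' @param meta Sample metadata.
#' @return A `protein_fits` object: coefficients, residual variances `s2`,
#'   residual df, and the design bookkeeping needed for contrasts.
#' @export
fit_protein_models <- function(matrix, meta) {
  v <- matrix$values
  if (anyNA(v)) abort("fit_protein_models needs a complete (imputed) matrix.")
  des <- build_design(meta, sample_ids(matrix))
  if (length(unique(des$meta$patient_id)) < 2) abort("Need at least 2 patients.")
  X <- des$X
  qx <- qr(X)
  beta <- t(qr.coef(qx, t(v)))
  fitted <- beta %*% t(X)
  res <- v - fitted
  d <- nrow(X) - qx$rank
  if (d <= 0) abort("No residual degrees of freedom (saturated design).")
  s2 <- rowSums(res^2) / d
  structure(list(
    coefficients = beta,
    s2 = s2,
    df_residual = d,
    xtx_inv = chol2inv(qr.R(qx)),
    design = des,
    proteins = rownames(v)
  ), class = "protein_fits")
}

#' @export
print.protein_fits <- function(x, ...) {
  cat(sprintf("<protein_fits> %d proteins, %d coefficients, %d residual df\n",
              length(x$proteins), ncol(x$coefficients), x$df_residual))
  invisible(x)
}

#' @export
tidy.protein_fits <- function(x, ...) {
  tibble::as_tibble(x$coefficients, rownames = "protein_id") |>
    dplyr::mutate(s2 = unname(x$s2), df = x$df_residual)
}

# Solve trigamma(x) = y by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-7          # huge x: trigamma(x) ~ 1/x
  out[lo] <- 1 / y[lo]
  hi <- y > 1e7           # tiny x: trigamma(x) ~ 1/x^2
  out[hi] <- 1 / sqrt(y[hi])
  mid <- !lo & !hi
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-protein residual variances toward a pooled prior. The prior
#' is a scaled inverse chi-square with df `d0` and scale `s0^2`, estimated
#' by matching the first two moments of `log(s2)`: with
#' `e = log(s2) - digamma(d/2) + log(d/2)`,
#' `var(e) = trigamma(d0/2) + trigamma(d/2)` and
#' `mean(e) = log(s0^2) + digamma(d0/2) - log(d0/2)`. The trigamma equation
#' is inverted by Newton iteration. When the observed spread of `log(s2)`
#' is no larger than expected from chi-square sampling alone, `d0` is
#' infinite and every posterior variance equals `s0^2`. Posterior
#' variances are `s2_post = (d0 s0^2 + d s2) / (d0 + d)` and downstream
#' t statistics gain `d0` degrees of freedom.
#'
#' @param fits A `protein_fits` object (>= 10 proteins recommended).
#' @param d0 Optional forced prior df (e.g. `0` for no moderation,
#'   `Inf` for complete pooling); default estimates it from the data.
#' @return A `moderated_fit` object.
#' @export
moderate_variances <- function(fits, d0 = NULL) {
  stopifnot(inherits(fits, "protein_fits"))
  s2 <- fits$s2
  d <- fits$df_residual
  ok <- is.finite(s2) & s2 > 0
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- if (sum(ok) > 1) stats::var(e) else 0
  evar <- evar - trigamma(d / 2)
  # geometric mean of the observed variances: the d0 = Inf limit, where the
  # observed spread carries no chi-square sampling noise to correct for
  geo <- exp(mean(log(s2[ok])))
  if (is.null(d0)) {
    if (sum(ok) < 2 || evar <= 0) {
      d0 <- Inf
      s02 <- geo
    } else {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    s02 <- if (is.finite(d0) && d0 > 0) {
      exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else geo
  }
  s2_post <- if (d0 == 0) s2 else if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  structure(list(fits = fits, d0 = d0, s02 = s02,
                 s2_post = setNames(s2_post, fits$proteins),
                 df_total = d0 + d), class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit> prior df d0 = %.3g, prior variance s0^2 = %.4g, total df = %.3g\n",
              x$d0, x$s02, x$df_total))
  invisible(x)
}

#' @export
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(n_proteins = length(x$fits$proteins),
                 df_residual = x$fits$df_residual,
                 d0 = x$d0, s02 = x$s02, df_total = x$df_total)
}

#' Pairwise timepoint contrasts with moderated t statistics
#'
#' Computes every pairwise timepoint contrast (later minus earlier, so a
#' positive log2 fold change means upregulation under therapy), the
#' moderated t statistic `estimate / sqrt(s2_post * v_c)` and a two-sided p
#' value on `d0 + d` degrees of freedom.
#'
#' @param mfit A `moderated_fit`.
#' @param timepoints Timepoints to compare (default: all in the design).
#' @return A tibble (one row per protein x contrast): `protein_id`,
#'   `contrast`, `t_from`, `t_to`, `log2fc`, `t`, `p`.
#' @export
test_contrasts <- function(mfit, timepoints = NULL) {
  fits <- mfit$fits
  des <- fits$design
  avail <- as.numeric(des$timepoints)
  timepoints <- timepoints %||% avail
  missing_tp <- setdiff(timepoints, avail)
  if (length(missing_tp)) {
    abort(paste0("Timepoint(s) not in the design: ",
                 paste(missing_tp, collapse = ", ")))
  }
  timepoints <- sort(timepoints)
  pairs <- utils::combn(timepoints, 2)
  ncoef <- ncol(fits$coefficients)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    t_from <- pairs[1, i]; t_to <- pairs[2, i]
    cvec <- numeric(ncoef)
    cvec[match(paste0("tp", t_to), colnames(fits$coefficients))] <- 1
    cvec[match(paste0("tp", t_from), colnames(fits$coefficients))] <- -1
    est <- drop(fits$coefficients %*% cvec)
    vc <- drop(t(cvec) %*% fits$xtx_inv %*% cvec)
    se <- sqrt(mfit$s2_post * vc)
    near_zero <- abs(est) < 1e-12
    tstat <- ifelse(se > 0, est / se,
                    ifelse(near_zero, 0, sign(est) * Inf))
    tstat[near_zero] <- 0
    pval <- 2 * pt(-abs(tstat), df = mfit$df_total)
    pval[tstat == 0] <- 1
    tibble::tibble(
      protein_id = fits$proteins,
      contrast = sprintf("m%d_vs_m%d", t_to, t_from),
      t_from = t_from, t_to = t_to,
      log2fc = unname(est), t = unname(tstat), p = unname(pval)
    )
  })
  res
}

#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @return The BH step-up adjusted vector.
#' @export
adjust_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Add FDR columns to a contrast table
#'
#' @param table A tibble from [test_contrasts()].
#' @param scope `"per_contrast"` (BH across proteins within each contrast,
#'   the default) or `"global"` (one BH pass over all rows).
#' @return The table with an `fdr` column.
#' @export
add_fdr <- function(table, scope = c("per_contrast", "global")) {
  scope <- match.arg(scope)
  if (scope == "per_contrast") {
    table |>
      dplyr::group_by(.data$contrast) |>
      dplyr::mutate(fdr = adjust_fdr(.data$p)) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(table, fdr = adjust_fdr(.data$p))
  }
}

#' Flag differentially expressed proteins
#'
#' A protein is a DEP for a contrast iff `fdr < fdr_alpha` and
#' `|log2fc| > log2fc_min`, both strict.
#'
#' @param table A contrast table with an `fdr` column (see [add_fdr()]).
#' @param fdr_alpha FDR threshold (strict `<`).
#' @param log2fc_min Absolute log2 fold-change threshold (strict `>`).
#' @return The table with `is_dep` and `direction` (`"up"`/`"down"`)
#'   columns.
#' @export
call_deps <- function(table, fdr_alpha = 0.05, log2fc_min = 0.5) {
  if (!"fdr" %in% names(table)) abort("Run add_fdr() first.")
  dplyr::mutate(table,
                is_dep = .data$fdr < fdr_alpha & abs(.data$log2fc) > log2fc_min,
                direction = ifelse(.data$log2fc > 0, "up", "down"))
}

#' DEP counts per contrast
#'
#' The per-contrast summary behind the usual "number of pairwise DEPs"
#' barplot.
#'
#' @param table A DEP-flagged table from [call_deps()].
#' @return A tibble with `contrast`, `n_up`, `n_down`, `n_dep`.
#' @export
dep_counts <- function(table) {
  table |>
    dplyr::group_by(.data$contrast, .data$t_from, .data$t_to) |>
    dplyr::summarise(
      n_up = sum(.data$is_dep & .data$direction == "up"),
      n_down = sum(.data$is_dep & .data$direction == "down"),
      n_dep = sum(.data$is_dep),
      .groups = "drop"
    )
}

#' Full differential-expression pass
#'
#' Convenience wrapper: fit patient-blocked models, moderate variances,
#' test all pairwise timepoint contrasts, adjust within contrast, and flag
#' DEPs at the given thresholds.
#'
#' @inheritParams fit_protein_models
#' @inheritParams call_deps
#' @inheritParams add_fdr
#' @return A DEP table (see [call_deps()]).
#' @export
dep_analysis <- function(matrix, meta, fdr_alpha = 0.05, log2fc_min = 0.5,
                         scope = "per_contrast") {
  fit_protein_models(matrix, meta) |>
    moderate_variances() |>
    test_contrasts() |>
    add_fdr(scope = scope) |>
    call_deps(fdr_alpha = fdr_alpha, log2fc_min = log2fc_min)
}
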