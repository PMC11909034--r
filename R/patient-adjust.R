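# Patient-blocked design matrix: one indicator per timepoint (no intercept)
# plus patient indicators with the first patient dropped for identifiability.
build_design <- function(meta, samples) {
  meta <- meta[match(samples, meta$sample_id), ]
  if (anyNA(meta$sample_id)) abort("Every sample needs a metadata row.")
  tp <- factor(meta$timepoint_months, levels = sort(unique(meta$timepoint_months)))
  pat <- factor(meta$patient_id)
  if (nlevels(tp) < 2) abort("Need at least 2 timepoints.")
  Xt <- stats::model.matrix(~ 0 + tp)
  colnames(Xt) <- paste0("tp", levels(tp))
  if (nlevels(pat) > 1) {
    Xp <- stats::model.matrix(~ pat)[, -1, drop = FALSE]
    colnames(Xp) <- paste0("patient", levels(pat)[-1])
  } else {
    Xp <- matrix(numeric(0), nrow(Xt), 0)
  }
  X <- cbind(Xt, Xp)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0("Design is rank deficient (patient confounded with timepoint?); aliased: ",
                 paste(aliased, collapse = ", ")))
  }
  singles <- names(which(table(meta$patient_id) == 1))
  if (length(singles)) {
    inform(paste0("Patient(s) with a single sample: ",
                  paste(singles, collapse = ", ")))
  }
  list(X = X, timepoints = levels(tp), tp_cols = seq_len(nlevels(tp)),
       patient_cols = nlevels(tp) + seq_len(ncol(Xp)), meta = meta)
}

#' Remove inter-patient heterogeneity
#'
#' Per protein, fits ordinary least squares on a design with timepoint
#' indicators plus patient indicators and subtracts only the fitted patient
#' component, so timepoint (treatment) effects are preserved: timepoint
#' contrasts computed on the adjusted data equal those on the original
#' data.
#'
#' @param matrix A complete (imputed) [intensity_matrix()].
#' @param meta Sample metadata.
#' @return The adjusted [intensity_matrix()] (same scale tag).
#' @export
remove_patient_effect <- function(matrix, meta) {
  v <- matrix$values
  if (anyNA(v)) abort("remove_patient_effect needs a complete (imputed) matrix.")
  des <- build_design(meta, sample_ids(matrix))
  X <- des$X
  beta <- t(qr.coef(qr(X), t(v)))  # proteins x coefficients
  if (length(des$patient_cols)) {
    pat_fit <- beta[, des$patient_cols, drop = FALSE] %*%
      t(X[, des$patient_cols, drop = FALSE])
    # centre the patient component so overall protein means are preserved
    pat_fit <- pat_fit - rowMeans(pat_fit)
    v <- v - pat_fit
  }
  set_values(matrix, v)
}

#' Standardize proteins to z-scores
#'
#' Scales each protein (row) to mean 0 and sample SD 1 (n - 1 denominator)
#' across samples. Constant proteins cannot be scaled and are dropped with
#' a warning.
#'
#' @param matrix A complete [intensity_matrix()].
#' @return An [intensity_matrix()] with scale `"zscore"`.
#' @export
zscore_rows <- function(matrix) {
  v <- matrix$values
  if (anyNA(v)) abort("zscore_rows needs a complete matrix.")
  s <- apply(v, 1, sd)
  const <- s == 0
  if (any(const)) {
    warn(paste0("Dropping ", sum(const), " constant protein(s): ",
                paste(head(rownames(v)[const], 5), collapse = ", ")))
    v <- v[!const, , drop = FALSE]
    s <- s[!const]
  }
  z <- (v - rowMeans(v)) / s
  set_values(matrix, z, scale = "zscore")
}

#' Pairwise Pearson correlation between samples
#'
#' @param matrix A z-scored [intensity_matrix()] with >= 3 proteins.
#' @return A `correlation_heatmap` object: the symmetric correlation
#'   matrix, unclustered (sample order as given).
#' @export
sample_correlation <- function(matrix) {
  v <- matrix$values
  if (nrow(v) < 3) abort("Need at least 3 proteins for sample correlation.")
  r <- cor(v)
  structure(list(r = r, order = colnames(r), hclust = NULL),
            class = "correlation_heatmap")
}

#' @export
print.correlation_heatmap <- function(x, ...) {
  cat(sprintf("<correlation_heatmap> %d samples%s\n", ncol(x$r),
              if (is.null(x$hclust)) " (unclustered)" else " (clustered)"))
  invisible(x)
}

#' Hierarchically cluster a sample correlation matrix
#'
#' Agglomerative clustering of samples with distance `1 - r` and the given
#' linkage; the returned object carries the leaf order and merge tree.
#'
#' @param heatmap A `correlation_heatmap` from [sample_correlation()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return The `correlation_heatmap` with `order` (leaf order) and
#'   `hclust` filled in.
#' @export
hierarchical_cluster <- function(heatmap, linkage = "average") {
  d <- as.dist(1 - heatmap$r)
  hc <- hclust(d, method = linkage)
  heatmap$hclust <- hc
  heatmap$order <- colnames(heatmap$r)[hc$order]
  heatmap
}

#' Tidy a correlation heatmap
#'
#' @param x A `correlation_heatmap`.
#' @param ... Unused.
#' @return A tibble with one row per sample pair (`sample_a`, `sample_b`,
#'   `r`), samples in clustered order when available.
#' @export
tidy.correlation_heatmap <- function(x, ...) {
  ord <- x$order
  r <- x$r[ord, ord]
  tibble::tibble(
    sample_a = factor(rep(ord, times = length(ord)), levels = ord),
    sample_b = factor(rep(ord, each = length(ord)), levels = ord),
    r = as.vector(r)
  )
}

#' How contiguously a sample group sits in the clustered order
#'
#' For a set of samples (e.g. all pre-treatment samples), finds the best
#' window of that size in the leaf order and returns the fraction of the
#' group it contains. 1 means the group forms a perfectly contiguous block.
#'
#' @param heatmap A clustered `correlation_heatmap`.
#' @param members Character vector of sample IDs forming the group.
#' @return Block purity in `[0, 1]`.
#' @export
block_purity <- function(heatmap, members) {
  ord <- heatmap$order
  inb <- ord %in% members
  w <- sum(inb)
  if (w == 0) abort("No group member appears in the clustering.")
  hits <- vapply(seq_len(length(ord) - w + 1),
                 function(i) sum(inb[i:(i + w - 1)]), numeric(1))
  max(hits) / w
}
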