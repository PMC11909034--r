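#' Overlap of identified proteins between platforms
#'
#' @param tmt_ids,lfq_ids Character vectors of protein IDs identified by
#'   each platform.
#' @return An `overlap_report` list: counts (`n_tmt_only`, `n_lfq_only`,
#'   `n_shared`) and the corresponding ID vectors.
#' @export
overlap_identified <- function(tmt_ids, lfq_ids) {
  tmt_ids <- unique(tmt_ids); lfq_ids <- unique(lfq_ids)
  shared <- intersect(tmt_ids, lfq_ids)
  structure(list(
    n_tmt_only = length(setdiff(tmt_ids, lfq_ids)),
    n_lfq_only = length(setdiff(lfq_ids, tmt_ids)),
    n_shared = length(shared),
    shared = shared,
    tmt_only = setdiff(tmt_ids, lfq_ids),
    lfq_only = setdiff(lfq_ids, tmt_ids)
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> shared %d | TMT-only %d | LFQ-only %d\n",
              x$n_shared, x$n_tmt_only, x$n_lfq_only))
  invisible(x)
}

#' Abundance-rank table
#'
#' Ranks proteins by mean non-missing intensity (descending; ties broken by
#' protein ID so the ranking is deterministic) and flags a highlight set —
#' typically the proteins also covered by the shallower platform.
#'
#' @param matrix An [intensity_matrix()].
#' @param highlight Protein IDs to flag.
#' @return A tibble: `protein_id`, `mean_intensity`, `rank`, `highlighted`.
#' @export
rank_intensity <- function(matrix, highlight = character()) {
  v <- matrix$values
  mu <- rowMeans(v, na.rm = TRUE)
  ord <- order(-mu, rownames(v))
  tibble::tibble(
    protein_id = rownames(v)[ord],
    mean_intensity = unname(mu[ord]),
    rank = seq_along(ord),
    highlighted = rownames(v)[ord] %in% highlight
  )
}

#' Rank trajectories of the most abundant proteins
#'
#' Takes the overall top-`k` proteins by mean intensity and reports their
#' abundance rank within each timepoint (rank among all proteins, by mean
#' intensity over that timepoint's samples).
#'
#' @param matrix An [intensity_matrix()].
#' @param meta Sample metadata.
#' @param k Number of top proteins to follow.
#' @return A tibble: `protein_id`, `timepoint_months`, `rank`,
#'   `overall_rank`.
#' @export
top_rank_trajectory <- function(matrix, meta, k = 10) {
  v <- matrix$values
  if (k > nrow(v)) abort(sprintf("k = %d exceeds the %d proteins available.", k, nrow(v)))
  meta <- meta[match(sample_ids(matrix), meta$sample_id), ]
  overall <- rank_intensity(matrix)
  top <- overall$protein_id[seq_len(k)]
  tps <- sort(unique(meta$timepoint_months))
  purrr::map_dfr(tps, function(tp) {
    cols <- meta$sample_id[meta$timepoint_months == tp]
    mu <- rowMeans(v[, cols, drop = FALSE], na.rm = TRUE)
    ord <- order(-mu, rownames(v))
    rk <- setNames(seq_along(ord), rownames(v)[ord])
    tibble::tibble(protein_id = top, timepoint_months = tp,
                   rank = unname(rk[top]),
                   overall_rank = match(top, overall$protein_id))
  })
}

#' Direction-consistent DEP intersection across platforms
#'
#' A protein is shared-up iff it is flagged as an upregulated DEP in the
#' same contrast on both platforms (analogously shared-down); proteins
#' flagged in both platforms but with conflicting directions are reported
#' separately. With `match = "any_contrast"` the two platforms may flag the
#' protein in different contrasts.
#'
#' @param tmt_deps,lfq_deps DEP tables from [call_deps()].
#' @param match `"same_contrast"` (default, strict) or `"any_contrast"`.
#' @return A list with `up`, `down` and `conflict` protein ID vectors.
#' @export
intersect_deps <- function(tmt_deps, lfq_deps,
                           match = c("same_contrast", "any_contrast")) {
  match <- match.arg(match)
  common <- intersect(unique(tmt_deps$contrast), unique(lfq_deps$contrast))
  if (length(common) == 0) abort("No common contrasts between the DEP tables.")
  key <- function(df) {
    df <- dplyr::filter(df, .data$is_dep, .data$contrast %in% common)
    if (match == "same_contrast") {
      dplyr::distinct(df, .data$protein_id, .data$contrast, .data$direction)
    } else {
      dplyr::distinct(df, .data$protein_id, .data$direction)
    }
  }
  a <- key(tmt_deps); b <- key(lfq_deps)
  hit <- dplyr::inner_join(a, b, by = setdiff(names(a), "direction"),
                           suffix = c("_tmt", "_lfq"), relationship = "many-to-many")
  agree <- dplyr::filter(hit, .data$direction_tmt == .data$direction_lfq)
  up <- sort(unique(agree$protein_id[agree$direction_tmt == "up"]))
  down <- sort(unique(agree$protein_id[agree$direction_tmt == "down"]))
  conflict <- sort(setdiff(unique(hit$protein_id), union(up, down)))
  # a protein both shared-up and shared-down (different contrasts) is a conflict
  both <- intersect(up, down)
  if (length(both)) {
    up <- setdiff(up, both); down <- setdiff(down, both)
    conflict <- sort(union(conflict, both))
  }
  list(up = up, down = down, conflict = conflict)
}
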