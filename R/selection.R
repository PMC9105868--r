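#' Pearson correlation coefficient between two series
#'
#' Direct evaluation of
#' `sum((x - mean(x)) * (y - mean(y))) / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))`.
#' Symmetric, in \[-1, 1\], invariant to positive affine transforms of
#' either argument. A zero-variance series is a degenerate input (a real
#' risk here: a fully saturated sensor is constant within a frame) and
#' raises an explicit error rather than returning NaN.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop_data("series lengths differ")
  if (length(x) < 2) stop_data("PCC needs at least 2 points")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    stop(errorCondition(
      "zero-variance series: PCC is undefined for a constant input",
      class = c("sensorprune_zero_variance", "sensorprune_data_error", "error")))
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  min(1, max(-1, r))
}

#' Cluster centroid series within a frame
#'
#' The pointwise mean pressure over the member sensors' columns.
#'
#' @param frame a `pressure_frame`.
#' @param members character vector of sensor labels, all present in the
#'   frame.
#' @return numeric vector of length `nrow(frame$data)`.
#' @export
cluster_centroid <- function(frame, members) {
  stopifnot(inherits(frame, "pressure_frame"))
  if (length(members) == 0) stop_data("empty member set")
  missing <- setdiff(members, frame$sensor_labels)
  if (length(missing)) stop_data("unknown sensor label: '", missing[1], "'")
  rowMeans(frame$data[, members, drop = FALSE])
}

#' Exact binomial coefficient
#'
#' @param m,k non-negative integers with `k <= m`.
#' @return `choose(m, k)` as an exact integer-valued numeric.
#' @export
n_combinations <- function(m, k) {
  if (k > m || k < 0 || m < 0) stop_config("need 0 <= k <= m")
  round(choose(m, k))
}

#' Choose the k sensors to keep in one cluster by exhaustive PCC scoring
#'
#' For every one of the `C(m, k)` k-subsets S of the cluster, the score is
#' the mean over frames of `pcc(centroid(frame, S), centroid(frame, cluster))`;
#' the chosen subset maximizes that mean (ties broken toward the
#' lexicographically smallest canonical subset). Scores are averaged over
#' per-frame PCCs, not computed on the concatenated series.
#'
#' If either centroid has zero variance within a frame (e.g. all member
#' sensors saturated for the whole frame), that subset's score excludes
#' that frame, with a warning; a subset excluded in every frame is marked
#' unscorable (`NA` score) and is never chosen.
#'
#' @param frames list of `pressure_frame`s.
#' @param cluster character vector of the cluster's sensor labels (size m).
#' @param k number of sensors to keep, `1 <= k <= m`. Chosen by the user
#'   (in the field, by the prosthetist); there is no automatic k.
#' @return a `selection_result`: list with `cluster`, `k`, `scored`
#'   (data.frame of subset and mean PCC score, one row per combination),
#'   `chosen` (character vector), `score` (its mean PCC),
#'   `n_combinations`.
#' @export
select_k <- function(frames, cluster, k) {
  cluster <- as.character(cluster)
  m <- length(cluster)
  if (k < 1 || k > m) stop_config("k must be between 1 and ", m)
  labels <- frames[[1]]$sensor_labels
  cluster <- cluster[order(match(cluster, labels))]
  subsets <- utils::combn(cluster, k, simplify = FALSE)

  full_centroids <- lapply(frames, cluster_centroid, members = cluster)
  n_excluded <- 0L
  scores <- vapply(subsets, function(s) {
    per_frame <- vapply(seq_along(frames), function(i) {
      tryCatch(
        pcc(cluster_centroid(frames[[i]], s), full_centroids[[i]]),
        sensorprune_zero_variance = function(e) NA_real_)
    }, numeric(1))
    n_excluded <<- n_excluded + sum(is.na(per_frame))
    if (all(is.na(per_frame))) NA_real_ else mean(per_frame, na.rm = TRUE)
  }, numeric(1))
  if (n_excluded > 0) {
    warning(n_excluded, " subset-frame score(s) excluded for zero variance",
            call. = FALSE)
  }
  if (all(is.na(scores))) stop_data("every subset is unscorable (zero variance)")

  subset_strings <- vapply(subsets, paste, character(1), collapse = ",")
  best <- max(scores, na.rm = TRUE)
  cand <- which(!is.na(scores) & scores == best)
  chosen_idx <- cand[order(subset_strings[cand])][1]

  structure(
    list(cluster = cluster, k = as.integer(k),
         scored = data.frame(subset = subset_strings, score = scores,
                             stringsAsFactors = FALSE),
         chosen = subsets[[chosen_idx]],
         score = scores[chosen_idx],
         n_combinations = n_combinations(m, k)),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> cluster {%s}, keep k=%d of m=%d (%d combinations)\n",
    paste(x$cluster, collapse = ","), x$k, length(x$cluster),
    x$n_combinations))
  cat(sprintf("  chosen: {%s}, mean PCC %.6f\n",
              paste(x$chosen, collapse = ","), x$score))
  invisible(x)
}
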