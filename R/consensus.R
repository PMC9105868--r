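#' Build the redundancy-detection model by consensus over frames
#'
#' Clusters every frame with the SOM and returns the modal partition (the
#' clustering result that appears most often across frames) together with
#' its support. Partitions are compared in canonical form, as sets of
#' sets. Ties between equally frequent partitions are broken toward fewer
#' clusters first (a coarser model detects more redundancy, which is the
#' method's purpose), then by lexicographically smallest canonical form;
#' a tie is flagged in the returned model.
#'
#' Per-frame SOM runs use `seed = cfg$seed + frame_index - 1` so frames
#' are independent yet reproducible.
#'
#' @param frames list of `pressure_frame`s over the same sensor set.
#' @param cfg a [som_config()].
#' @return a `consensus_model`: list with `partition` (the model),
#'   `support`, `n_frames`, `per_frame` (list of per-frame partitions),
#'   `tie` (logical), `crosscheck_support` (NULL until
#'   [crosscheck_kmeans()]).
#' @export
detect_redundancy <- function(frames, cfg = som_config()) {
  if (length(frames) < 1) stop_data("need at least one frame")
  labels <- frames[[1]]$sensor_labels
  ok <- vapply(frames, function(f) identical(f$sensor_labels, labels),
               logical(1))
  if (!all(ok)) stop_data("frames do not share one sensor set")

  per_frame <- lapply(seq_along(frames), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    som_cluster(frames[[i]], cfg_i)
  })

  vote <- modal_partition(per_frame)
  structure(
    list(partition = vote$partition,
         support = vote$support,
         n_frames = length(frames),
         per_frame = per_frame,
         tie = vote$tie,
         crosscheck_support = NULL),
    class = "consensus_model")
}

# Majority vote over canonical partitions. Ties: fewer clusters first,
# then lexicographically smallest canonical form; tie flagged.
modal_partition <- function(partitions) {
  keys <- vapply(partitions, partition_key, character(1))
  counts <- table(keys)
  top_keys <- names(counts)[counts == max(counts)]
  cand <- partitions[match(top_keys, keys)]
  ord <- order(lengths(cand), top_keys)
  list(partition = cand[[ord[1]]],
       support = as.integer(max(counts)),
       tie = length(top_keys) > 1)
}

#' Cross-check the consensus model with k-means
#'
#' Runs [kmeans_cluster()] on every frame with `K` equal to the model's
#' cluster count and counts the frames whose k-means partition equals the
#' SOM consensus partition. The model is returned augmented with
#' `crosscheck_support` and the per-frame k-means partitions; the
#' partition itself is unchanged.
#'
#' @param frames the same frames passed to [detect_redundancy()].
#' @param model a `consensus_model`.
#' @param iterations maximum Lloyd rounds per frame; default 10.
#' @param seed base seed; frame i uses `seed + i - 1`.
#' @return the augmented `consensus_model`.
#' @export
crosscheck_kmeans <- function(frames, model, iterations = 10, seed = 1L) {
  stopifnot(inherits(model, "consensus_model"))
  K <- length(model$partition)
  km <- lapply(seq_along(frames), function(i) {
    kmeans_cluster(frames[[i]], K = K, iterations = iterations,
                   seed = seed + i - 1L)
  })
  model$crosscheck_support <- sum(vapply(
    km, function(p) partition_equal(p, model$partition), logical(1)))
  model$kmeans_per_frame <- km
  model
}

#' @export
print.consensus_model <- function(x, ...) {
  cat("<consensus_model> support", x$support, "/", x$n_frames, "frames\n")
  print(x$partition)
  if (!is.null(x$crosscheck_support)) {
    cat("  k-means crosscheck:", x$crosscheck_support, "/", x$n_frames,
        "frames agree\n")
  }
  if (isTRUE(x$tie)) cat("  note: modal partition was tied\n")
  invisible(x)
}

#' Compare consensus stability across frame lengths
#'
#' Reruns [detect_redundancy()] at each frame length and reports the
#' modal partition and its support, for judging which frame length gives
#' the more stable model. This is a report, not an automatic chooser.
#'
#' @param rec a [sensor_recording()].
#' @param frame_lengths integer vector of frame lengths in samples.
#' @param cfg a [som_config()].
#' @return data.frame with one row per frame length: `frame_length`,
#'   `n_frames`, `support`, `n_clusters`, `partition` (canonical string).
#' @export
frame_length_report <- function(rec, frame_lengths = c(500, 250),
                                cfg = som_config()) {
  rows <- lapply(frame_lengths, function(L) {
    m <- detect_redundancy(slice_frames(rec, L), cfg)
    data.frame(frame_length = L, n_frames = m$n_frames,
               support = m$support, n_clusters = length(m$partition),
               partition = partition_key(m$partition),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
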