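#' Canonical sensor partition
#'
#' A partition is a set of disjoint non-empty clusters of sensor labels
#' whose union is the full sensor set. The canonical form orders members
#' within each cluster by their position in `labels` (the strip order) and
#' orders clusters by their first (smallest-position) member, so two
#' partitions are equal as sets of sets iff their canonical forms are
#' identical.
#'
#' @param clusters list of character vectors of sensor labels.
#' @param labels the full ordered sensor label set of the recording.
#' @return an object of class `sensor_partition`: the canonical list of
#'   clusters, with attribute `labels`.
#' @export
sensor_partition <- function(clusters, labels) {
  clusters <- lapply(clusters, as.character)
  if (any(lengths(clusters) == 0)) stop_data("empty cluster in partition")
  members <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop_data("partition clusters are not disjoint: '",
              members[duplicated(members)][1], "' appears twice")
  }
  if (!setequal(members, labels)) {
    stop_data("partition does not cover the sensor set exactly")
  }
  clusters <- lapply(clusters, function(cl) cl[order(match(cl, labels))])
  first <- vapply(clusters, function(cl) match(cl[1], labels), integer(1))
  clusters <- clusters[order(first)]
  structure(clusters, labels = labels, class = "sensor_partition")
}

#' @export
print.sensor_partition <- function(x, ...) {
  cat("<sensor_partition>",
      paste(vapply(x, function(cl) paste0("{", paste(cl, collapse = ","), "}"),
                   character(1)), collapse = " "), "\n")
  invisible(x)
}

#' Test two partitions for equality (set-of-sets semantics)
#'
#' @param a,b `sensor_partition` objects over the same label set.
#' @return logical scalar.
#' @export
partition_equal <- function(a, b) {
  identical(partition_key(a), partition_key(b))
}

# Serialized canonical form; used for equality, voting and tie-breaking.
partition_key <- function(p) {
  paste(vapply(p, function(cl) paste(cl, collapse = ","), character(1)),
        collapse = "|")
}

# Build a partition from an assignment vector (cluster id per label).
partition_from_assignment <- function(assignment, labels) {
  sensor_partition(split(labels, assignment), labels)
}
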