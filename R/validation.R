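#' Pooled pressure histogram over a whole recording
#'
#' All readings of all member sensors over the entire recording are pooled
#' into one sample and binned into `n_bins` equal-width bins spanning the
#' recording's reading range (not the data min/max, so any two histograms
#' from the same recording share support). The last bin is closed:
#' saturation values at the range ceiling fall in the final bin. Counts
#' are normalized to probabilities.
#'
#' @param rec a [sensor_recording()] (clean it first; values outside the
#'   reading range are clamped into it here as well).
#' @param members non-empty character vector of sensor labels.
#' @param n_bins number of bins; default 64 (one per kPa over 0--64).
#' @return a `pressure_histogram`: list with `bin_edges` (length
#'   `n_bins + 1`) and `probabilities` (length `n_bins`, summing to 1).
#' @export
pooled_histogram <- function(rec, members, n_bins = 64) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (length(members) == 0) stop_data("empty member set")
  missing <- setdiff(members, rec$sensor_labels)
  if (length(missing)) stop_data("unknown sensor label: '", missing[1], "'")
  if (n_bins < 1) stop_config("n_bins must be >= 1")
  lo <- rec$reading_range[1]
  hi <- rec$reading_range[2]
  v <- as.vector(rec$readings[, members, drop = FALSE])
  v <- pmin(pmax(v, lo), hi)
  width <- (hi - lo) / n_bins
  idx <- pmin(floor((v - lo) / width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(bin_edges = lo + width * (0:n_bins),
         probabilities = counts / length(v)),
    class = "pressure_histogram")
}

#' Jensen--Shannon divergence between two histograms
#'
#' `JSD(P, Q) = KL(P || M)/2 + KL(Q || M)/2` with `M = (P + Q)/2` and
#' Kullback--Leibler divergence `KL(P || Q) = sum(p * log2(p / q))`.
#' Logarithms are base 2, which is what bounds the value in \[0, 1\]
#' (natural logs would cap it at ln 2). Terms with `p(x) = 0` contribute
#' zero (`0 * log 0 := 0`). Symmetric; zero iff `P = Q`.
#'
#' @param p,q `pressure_histogram`s with identical bin edges.
#' @return divergence in \[0, 1\].
#' @export
jsd <- function(p, q) {
  stopifnot(inherits(p, "pressure_histogram"),
            inherits(q, "pressure_histogram"))
  if (length(p$bin_edges) != length(q$bin_edges) ||
      !isTRUE(all.equal(p$bin_edges, q$bin_edges, tolerance = 0))) {
    stop_data("histograms have different bin edges")
  }
  pp <- p$probabilities
  qq <- q$probabilities
  m <- (pp + qq) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  d <- kl(pp, m) / 2 + kl(qq, m) / 2
  min(1, max(0, d))
}

#' Validate a pruned sensor layout against the original
#'
#' Posterior check, per cluster of the redundancy-detection model, on the
#' whole concatenated recording (not per frame):
#' * `jsd_chosen` -- JSD between the pooled pressure histogram of the full
#'   cluster (P, the initial layout) and of the chosen subset (Q);
#' * an exhaustive search over all `C(m, k)` subsets gives
#'   `best_subset_by_jsd` and `jsd_min`, the minimum attainable JSD;
#' * `mean_all` / `mean_chosen` -- arithmetic mean of the pooled readings,
#'   in kPa, and `variation_pct = 100 * |mean_chosen - mean_all| / mean_all`.
#'
#' The report prints the JSD gap and leaves the keep-or-add-sensors
#' judgment to the user.
#'
#' @param rec the (cleaned) full [sensor_recording()].
#' @param model a `consensus_model` whose clusters the selections cover.
#' @param selections list of `selection_result`s, one per cluster of the
#'   model.
#' @param n_bins histogram bins; default 64.
#' @return a `validation_report`: data.frame with one row per cluster:
#'   `cluster`, `k`, `chosen`, `jsd_chosen`, `best_subset_by_jsd`,
#'   `jsd_min`, `mean_all`, `mean_chosen`, `variation_pct`.
#' @export
validate_selection <- function(rec, model, selections, n_bins = 64) {
  stopifnot(inherits(rec, "sensor_recording"),
            inherits(model, "consensus_model"))
  rows <- lapply(selections, function(sel) {
    stopifnot(inherits(sel, "selection_result"))
    in_model <- any(vapply(model$partition,
                           function(cl) setequal(cl, sel$cluster),
                           logical(1)))
    if (!in_model) {
      stop_data("selection cluster {", paste(sel$cluster, collapse = ","),
                "} is not a cluster of the model")
    }
    if (!all(sel$chosen %in% sel$cluster)) {
      stop_data("chosen subset is not within its cluster")
    }
    hp <- pooled_histogram(rec, sel$cluster, n_bins)
    jsd_chosen <- jsd(hp, pooled_histogram(rec, sel$chosen, n_bins))

    subsets <- utils::combn(sel$cluster, sel$k, simplify = FALSE)
    jsds <- vapply(subsets, function(s)
      jsd(hp, pooled_histogram(rec, s, n_bins)), numeric(1))
    best <- which.min(jsds)

    mean_all <- mean(rec$readings[, sel$cluster])
    mean_chosen <- mean(rec$readings[, sel$chosen])
    data.frame(
      cluster = paste(sel$cluster, collapse = ","),
      k = sel$k,
      chosen = paste(sel$chosen, collapse = ","),
      jsd_chosen = jsd_chosen,
      best_subset_by_jsd = paste(subsets[[best]], collapse = ","),
      jsd_min = min(jsds),
      mean_all = mean_all,
      mean_chosen = mean_chosen,
      variation_pct = 100 * abs(mean_chosen - mean_all) / mean_all,
      stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  class(report) <- c("validation_report", class(report))
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  NextMethod()
  invisible(x)
}
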