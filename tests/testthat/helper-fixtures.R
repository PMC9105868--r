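# Shared fixtures and independent oracles for the suite.

# tiny recording with known values; 4 samples x 3 sensors
tiny_recording <- function(range = c(0, 64)) {
  sensor_recording(
    matrix(c(1, 2, 3,
             2, 4, 6,
             3, 6, 9,
             4, 8, 12), nrow = 4, byrow = TRUE),
    sensor_labels = c("s1", "s2", "s3"),
    sampling_rate = 100, reading_range = range)
}

# noise-free recording with two exactly-correlated groups and
# well-separated waveforms; gains all 1 so within-group series are identical
noiseless_two_groups <- function(seed = 1L, n_sensors = 10) {
  groups <- c("a", "a", "b", "b", "b", "a", "b", "b", "b", "b")[seq_len(n_sensors)]
  cfg <- gait_sim_config(
    group_assignment = groups,
    sensor_labels = as.character(seq_len(n_sensors)),
    base_amplitude = c(a = 30, b = 50),
    baseline = c(a = 4, b = 8),
    phase = c(a = 0, b = 0.45),
    gain = 1, noise_sd = 0, seed = seed)
  simulate_recording(cfg)
}

ground_truth_partition <- function(rec) {
  sensor_partition(list(c("1", "2", "6"), c("3", "4", "5", "7", "8", "9", "10")),
                   rec$sensor_labels)
}

# --- independent oracles -------------------------------------------------

# JSD via the entropy form: H(M) - (H(P) + H(Q))/2, base-2 entropies.
# Algebraically equal to the KL form but a distinct computation path.
oracle_jsd <- function(p, q) {
  h <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  m <- (p + q) / 2
  h(m) - (h(p) + h(q)) / 2
}

# within-cluster sum of squares of a 2-partition of frame columns
wss <- function(frame, part) {
  sum(vapply(part, function(cl) {
    x <- frame$data[, cl, drop = FALSE]
    sum((x - rowMeans(x))^2)
  }, numeric(1)))
}

# all 2^(p-1)-1 two-partitions of the frame's sensors
all_two_partitions <- function(labels) {
  p <- length(labels)
  out <- list()
  for (mask in 1:(2^(p - 1) - 1)) {
    inA <- as.logical(bitwAnd(mask, 2^(seq_len(p) - 1)))
    out[[length(out) + 1]] <- list(labels[inA], labels[!inA])
  }
  out
}

# random normalized histogram pair sharing support size
random_histogram <- function(n_bins, edges = seq(0, 64, length.out = n_bins + 1)) {
  v <- stats::runif(n_bins)
  structure(list(bin_edges = edges, probabilities = v / sum(v)),
            class = "pressure_histogram")
}

# independent exhaustive PCC selection using stats::cor
oracle_select <- function(frames, cluster, k) {
  subsets <- utils::combn(sort(cluster), k, simplify = FALSE)
  scores <- vapply(subsets, function(s) {
    mean(vapply(frames, function(f) {
      stats::cor(rowMeans(f$data[, s, drop = FALSE]),
                 rowMeans(f$data[, cluster, drop = FALSE]))
    }, numeric(1)))
  }, numeric(1))
  subsets[[which.max(scores)]]
}
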