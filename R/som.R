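#' Self-organizing map configuration
#'
#' The SOM is a two-layer competitive network: the input layer carries one
#' neuron per time sample of the frame, and the output (competitive) layer
#' is a rectangular grid of `grid_rows * grid_cols` neurons. Each output
#' neuron can end up the best matching unit (BMU) of zero or more sensors;
#' sensors sharing a BMU form one cluster, so the grid size is an upper
#' bound on the number of clusters, not a target.
#'
#' @param grid_rows,grid_cols output grid dimensions (default 3 x 3, an
#'   upper bound of 9 clusters for a 10-sensor strip).
#' @param eta0 initial learning rate, in (0, 1]; default 0.2.
#' @param sigma0 initial neighborhood width in grid-distance units;
#'   default 0.5 (half the grid spacing). In this method a cluster is the
#'   set of sensors sharing a BMU, so the neighborhood must stay narrow
#'   enough that only one neuron converges into each redundancy group's
#'   interior; empirically sigma0 >= 1 pulls neighboring neurons inside a
#'   group's spread and fragments it, while any sigma0 <= 0.8 keeps one
#'   winning neuron per group (see the methods vignette).
#' @param tau total number of iterations (epochs over all inputs);
#'   default 10.
#' @param seed integer seed for weight initialization (and presentation
#'   shuffling, if enabled).
#' @param presentation_order `"fixed"` (input column order, reproducible,
#'   the default) or `"shuffled"` (re-shuffled each epoch).
#' @return a list of class `som_config`.
#' @export
som_config <- function(grid_rows = 3, grid_cols = 3, eta0 = 0.2,
                       sigma0 = 0.5,
                       tau = 10, seed = 1L,
                       presentation_order = c("fixed", "shuffled")) {
  presentation_order <- match.arg(presentation_order)
  if (grid_rows < 1 || grid_cols < 1) stop_config("grid must be at least 1x1")
  if (!(eta0 > 0 && eta0 <= 1)) stop_config("eta0 must be in (0, 1]")
  if (sigma0 <= 0) stop_config("sigma0 must be positive")
  if (tau < 1) stop_config("tau must be >= 1")
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         eta0 = eta0, sigma0 = sigma0, tau = as.integer(tau),
         seed = as.integer(seed), presentation_order = presentation_order),
    class = "som_config")
}

# Grid coordinates (row, col) for neurons 1..k, row-major.
som_grid_coords <- function(cfg) {
  k <- cfg$grid_rows * cfg$grid_cols
  cbind(row = (seq_len(k) - 1L) %/% cfg$grid_cols + 1L,
        col = (seq_len(k) - 1L) %% cfg$grid_cols + 1L)
}

# BMU of input vector x among weight columns w (n x k): minimal Euclidean
# distance, ties broken by lowest neuron index (which.min does both).
som_bmu <- function(x, w) {
  which.min(colSums((w - x)^2))
}

#' Cluster the sensors of one frame with a self-organizing map
#'
#' Each sensor's pressure series within the frame (one column, length n)
#' is one input vector; input vectors are the raw kPa series, not
#' standardized, since all sensors share one physical unit and range.
#'
#' Training: weights are initialized uniformly at random within each input
#' dimension's observed min--max (seeded from `cfg$seed`). For each epoch
#' t = 0, ..., tau-1, every input vector x is presented in turn; its BMU is
#' the neuron with minimal Euclidean distance (ties to the lowest neuron
#' index), and every neuron j is updated by
#' `delta_w = eta(t) * T(j, BMU, t) * (x - w_j)` with Gaussian neighborhood
#' `T = exp(-D^2 / (2 sigma(t)^2))` over the Euclidean grid distance D, and
#' exponential decays `sigma(t) = sigma0 exp(-t/tau)`,
#' `eta(t) = eta0 exp(-t/tau)`. One iteration is one full epoch; t advances
#' per epoch. After tau epochs each sensor is assigned to its final BMU and
#' sensors sharing a BMU form a cluster; empty neurons are simply absent.
#'
#' @param frame a `pressure_frame` (from [slice_frames()]).
#' @param cfg a [som_config()].
#' @return a [sensor_partition()] in canonical form.
#' @export
som_cluster <- function(frame, cfg = som_config()) {
  stopifnot(inherits(frame, "pressure_frame"), inherits(cfg, "som_config"))
  x <- frame$data                         # n samples x p sensors
  if (ncol(x) < 1) stop_data("frame has no sensors")
  if (nrow(x) < 1) stop_data("frame has no samples")
  if (!all(is.finite(x))) stop_data("non-finite data in frame")
  n <- nrow(x)
  p <- ncol(x)
  k <- cfg$grid_rows * cfg$grid_cols
  coords <- som_grid_coords(cfg)
  # squared Euclidean grid distance between every pair of neurons
  d2 <- as.matrix(stats::dist(coords))^2

  lo <- apply(x, 1, min)
  hi <- apply(x, 1, max)
  w <- with_seed(cfg$seed, {
    w0 <- matrix(stats::runif(n * k, min = lo, max = hi), nrow = n, ncol = k)
    orders <- if (cfg$presentation_order == "shuffled") {
      lapply(seq_len(cfg$tau), function(i) sample.int(p))
    } else {
      rep(list(seq_len(p)), cfg$tau)
    }
    attr(w0, "orders") <- orders
    w0
  })
  orders <- attr(w, "orders")
  attr(w, "orders") <- NULL

  for (t in seq_len(cfg$tau) - 1L) {
    sigma_t <- cfg$sigma0 * exp(-t / cfg$tau)
    eta_t <- cfg$eta0 * exp(-t / cfg$tau)
    for (s in orders[[t + 1L]]) {
      bmu <- som_bmu(x[, s], w)
      tj <- exp(-d2[, bmu] / (2 * sigma_t^2))
      # rank-one update of all neurons toward the input
      w <- w + (x[, s] - w) * matrix(eta_t * tj, nrow = n, ncol = k,
                                     byrow = TRUE)
    }
  }

  assignment <- vapply(seq_len(p), function(s) som_bmu(x[, s], w), integer(1))
  partition_from_assignment(assignment, frame$sensor_labels)
}

#' Cluster the sensors of one frame with k-means (Lloyd's algorithm)
#'
#' Cross-validation counterpart of [som_cluster()]: minimizes the
#' within-cluster sum of squared Euclidean distances of the sensor series
#' to their centroids. Centroids are initialized as `K` distinct sensor
#' vectors chosen uniformly at random (seeded); the algorithm runs
#' `iterations` assignment/update rounds or to convergence, whichever
#' comes first. Clusters left empty by an assignment round are dropped
#' from the returned partition.
#'
#' @param frame a `pressure_frame`.
#' @param K number of centroids, `1 <= K <=` number of sensors.
#' @param iterations maximum Lloyd rounds; default 10.
#' @param seed integer seed for centroid initialization.
#' @return a [sensor_partition()].
#' @export
kmeans_cluster <- function(frame, K, iterations = 10, seed = 1L) {
  stopifnot(inherits(frame, "pressure_frame"))
  x <- frame$data
  p <- ncol(x)
  if (K < 1 || K > p) stop_config("K must be between 1 and ", p)
  centroids <- with_seed(seed, x[, sample.int(p, K), drop = FALSE])
  assignment <- rep(NA_integer_, p)
  for (it in seq_len(iterations)) {
    d2 <- vapply(seq_len(K),
                 function(j) colSums((x - centroids[, j])^2),
                 numeric(p))
    d2 <- matrix(d2, nrow = p)
    new_assignment <- max.col(-d2, ties.method = "first")
    if (identical(new_assignment, assignment)) break
    assignment <- new_assignment
    for (j in unique(assignment)) {
      centroids[, j] <- rowMeans(x[, assignment == j, drop = FALSE])
    }
  }
  partition_from_assignment(assignment, frame$sensor_labels)
}
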