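test_that("pooled_histogram bins over the reading range with closed last bin", {
  # all readings at the ceiling -> all mass in the final bin
  rec <- sensor_recording(matrix(64, 10, 2), c("a", "b"))
  h <- pooled_histogram(rec, c("a", "b"), 64)
  expect_length(h$bin_edges, 65)
  expect_length(h$probabilities, 64)
  expect_equal(h$probabilities[64], 1)
  expect_equal(sum(h$probabilities), 1, tolerance = 1e-9)

  # equal counts at the centers of bins 1 and 2 -> [0.5, 0.5, 0, ...]
  rec2 <- sensor_recording(matrix(c(0.5, 1.5, 0.5, 1.5), 4, 1), "a")
  h2 <- pooled_histogram(rec2, "a", 64)
  expect_equal(h2$probabilities[1:2], c(0.5, 0.5))
  expect_equal(sum(h2$probabilities[-(1:2)]), 0)

  # pooling identical sensors gives the same histogram as one of them
  rec3 <- sensor_recording(matrix(rep(runif(50, 0, 64), 3), ncol = 3),
                           c("a", "b", "c"))
  expect_equal(pooled_histogram(rec3, c("a", "b", "c"))$probabilities,
               pooled_histogram(rec3, "a")$probabilities)

  expect_error(pooled_histogram(rec, character(0)), "empty")
  expect_error(pooled_histogram(rec, "zz"), "unknown")
})

test_that("jsd matches hand-derived values and the entropy-form oracle", {
  mk <- function(p) structure(list(bin_edges = seq(0, 64, length.out = length(p) + 1),
                                   probabilities = p),
                              class = "pressure_histogram")
  expect_equal(jsd(mk(c(0.5, 0.5)), mk(c(0.5, 0.5))), 0)
  expect_equal(jsd(mk(c(1, 0)), mk(c(0, 1))), 1)
  # derived by hand from the KL form with base-2 logs
  expect_equal(jsd(mk(c(0.5, 0.5)), mk(c(0.25, 0.75))), 0.04879494,
               tolerance = 1e-7)

  # property suite: symmetry, bounds, oracle agreement over random pairs
  set.seed(11)
  for (i in 1:1000) {
    nb <- sample(c(8, 64), 1)
    p <- random_histogram(nb)
    q <- random_histogram(nb)
    d <- jsd(p, q)
    expect_identical(d, jsd(q, p))
    expect_true(d >= 0 && d <= 1)
    expect_equal(d, oracle_jsd(p$probabilities, q$probabilities),
                 tolerance = 1e-12)
  }
  expect_error(jsd(mk(c(0.5, 0.5)), mk(c(0.25, 0.25, 0.25, 0.25))),
               "bin edges")
})

test_that("validate_selection reports per-cluster JSD and mean deviation", {
  rec <- clean_recording(demo_recording(seed = 5))
  frames <- slice_frames(rec, 500)
  m <- detect_redundancy(frames, som_config(seed = 5))
  sels <- lapply(m$partition, function(cl) select_k(frames, cl, min(2, length(cl))))
  rep <- validate_selection(rec, m, sels)

  expect_equal(nrow(rep), length(m$partition))
  expect_true(all(rep$jsd_chosen >= 0 & rep$jsd_chosen <= 1))
  expect_true(all(rep$jsd_min <= rep$jsd_chosen + 1e-15))
  expect_true(all(rep$variation_pct >= 0))

  # exhaustive-min consistency against a brute-force loop coded here
  for (i in seq_along(sels)) {
    cl <- sels[[i]]$cluster
    hp <- pooled_histogram(rec, cl)
    brute <- vapply(utils::combn(cl, sels[[i]]$k, simplify = FALSE),
                    function(s) jsd(hp, pooled_histogram(rec, s)), numeric(1))
    expect_equal(rep$jsd_min[i], min(brute))
  }
})

test_that("choosing the whole cluster gives zero JSD and zero deviation", {
  rec <- clean_recording(demo_recording(seed = 6))
  frames <- slice_frames(rec, 500)
  m <- detect_redundancy(frames, som_config(seed = 6))
  cl <- m$partition[[1]]
  sel <- select_k(frames, cl, length(cl))
  rep <- validate_selection(rec, m, list(sel))
  expect_equal(rep$jsd_chosen[1], 0)
  expect_equal(rep$variation_pct[1], 0)
})

test_that("identical-sensor cluster yields zero JSD for any subset", {
  series <- runif(600, 0, 60)
  rec <- sensor_recording(matrix(rep(series, 3), ncol = 3), c("a", "b", "c"))
  frames <- slice_frames(rec, 200)
  model <- structure(list(partition = sensor_partition(list(c("a", "b", "c")),
                                                       rec$sensor_labels)),
                     class = "consensus_model")
  sel <- select_k(frames, c("a", "b", "c"), 1)
  rep <- validate_selection(rec, model, list(sel))
  expect_equal(rep$jsd_chosen[1], 0)
})

test_that("validate_selection rejects mismatched selections", {
  rec <- clean_recording(demo_recording(seed = 7))
  frames <- slice_frames(rec, 500)
  m <- detect_redundancy(frames, som_config(seed = 7))
  sel <- select_k(frames, m$partition[[1]], 1)
  sel$cluster <- c("1", "2")       # not a model cluster
  expect_error(validate_selection(rec, m, list(sel)), "not a cluster")

  sel2 <- select_k(frames, m$partition[[1]], 1)
  sel2$chosen <- "99"
  expect_error(validate_selection(rec, m, list(sel2)), "within its cluster")
})
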