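Package: sensorprune
Title: Redundancy Reduction for Wearable Pressure Sensor Deployments
Version: 0.1.0
Authors@R:
    person("Sensorprune", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects groups of mutually redundant pressure sensors in
    multi-sensor recordings (e.g. capacitive strips inside a prosthetic
    socket during gait), proposes a minimal sensor subset per group, and
    validates the pruned layout against the original. Recordings are
    sliced into fixed-length frames; each frame is clustered with a
    self-organizing map (cross-validated with k-means); the modal
    partition across frames is the redundancy-detection model; within
    each cluster the kept subset is chosen by exhaustive Pearson
    correlation against the cluster centroid; the pruned layout is
    validated by Jensen-Shannon divergence between pooled pressure
    histograms and by mean-pressure deviation. Includes a seeded
    gait-like synthetic-data generator with known group structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
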