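Package: groomensembles
Title: Striatal Ensemble Analysis of Spontaneous Grooming Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for analyzing striatal population
    activity during mouse self-grooming. Detects grooming bouts from 3D
    keypoint tracks with postural heuristics, classifies sorted units into
    putative spiny projection neurons and fast-spiking interneurons from
    waveform features and firing rate, characterizes transition-aligned
    responses with event-triggered averages and PCA response typing,
    detects co-active ensembles with a shuffle-eigenvalue count estimate
    and meta-k-means consensus clustering, quantifies ensemble encoding of
    bout structure with time-warped activity and duration-matched bootstrap
    null bands, and extracts low-dimensional grooming trajectories with
    rank-3 non-negative matrix factorization. Includes a synthetic-session
    generator with planted ground truth (spike trains, bout schedules, 3D
    pose) so every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
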