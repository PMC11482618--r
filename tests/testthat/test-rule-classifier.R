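test_that("p-cutoff conditioning keeps the boundary and drops below it", {
  tr <- keypoint_track(x = matrix(c(1, 2, 3)), y = matrix(c(4, 5, 6)),
                       likelihood = matrix(c(0.4, 0.5, 1.0)),
                       bodyparts = "head", fps = 25)
  out <- apply_pcutoff(tr, 0.5)
  expect_true(is.na(out$x[1, 1]))            # 0.4 < 0.5: invalid
  expect_equal(unname(out$x[2, 1]), 2)       # exactly 0.5: retained
  expect_equal(unname(out$x[3, 1]), 3)
  # all likelihoods 1.0: identity
  tr2 <- keypoint_track(matrix(1:4), matrix(1:4), matrix(rep(1, 4)),
                        "head", 25)
  expect_equal(apply_pcutoff(tr2, 0.5), tr2)
})

test_that("per-frame classification follows zone, default and out-of-view semantics", {
  cfg <- tiny_config()
  # nose inside the Eat box, anchor valid -> zone behavior
  expect_identical(
    classify_frame(c(head = 150, nose = 50), c(head = 150, nose = 50),
                   c(head = 0.9, nose = 0.9), cfg), "Eat")
  # nose nowhere special, anchor valid -> default
  expect_identical(
    classify_frame(c(head = 150, nose = 150), c(head = 150, nose = 150),
                   c(head = 0.9, nose = 0.9), cfg), "Stand")
  # all keypoints invalid -> out of view
  expect_identical(
    classify_frame(c(head = NA, nose = NA), c(head = NA, nose = NA),
                   c(head = NA, nose = NA), cfg), OUT_OF_VIEW)
  # nose in zone but below cutoff, anchor valid -> default
  expect_identical(
    classify_frame(c(head = 150, nose = 50), c(head = 150, nose = 50),
                   c(head = 0.9, nose = 0.2), cfg), "Stand")
  # anchor invalid but zone bodypart valid: anchors define in-view,
  # the matching rule still wins
  expect_identical(
    classify_frame(c(head = NA, nose = 50), c(head = NA, nose = 50),
                   c(head = NA, nose = 0.9), cfg), "Eat")
})

test_that("overlapping zone matches resolve by lowest priority number", {
  overlapping <- list(
    zone_rule("Eat", 2, data.frame(bodypart = "nose", x_min = 0, x_max = 100,
                                   y_min = 0, y_max = 100)),
    zone_rule("Drink", 1, data.frame(bodypart = "nose", x_min = 0, x_max = 100,
                                     y_min = 0, y_max = 100)))
  cfg <- tiny_config(zone_rules = overlapping)
  expect_identical(
    classify_frame(c(head = 150, nose = 50), c(head = 150, nose = 50),
                   c(head = 0.9, nose = 0.9), cfg), "Drink")
})

test_that("classify_track matches the brute-force per-frame oracle", {
  set.seed(123)
  cfg <- tiny_config()
  tr <- random_track(1000, cfg$bodyparts, fps = cfg$fps, na_frac = 0.15)
  got <- classify_track(tr, cfg)$labels
  want <- vapply(seq_len(1000), function(i)
    oracle_classify_frame(tr, i, cfg), "")
  expect_identical(got, want)
  expect_equal(length(got), n_frames(tr))
})

test_that("empty track classifies to an empty sequence", {
  cfg <- tiny_config()
  m <- matrix(numeric(0), 0, 2)
  tr <- keypoint_track(m, m, m, cfg$bodyparts, cfg$fps)
  expect_equal(length(classify_track(tr, cfg)$labels), 0L)
})

test_that("out-of-view count never decreases as the p-cutoff rises", {
  set.seed(5)
  cfg <- tiny_config()
  tr <- random_track(400, cfg$bodyparts, fps = cfg$fps, na_frac = 0.1)
  oov <- vapply(seq(0, 1, by = 0.1), function(pc)
    sum(classify_track(tr, cfg, p_cutoff = pc)$labels == OUT_OF_VIEW),
    numeric(1))
  expect_true(all(diff(oov) >= 0))
})

test_that("classified labels stay inside the config label set", {
  set.seed(6)
  cfg <- tiny_config()
  for (rep in 1:5) {
    tr <- random_track(200, cfg$bodyparts, fps = cfg$fps,
                       na_frac = runif(1, 0, 0.5))
    expect_true(all(classify_track(tr, cfg)$labels %in% label_set(cfg)))
  }
})

test_that("detection streams convert with confidence thresholding", {
  labels <- c("Stand", "Eat")
  st <- detection_stream(c("Stand", "Eat", NA, "Stand"),
                         c(1.0, 0.6, NA, 0.4), labels, fps = 5)
  out <- detections_to_sequence(st, 0.5)
  expect_identical(out$labels, c("Stand", "Eat", OUT_OF_VIEW, OUT_OF_VIEW))
  # threshold 1.0 on sub-unit confidences: everything out of view
  st2 <- detection_stream(c("Stand", "Eat"), c(0.9, 0.99), labels, fps = 5)
  expect_identical(unique(detections_to_sequence(st2, 1.0)$labels),
                   OUT_OF_VIEW)
})

test_that("identity confusion and no misses make the detection path lossless", {
  cfg <- tiny_config()
  script <- random_script(cfg, 13, c(Stand = 30, Eat = 20, Drink = 10), 240)
  det <- simulate_detections(script, cfg, noise_model(), seed = 13)
  out <- aggregate_to_seconds(detections_to_sequence(det, 0.5), cfg)
  expect_identical(out$labels, rasterize_script(script, cfg)$labels)
})

test_that("second aggregation takes the majority and breaks ties by priority", {
  cfg <- default_ethogram_config()   # fps 25
  mk <- function(labels) behavior_sequence(labels, "frame", 25)
  expect_identical(
    aggregate_to_seconds(mk(rep("Foraging", 25)), cfg)$labels, "Foraging")
  expect_identical(
    aggregate_to_seconds(mk(c(rep("Standing", 13), rep("Foraging", 12))),
                         cfg)$labels, "Standing")
  # 12 + 12 + 1 tie: zone priority beats the default, OUT_OF_VIEW loses
  expect_identical(
    aggregate_to_seconds(mk(c(rep("Foraging", 12), rep("Standing", 12),
                              OUT_OF_VIEW)), cfg)$labels, "Foraging")
  expect_identical(
    aggregate_to_seconds(mk(c(rep(OUT_OF_VIEW, 13), rep("Drinking", 12))),
                         cfg)$labels, OUT_OF_VIEW)
  # enumeration oracle over two-way splits of one second: majority wins,
  # the 12/13 boundary falling to the higher-count label
  for (k in c(0, 5, 12, 13, 20, 25)) {
    got <- aggregate_to_seconds(mk(c(rep("Foraging", k),
                                     rep("Standing", 25 - k))), cfg)$labels
    expect_identical(got, if (k >= 13) "Foraging" else
      if (k >= 1 && k >= 25 - k) "Foraging" else "Standing")
  }
})

test_that("trailing partial seconds are voted over their available frames", {
  cfg <- tiny_config()  # fps 5
  seq <- behavior_sequence(c(rep("Stand", 5), "Eat", "Eat"), "frame", 5)
  out <- aggregate_to_seconds(seq, cfg)
  expect_identical(out$labels, c("Stand", "Eat"))
})

test_that("minimum-duration enforcement relabels short stereotypy runs", {
  cfg <- default_ethogram_config()  # Swaying: min 5 s
  mk <- function(labels) behavior_sequence(labels, "second", 25)
  s4 <- mk(c(rep("Standing", 3), rep("Swaying", 4), rep("Foraging", 3)))
  expect_identical(enforce_min_duration(s4, cfg)$labels,
                   c(rep("Standing", 3), rep("Standing", 4),
                     rep("Foraging", 3)))
  s6 <- mk(c(rep("Standing", 3), rep("Swaying", 6), rep("Standing", 3)))
  expect_identical(enforce_min_duration(s6, cfg), s6)
  # sequences without constrained behaviors are untouched
  s0 <- mk(rep(c("Foraging", "Standing"), 10))
  expect_identical(enforce_min_duration(s0, cfg), s0)
  # boundary: exactly 5 s is kept
  s5 <- mk(c("Standing", rep("Swaying", 5), "Standing"))
  expect_identical(enforce_min_duration(s5, cfg), s5)
})
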