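#' Noise model for the synthetic night
#'
#' Describes the failure modes of the two automated coding routes: Gaussian
#' pixel jitter on keypoints, label dropout (the network not labeling a
#' bodypart at all), low-likelihood draws (labeled but below the p-cutoff),
#' detector misses, and detector label confusion.
#'
#' @param coord_sd Gaussian jitter SD in pixels added to every present
#'   keypoint estimate.
#' @param dropout_p Probability that a (frame, bodypart) sample is missing.
#' @param low_conf_p Probability that a present sample's likelihood is drawn
#'   below the p-cutoff (uniform on \[0, p_cutoff)); otherwise uniform on
#'   \[p_cutoff, 1\].
#' @param det_miss_p Probability that a frame is unlabeled in the detection
#'   stream.
#' @param det_confuse Row-stochastic label-confusion matrix (rows = true
#'   behavior, columns = emitted label), dimnames = behavior names; `NULL`
#'   for the identity (no confusion).
#' @return A `noise_model` list.
#' @export
noise_model <- function(coord_sd = 0, dropout_p = 0, low_conf_p = 0,
                        det_miss_p = 0, det_confuse = NULL) {
  pr <- c(dropout_p = dropout_p, low_conf_p = low_conf_p,
          det_miss_p = det_miss_p)
  if (any(pr < 0 | pr > 1))
    stop("noise probabilities must lie in [0, 1]: ",
         paste(names(pr)[pr < 0 | pr > 1], collapse = ", "))
  if (coord_sd < 0) stop("coord_sd must be >= 0")
  if (!is.null(det_confuse)) {
    det_confuse <- as.matrix(det_confuse)
    if (nrow(det_confuse) != ncol(det_confuse) ||
        is.null(rownames(det_confuse)) ||
        !identical(rownames(det_confuse), colnames(det_confuse)))
      stop("det_confuse must be square with matching row/column behavior names")
    if (any(det_confuse < 0) || any(abs(rowSums(det_confuse) - 1) > 1e-8))
      stop("det_confuse rows must be nonnegative and sum to 1")
  }
  structure(list(coord_sd = coord_sd, dropout_p = dropout_p,
                 low_conf_p = low_conf_p, det_miss_p = det_miss_p,
                 det_confuse = det_confuse),
            class = "noise_model")
}

#' Simulation script: a scripted night of behavior bouts
#'
#' @param bouts Data frame with columns `behavior`, `start_s`, `duration_s`;
#'   whole seconds, non-overlapping, inside `[0, total_duration_s)`.
#' @param total_duration_s Night length in seconds (default 25200: seven
#'   hours of nocturnal observation, 22:00 to 05:00).
#' @param seed Seed recorded for provenance (may be `NA`).
#' @return A `simulation_script` object.
#' @export
simulation_script <- function(bouts, total_duration_s = 25200, seed = NA) {
  bouts <- as.data.frame(bouts)
  stopifnot(all(c("behavior", "start_s", "duration_s") %in% names(bouts)))
  bouts <- bouts[order(bouts$start_s), , drop = FALSE]
  rownames(bouts) <- NULL
  if (nrow(bouts)) {
    if (any(bouts$duration_s <= 0)) stop("bout durations must be positive")
    if (min(bouts$start_s) < 0 ||
        max(bouts$start_s + bouts$duration_s) > total_duration_s)
      stop("bouts must lie within [0, total_duration_s)")
    ends <- bouts$start_s + bouts$duration_s
    if (nrow(bouts) > 1L && any(bouts$start_s[-1L] < ends[-nrow(bouts)]))
      stop("bouts overlap")
  }
  structure(list(bouts = bouts,
                 total_duration_s = as.numeric(total_duration_s),
                 seed = seed),
            class = "simulation_script")
}

#' @export
print.simulation_script <- function(x, ...) {
  cat("<simulation_script> ", nrow(x$bouts), " bouts over ",
      x$total_duration_s, " s\n", sep = "")
  invisible(x)
}

#' Draw a random night script
#'
#' Alternating-renewal schedule: behaviors are drawn uniformly (never
#' repeating the immediately preceding one) with exponentially distributed
#' bout lengths of the given means, rounded to whole seconds and clamped to
#' at least 1 s, until the night is tiled; the last bout is truncated at the
#' night's end.
#'
#' @param config An [ethogram_config()] (bout behaviors must be declared).
#' @param seed Integer seed; fixed seed gives an identical script.
#' @param mean_bout_s Named numeric vector of mean bout lengths in seconds,
#'   one entry per behavior to simulate.
#' @param total_duration_s Night length in seconds.
#' @return A [simulation_script()].
#' @export
random_script <- function(config, seed, mean_bout_s,
                          total_duration_s = 25200) {
  if (is.null(names(mean_bout_s)) || any(!nzchar(names(mean_bout_s))))
    stop("mean_bout_s must be a named vector")
  unknown <- setdiff(names(mean_bout_s), config$behaviors$name)
  if (length(unknown)) stop("undeclared behavior in mean_bout_s: ", unknown[1])
  if (any(mean_bout_s <= 0)) stop("mean bout lengths must be positive")
  set.seed(seed)
  nm <- names(mean_bout_s)
  beh <- character(0); dur <- numeric(0)
  t <- 0; prev <- NA_character_
  while (t < total_duration_s) {
    pick <- if (length(nm) == 1L) nm else sample(setdiff(nm, prev), 1L)
    d <- max(1, round(stats::rexp(1L, rate = 1 / mean_bout_s[[pick]])))
    d <- min(d, total_duration_s - t)
    if (length(beh) && pick == beh[length(beh)]) {
      dur[length(dur)] <- dur[length(dur)] + d   # merge same-behavior bouts
    } else {
      beh <- c(beh, pick); dur <- c(dur, d)
    }
    prev <- pick; t <- t + d
  }
  simulation_script(data.frame(behavior = beh,
                               start_s = cumsum(c(0, dur[-length(dur)])),
                               duration_s = dur),
                    total_duration_s, seed)
}

#' Rasterize a script to a labeled grid
#'
#' Expands a bout script into a fully labeled [behavior_sequence()]; seconds
#' (or frames) not covered by any bout get the config's default behavior.
#' This is the ground truth against which classified sequences are compared.
#'
#' @param script A [simulation_script()].
#' @param config An [ethogram_config()].
#' @param resolution `"second"` or `"frame"`.
#' @return A [behavior_sequence()].
#' @export
rasterize_script <- function(script, config,
                             resolution = c("second", "frame")) {
  resolution <- match.arg(resolution)
  labels <- rep(default_behavior(config), script$total_duration_s)
  for (i in seq_len(nrow(script$bouts))) {
    b <- script$bouts[i, ]
    labels[seq.int(b$start_s + 1L, b$start_s + b$duration_s)] <- b$behavior
  }
  if (resolution == "frame") labels <- rep(labels, each = config$fps)
  behavior_sequence(labels, resolution, config$fps)
}

# Per-frame true-label vector for a script (0-based frame t covers time
# [t/fps, (t+1)/fps); second s covers frames floor(s*fps)..floor((s+1)*fps)-1).
script_frame_labels <- function(script, config) {
  rasterize_script(script, config, "frame")$labels
}

#' Simulate keypoint trajectories for a scripted night
#'
#' Places every bodypart at its behavior's geometry position (a point inside
#' that behavior's zone box, or the default stance), renders swaying bouts as
#' a lateral sinusoid `x(t) = x0 + A sin(2 pi t / T)` on the configured sway
#' bodyparts (head and trunk root by default), then applies the noise model:
#' Gaussian jitter, dropout, and low-likelihood draws.
#'
#' @param script A [simulation_script()].
#' @param config An [ethogram_config()] with `geometry` for every scripted
#'   behavior.
#' @param noise A [noise_model()].
#' @param seed Integer seed for all stochastic draws.
#' @return A [keypoint_track()].
#' @export
simulate_keypoints <- function(script, config, noise = noise_model(),
                               seed = 1) {
  set.seed(seed)
  fps <- config$fps
  nf <- as.integer(script$total_duration_s * fps)
  bp <- config$bodyparts
  truth <- script_frame_labels(script, config)
  missing_geom <- setdiff(unique(truth), names(config$geometry))
  if (length(missing_geom))
    stop("scripted behavior lacking geometry: '", missing_geom[1], "'")

  x <- matrix(NA_real_, nf, length(bp), dimnames = list(NULL, bp))
  y <- x
  for (b in unique(truth)) {
    idx <- truth == b
    g <- config$geometry[[b]]
    miss_bp <- setdiff(bp, names(g))
    if (length(miss_bp))
      stop("geometry for '", b, "' lacks bodypart '", miss_bp[1], "'")
    for (p in bp) {
      x[idx, p] <- g[[p]][1]
      y[idx, p] <- g[[p]][2]
    }
  }
  # sway kinematics: lateral oscillation while otherwise standing in place
  sway_cfg <- config$sway
  if (!is.null(sway_cfg) && "Swaying" %in% truth) {
    A <- sway_cfg$amplitude_px %||% 40
    Tp <- sway_cfg$period_s %||% 4
    sway_bp <- intersect(unlist(sway_cfg$bodyparts %||% c("head", "trunk_root")), bp)
    sb <- script$bouts[script$bouts$behavior == "Swaying", , drop = FALSE]
    for (i in seq_len(nrow(sb))) {
      f0 <- as.integer(sb$start_s[i] * fps)
      fl <- as.integer(sb$duration_s[i] * fps)
      tt <- (seq_len(fl) - 1L) / fps
      osc <- A * sin(2 * pi * tt / Tp)
      for (p in sway_bp) x[f0 + seq_len(fl), p] <- x[f0 + seq_len(fl), p] + osc
    }
  }
  if (noise$coord_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, noise$coord_sd)
    y <- y + stats::rnorm(length(y), 0, noise$coord_sd)
  }
  pc <- config$p_cutoff
  low <- stats::runif(nf * length(bp)) < noise$low_conf_p
  lik <- matrix(ifelse(low, stats::runif(nf * length(bp), 0, max(pc - 1e-9, 0)),
                       stats::runif(nf * length(bp), pc, 1)),
                nf, length(bp), dimnames = list(NULL, bp))
  if (noise$dropout_p > 0) {
    drop <- matrix(stats::runif(nf * length(bp)) < noise$dropout_p,
                   nf, length(bp))
    x[drop] <- NA_real_; y[drop] <- NA_real_; lik[drop] <- NA_real_
  }
  keypoint_track(x, y, lik, bp, fps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a detection stream for a scripted night
#'
#' Emits one detection per frame from the true label, dropped with
#' probability `det_miss_p` and passed through the label-confusion matrix
#' `det_confuse` (identity when `NULL`). Confidences are drawn uniformly on
#' \[0.5, 1\].
#'
#' @inheritParams simulate_keypoints
#' @return A [detection_stream()].
#' @export
simulate_detections <- function(script, config, noise = noise_model(),
                                seed = 1) {
  set.seed(seed)
  truth <- script_frame_labels(script, config)
  nf <- length(truth)
  labels <- config$behaviors$name
  emitted <- truth
  C <- noise$det_confuse
  if (!is.null(C)) {
    miss <- setdiff(unique(truth), rownames(C))
    if (length(miss))
      stop("det_confuse lacks a row for behavior '", miss[1], "'")
    for (b in unique(truth)) {
      idx <- which(truth == b)
      emitted[idx] <- sample(colnames(C), length(idx), replace = TRUE,
                             prob = C[b, ])
    }
  }
  conf <- stats::runif(nf, 0.5, 1)
  if (noise$det_miss_p > 0) {
    missed <- stats::runif(nf) < noise$det_miss_p
    emitted[missed] <- NA_character_
    conf[missed] <- NA_real_
  }
  detection_stream(emitted, conf, labels, config$fps)
}

#' Simulate a complete synthetic night
#'
#' Runs [simulate_keypoints()] and [simulate_detections()] on one script and
#' returns them together with the rasterized ground truth. All randomness
#' flows from `seed` (keypoints and detections use derived sub-seeds), so a
#' fixed seed reproduces the night bit-identically.
#'
#' @inheritParams simulate_keypoints
#' @return A list with elements `track` ([keypoint_track()]), `detections`
#'   ([detection_stream()]), and `truth` (second-resolution
#'   [behavior_sequence()]).
#' @export
simulate_night <- function(script, config, noise = noise_model(), seed = 1) {
  list(track = simulate_keypoints(script, config, noise, seed = seed),
       detections = simulate_detections(script, config, noise,
                                        seed = seed + 1L),
       truth = rasterize_script(script, config, "second"))
}
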