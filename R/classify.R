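#' Condition a track by the likelihood p-cutoff
#'
#' Samples whose likelihood is missing or strictly below the cutoff are
#' marked invalid (x and y set to missing); samples at or above the cutoff
#' are kept unchanged, so a likelihood exactly equal to the cutoff is
#' retained. Likelihood values themselves are preserved, which makes
#' re-conditioning at a stricter cutoff well defined.
#'
#' @param track A [keypoint_track()].
#' @param p_cutoff Likelihood threshold in \[0, 1\].
#' @return A conditioned [keypoint_track()].
#' @export
apply_pcutoff <- function(track, p_cutoff = 0.5) {
  stopifnot(p_cutoff >= 0, p_cutoff <= 1)
  invalid <- !valid_samples(track, p_cutoff)
  track$x[invalid] <- NA_real_
  track$y[invalid] <- NA_real_
  track
}

# frames x bodyparts logical matrix: sample present and at/above the cutoff
valid_samples <- function(track, p_cutoff) {
  v <- !is.na(track$x) & !is.na(track$y) & !is.na(track$likelihood) &
    track$likelihood >= p_cutoff
  v
}

#' Classify one frame of keypoints
#'
#' Zone rules are tried in priority order (lowest number first); a rule
#' matches when all of its constrained bodyparts are valid and inside their
#' boxes. If no rule matches but at least one anchor bodypart is valid, the
#' default behavior is returned; if every anchor is invalid the frame is
#' [OUT_OF_VIEW].
#'
#' @param x,y,likelihood Named numeric vectors over the config's bodyparts
#'   (`NA` = missing).
#' @param config An [ethogram_config()].
#' @param p_cutoff Likelihood threshold; defaults to the config's.
#' @return A single behavior label.
#' @export
classify_frame <- function(x, y, likelihood, config,
                           p_cutoff = config$p_cutoff) {
  tr <- keypoint_track(matrix(x[config$bodyparts], 1),
                       matrix(y[config$bodyparts], 1),
                       matrix(likelihood[config$bodyparts], 1),
                       config$bodyparts, config$fps)
  classify_track(tr, config, p_cutoff = p_cutoff)$labels
}

#' Classify a keypoint track into a frame-resolution behavior sequence
#'
#' Applies the p-cutoff, then the zone rules of the configuration to every
#' frame (see [classify_frame()] for the per-frame semantics). Length is
#' preserved: one label per frame.
#'
#' @param track A [keypoint_track()]; may be raw (the cutoff is applied
#'   internally) or already conditioned.
#' @param config An [ethogram_config()].
#' @param p_cutoff Likelihood threshold; defaults to the config's.
#' @return A frame-resolution [behavior_sequence()].
#' @export
classify_track <- function(track, config, p_cutoff = config$p_cutoff) {
  miss_bp <- setdiff(config$bodyparts, track$bodyparts)
  if (length(miss_bp))
    stop("track lacks config bodypart '", miss_bp[1], "'")
  nf <- n_frames(track)
  v <- valid_samples(track, p_cutoff)
  out <- rep(NA_character_, nf)
  unassigned <- rep(TRUE, nf)
  for (r in config$zone_rules) {
    match <- unassigned
    for (i in seq_len(nrow(r$constraints))) {
      cs <- r$constraints[i, ]
      p <- cs$bodypart
      match <- match & v[, p] &
        !is.na(track$x[, p]) & track$x[, p] >= cs$x_min & track$x[, p] <= cs$x_max &
        !is.na(track$y[, p]) & track$y[, p] >= cs$y_min & track$y[, p] <= cs$y_max
      match[is.na(match)] <- FALSE
    }
    out[match] <- r$behavior
    unassigned <- unassigned & !match
  }
  anchored <- if (nf) rowSums(v[, config$anchor_bodyparts, drop = FALSE]) > 0
    else logical(0)
  out[unassigned & anchored] <- default_behavior(config)
  out[unassigned & !anchored] <- OUT_OF_VIEW
  behavior_sequence(out, "frame", track$fps, track$origin_time)
}

#' Adopt detector labels as a behavior sequence
#'
#' Labeled frames whose confidence is at or above the threshold keep their
#' label; unlabeled or low-confidence frames become [OUT_OF_VIEW].
#'
#' @param stream A [detection_stream()].
#' @param min_confidence Confidence threshold in \[0, 1\].
#' @return A frame-resolution [behavior_sequence()].
#' @export
detections_to_sequence <- function(stream, min_confidence = 0.5) {
  stopifnot(min_confidence >= 0, min_confidence <= 1)
  keep <- !is.na(stream$label) & stream$confidence >= min_confidence
  labels <- ifelse(keep, stream$label, OUT_OF_VIEW)
  behavior_sequence(labels, "frame", stream$fps, stream$origin_time)
}

#' Aggregate a frame-resolution sequence to seconds
#'
#' Second `s` covers frames `floor(s*fps) .. floor((s+1)*fps) - 1` and is
#' labeled by majority vote over those frames. Ties are broken by the
#' config's tie ranking (zone-rule priority first, the default behavior
#' after all ruled behaviors) and [OUT_OF_VIEW] loses every tie. A trailing
#' partial second is voted over its available frames.
#'
#' @param seq A frame-resolution [behavior_sequence()].
#' @param config An [ethogram_config()].
#' @param fps Frame rate; defaults to the sequence's.
#' @return A second-resolution [behavior_sequence()].
#' @export
aggregate_to_seconds <- function(seq, config, fps = seq$fps) {
  stopifnot(seq$resolution == "frame", fps > 0)
  nf <- length(seq$labels)
  if (nf == 0L) return(behavior_sequence(character(0), "second", fps,
                                         seq$origin_time))
  rk <- tie_rank(config)
  lv <- names(sort(rk))                      # columns ordered by tie rank
  unknown <- setdiff(unique(seq$labels), lv)
  if (length(unknown)) stop("label '", unknown[1], "' not in config label set")
  sec <- floor((seq_len(nf) - 1L) / fps)
  counts <- table(factor(sec, levels = 0:max(sec)),
                  factor(seq$labels, levels = lv))
  # max.col(ties = "first") + tie-ranked column order == the tie rule
  win <- lv[max.col(counts, ties.method = "first")]
  behavior_sequence(win, "second", fps, seq$origin_time)
}

#' Enforce minimum bout durations
#'
#' Every maximal run of a behavior with a positive `min_duration_s` that is
#' shorter than its minimum is relabeled to the default behavior (e.g. a
#' swaying run under 5 s is coded as standing); all other labels are
#' untouched.
#'
#' @param seq A second-resolution [behavior_sequence()].
#' @param config An [ethogram_config()].
#' @return A second-resolution [behavior_sequence()].
#' @export
enforce_min_duration <- function(seq, config) {
  stopifnot(seq$resolution == "second")
  mins <- stats::setNames(config$behaviors$min_duration_s,
                          config$behaviors$name)
  constrained <- names(mins)[mins > 0]
  if (!length(constrained) || !length(seq$labels)) return(seq)
  r <- rle(seq$labels)
  short <- r$values %in% constrained & r$lengths < mins[r$values]
  r$values[which(short)] <- default_behavior(config)
  seq$labels <- inverse.rle(r)
  seq
}

#' Full pose-to-seconds classification pipeline
#'
#' [classify_track()], [aggregate_to_seconds()] and
#' [enforce_min_duration()] composed in the standard order.
#'
#' @inheritParams classify_track
#' @return A second-resolution [behavior_sequence()].
#' @export
classify_to_seconds <- function(track, config, p_cutoff = config$p_cutoff) {
  enforce_min_duration(
    aggregate_to_seconds(classify_track(track, config, p_cutoff), config),
    config)
}
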