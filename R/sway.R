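#' Per-frame step displacements of one bodypart
#'
#' Euclidean distance between the bodypart's positions in consecutive valid
#' frames. The first frame and any frame adjacent to an invalid sample get
#' step 0: gaps are bridged without charging the jump across them, so label
#' dropout does not fabricate motion.
#'
#' @param track A [keypoint_track()].
#' @param bodypart Bodypart name (e.g. `"trunk_root"`).
#' @param p_cutoff Optional likelihood threshold; samples below it are
#'   treated as invalid. `NULL` (default) uses presence only, for tracks
#'   already conditioned with [apply_pcutoff()].
#' @return Numeric vector of length `n_frames(track)`; `steps[1] == 0`.
#' @export
step_displacements <- function(track, bodypart, p_cutoff = NULL) {
  if (!bodypart %in% track$bodyparts)
    stop("unknown bodypart '", bodypart, "'")
  x <- track$x[, bodypart]; y <- track$y[, bodypart]
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(p_cutoff))
    ok <- ok & !is.na(track$likelihood[, bodypart]) &
      track$likelihood[, bodypart] >= p_cutoff
  nf <- length(x)
  if (nf == 0L) return(numeric(0))
  d <- c(0, sqrt(diff(x)^2 + diff(y)^2))
  both <- c(FALSE, ok[-nf] & ok[-1L])
  d[!both] <- 0
  d
}

#' Cumulative displacement series
#'
#' Running sum of non-negative step displacements; its slope is the
#' displacement rate, and sustained steep increases are the signature of
#' swaying in the cumulative trace.
#'
#' @param steps Non-negative numeric vector from [step_displacements()].
#' @return Numeric vector of the same length, nondecreasing.
#' @export
cumulative_displacement <- function(steps) {
  if (any(steps < 0, na.rm = TRUE)) stop("steps must be >= 0")
  cumsum(steps)
}

#' Detect sway bouts from displacement rate
#'
#' A second is "active" when the windowed mean displacement rate (centered
#' rolling mean of per-second displacement, partial windows at the edges) is
#' at or above `rate_threshold`. Active runs separated by gaps of at most
#' `merge_gap_s` are merged, and merged runs of at least `min_duration_s`
#' (the ethogram's 5-s minimum for stereotypic swaying, by default) are
#' returned as bouts.
#'
#' @param steps Per-frame step series from [step_displacements()].
#' @param fps Frames per second.
#' @param window_s Smoothing window in seconds (> 0).
#' @param rate_threshold Activity threshold in pixels/second.
#' @param min_duration_s Minimum bout length in seconds.
#' @param merge_gap_s Maximum inactive gap (seconds) bridged inside a bout.
#' @return Data frame with columns `start_s`, `end_s` (half-open
#'   `[start_s, end_s)` intervals) and `mean_rate_px_s`; zero rows when
#'   nothing exceeds the threshold.
#' @export
detect_sway_bouts <- function(steps, fps = 25, window_s = 10,
                              rate_threshold, min_duration_s = 5,
                              merge_gap_s = 2) {
  stopifnot(window_s > 0, min_duration_s >= 0, merge_gap_s >= 0, fps > 0)
  nf <- length(steps)
  ns <- floor(nf / fps)
  if (ns == 0L) return(empty_bouts())
  sec <- floor((seq_len(ns * fps) - 1L) / fps)
  rate <- as.numeric(tapply(steps[seq_len(ns * fps)], sec, sum))  # px per second
  smooth <- rolling_mean_partial(rate, window_s)
  active <- smooth >= rate_threshold
  active <- merge_gaps(active, merge_gap_s)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration_s
  if (!any(keep)) return(empty_bouts())
  out <- data.frame(start_s = starts[keep] - 1L, end_s = ends[keep])
  out$mean_rate_px_s <- vapply(seq_len(nrow(out)), function(i)
    mean(rate[(out$start_s[i] + 1L):out$end_s[i]]), numeric(1))
  out
}

empty_bouts <- function()
  data.frame(start_s = numeric(0), end_s = numeric(0),
             mean_rate_px_s = numeric(0))

# centered rolling mean with shrinking windows at the edges
rolling_mean_partial <- function(v, w) {
  n <- length(v)
  half_lo <- floor((w - 1) / 2)
  half_hi <- w - 1 - half_lo
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# bridge FALSE runs of length <= gap that sit between TRUE runs
merge_gaps <- function(active, gap) {
  if (gap <= 0 || !any(active)) return(active)
  r <- rle(active)
  k <- length(r$values)
  bridge <- !r$values & r$lengths <= gap &
    seq_len(k) > 1L & seq_len(k) < k
  r$values[bridge] <- TRUE
  inverse.rle(r)
}

#' Build a sway trace for one bodypart
#'
#' Convenience wrapper bundling [step_displacements()],
#' [cumulative_displacement()] and [detect_sway_bouts()] into one object for
#' reporting and plotting the cumulative trunk-root trace.
#'
#' @inheritParams step_displacements
#' @inheritParams detect_sway_bouts
#' @return A `sway_trace` list with fields `bodypart`, `steps`,
#'   `cumulative`, `bouts`, `fps`.
#' @export
sway_trace <- function(track, bodypart = "trunk_root",
                       p_cutoff = NULL, window_s = 10, rate_threshold,
                       min_duration_s = 5, merge_gap_s = 2) {
  steps <- step_displacements(track, bodypart, p_cutoff)
  structure(list(
    bodypart = bodypart,
    steps = steps,
    cumulative = cumulative_displacement(steps),
    bouts = detect_sway_bouts(steps, track$fps, window_s, rate_threshold,
                              min_duration_s, merge_gap_s),
    fps = track$fps), class = "sway_trace")
}

#' @export
print.sway_trace <- function(x, ...) {
  cat("<sway_trace> '", x$bodypart, "': total displacement ",
      round(max(c(0, x$cumulative)), 1), " px over ",
      round(length(x$steps) / x$fps, 1), " s; ",
      nrow(x$bouts), " bout(s)\n", sep = "")
  invisible(x)
}
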