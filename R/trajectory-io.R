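#' Keypoint trajectory track
#'
#' Rectangular container for pose-estimation output: for each frame and each
#' bodypart an (x, y) pixel estimate and a likelihood in \[0, 1\]. Missing
#' estimates (frames the network did not label) are `NA` in all three slots;
#' this is distinct from a low-likelihood estimate, which is present but may
#' be discarded by the p-cutoff.
#'
#' @param x,y,likelihood Numeric matrices, frames x bodyparts.
#' @param bodyparts Character vector naming the columns.
#' @param fps Frames per second.
#' @param origin_time Clock time of frame 0 (informational), e.g. `"22:00:00"`.
#' @return A `keypoint_track` object.
#' @export
keypoint_track <- function(x, y, likelihood, bodyparts, fps = 25,
                           origin_time = "22:00:00") {
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  stopifnot(identical(dim(x), dim(y)), identical(dim(x), dim(likelihood)),
            ncol(x) == length(bodyparts), fps > 0)
  if (any(likelihood < 0 | likelihood > 1, na.rm = TRUE))
    stop("likelihood outside [0, 1]")
  dimnames(x) <- dimnames(y) <- dimnames(likelihood) <-
    list(NULL, as.character(bodyparts))
  structure(list(x = x, y = y, likelihood = likelihood,
                 bodyparts = as.character(bodyparts),
                 fps = as.numeric(fps), origin_time = origin_time),
            class = "keypoint_track")
}

#' @export
print.keypoint_track <- function(x, ...) {
  cat("<keypoint_track> ", nrow(x$x), " frames x ", length(x$bodyparts),
      " bodyparts @ ", x$fps, " FPS (",
      round(nrow(x$x) / x$fps, 1), " s)\n", sep = "")
  cat("  bodyparts: ", paste(x$bodyparts, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of frames in a track
#' @param track A `keypoint_track`.
#' @return Integer frame count.
#' @export
n_frames <- function(track) nrow(track$x)

#' Read a pose-trajectory CSV
#'
#' Parses the three-header-row pose-CSV dialect used by markerless
#' pose-estimation tools: row 1 names the scorer/model, row 2 repeats each
#' bodypart three times, row 3 cycles `x, y, likelihood`; the first column
#' holds the frame index. Empty cells mean "not labeled" and become missing
#' samples; malformed headers, non-numeric cells and likelihoods outside
#' \[0, 1\] raise errors naming the offending row/column.
#'
#' @param path CSV file path.
#' @param fps Frames per second recorded on the returned track.
#' @param origin_time Clock time of frame 0.
#' @return A [keypoint_track()].
#' @export
read_pose_csv <- function(path, fps = 25, origin_time = "22:00:00") {
  if (!file.exists(path)) stop("pose CSV not found: ", path)
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         colClasses = "character")
  if (nrow(hdr) < 3L) stop("pose CSV '", path, "': expected 3 header rows")
  coords <- as.character(hdr[3, -1])
  bp_row <- as.character(hdr[2, -1])
  ncol_data <- length(coords)
  if (ncol_data == 0L || ncol_data %% 3L != 0L)
    stop("pose CSV '", path, "': data columns not a multiple of 3")
  if (!all(coords == rep(c("x", "y", "likelihood"), ncol_data / 3L)))
    stop("pose CSV '", path, "': third header row must cycle x,y,likelihood")
  bodyparts <- bp_row[seq(1L, ncol_data, by = 3L)]
  if (!all(bp_row == rep(bodyparts, each = 3L)))
    stop("pose CSV '", path, "': bodypart header does not repeat in triplets")

  dat <- utils::read.csv(path, header = FALSE, skip = 3,
                         colClasses = "character")
  if (nrow(dat) == 0L) {
    m <- matrix(numeric(0), 0, length(bodyparts))
    return(keypoint_track(m, m, m, bodyparts, fps, origin_time))
  }
  if (ncol(dat) != ncol_data + 1L)
    stop("pose CSV '", path, "': data rows have ", ncol(dat),
         " columns, header implies ", ncol_data + 1L)
  num <- function(col, j) {
    v <- col
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop("pose CSV '", path, "': non-numeric cell at data row ", bad[1],
           ", column ", j)
    out
  }
  vals <- vapply(seq_len(ncol_data),
                 function(j) num(dat[[j + 1L]], j + 1L),
                 numeric(nrow(dat)))
  vals <- matrix(vals, nrow = nrow(dat))
  xi <- seq(1L, ncol_data, by = 3L)
  x <- vals[, xi, drop = FALSE]
  y <- vals[, xi + 1L, drop = FALSE]
  lik <- vals[, xi + 2L, drop = FALSE]
  bad <- which(lik < 0 | lik > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop("pose CSV '", path, "': likelihood outside [0,1] at data row ",
         bad[1, 1], ", bodypart '", bodyparts[bad[1, 2]], "'")
  # a partially-missing triplet is treated as fully missing
  miss <- is.na(x) | is.na(y) | is.na(lik)
  x[miss] <- NA_real_; y[miss] <- NA_real_; lik[miss] <- NA_real_
  keypoint_track(x, y, lik, bodyparts, fps, origin_time)
}

#' Write a pose-trajectory CSV
#'
#' Inverse of [read_pose_csv()]; missing samples are written as empty cells.
#'
#' @param track A [keypoint_track()].
#' @param path Output path.
#' @param scorer Name written in the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path, scorer = "ethonight") {
  p <- length(track$bodyparts)
  hdr1 <- c("scorer", rep(scorer, 3L * p))
  hdr2 <- c("bodyparts", rep(track$bodyparts, each = 3L))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), p))
  nf <- n_frames(track)
  body <- matrix("", nrow = nf, ncol = 3L * p)
  fmt <- function(m) ifelse(is.na(m), "", formatC(m, format = "g", digits = 15))
  for (j in seq_len(p)) {
    body[, 3L * j - 2L] <- fmt(track$x[, j])
    body[, 3L * j - 1L] <- fmt(track$y[, j])
    body[, 3L * j]      <- fmt(track$likelihood[, j])
  }
  lines <- c(paste(hdr1, collapse = ","), paste(hdr2, collapse = ","),
             paste(hdr3, collapse = ","),
             if (nf) paste(seq_len(nf) - 1L, apply(body, 1L, paste, collapse = ","),
                           sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Per-frame detection stream
#'
#' Output of a frame-classifying object detector: for each frame, optionally
#' a behavior label and a confidence. Frames the detector left unlabeled are
#' `NA` and are mapped to [OUT_OF_VIEW] downstream.
#'
#' @param label Character vector (length = frames), `NA` where unlabeled.
#' @param confidence Numeric vector aligned with `label`; must be present
#'   exactly where a label is present.
#' @param labels Declared label set the stream may use.
#' @param fps Frames per second.
#' @param origin_time Clock time of frame 0.
#' @return A `detection_stream` object.
#' @export
detection_stream <- function(label, confidence, labels, fps = 25,
                             origin_time = "22:00:00") {
  label <- as.character(label); confidence <- as.numeric(confidence)
  stopifnot(length(label) == length(confidence))
  if (any(is.na(label) != is.na(confidence)))
    stop("confidence must be present exactly where a label is present")
  unknown <- setdiff(unique(label[!is.na(label)]), labels)
  if (length(unknown)) stop("unknown label '", unknown[1], "' in stream")
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE))
    stop("confidence outside [0, 1]")
  structure(list(label = label, confidence = confidence,
                 labels = as.character(labels), fps = as.numeric(fps),
                 origin_time = origin_time),
            class = "detection_stream")
}

#' @export
print.detection_stream <- function(x, ...) {
  cat("<detection_stream> ", length(x$label), " frames @ ", x$fps,
      " FPS; ", sum(!is.na(x$label)), " labeled\n", sep = "")
  invisible(x)
}

#' Read a detection CSV
#'
#' One row per labeled frame: `frame` (0-based index), `behavior`,
#' `confidence` (optional column; defaults to 1.0 when absent, for exports
#' thresholded upstream). Frames not listed are unlabeled.
#'
#' @param path CSV path with header `frame,behavior[,confidence]`.
#' @param n_frames Declared stream length.
#' @param labels Declared label set.
#' @param fps,origin_time Stream metadata.
#' @return A [detection_stream()].
#' @export
read_detections_csv <- function(path, n_frames, labels, fps = 25,
                                origin_time = "22:00:00") {
  if (!file.exists(path)) stop("detection CSV not found: ", path)
  d <- utils::read.csv(path, colClasses = NA)
  if (!all(c("frame", "behavior") %in% names(d)))
    stop("detection CSV '", path, "' needs columns frame,behavior")
  if (is.null(d$confidence)) d$confidence <- rep(1, nrow(d))
  if (anyDuplicated(d$frame))
    stop("duplicate detection for frame ", d$frame[duplicated(d$frame)][1])
  if (nrow(d) && (min(d$frame) < 0 || max(d$frame) >= n_frames))
    stop("detection frame index outside [0, ", n_frames, ")")
  label <- rep(NA_character_, n_frames)
  conf <- rep(NA_real_, n_frames)
  label[d$frame + 1L] <- as.character(d$behavior)
  conf[d$frame + 1L] <- d$confidence
  detection_stream(label, conf, labels, fps, origin_time)
}

#' Write a detection CSV
#' @param stream A [detection_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(stream, path) {
  i <- which(!is.na(stream$label))
  utils::write.csv(data.frame(frame = i - 1L, behavior = stream$label[i],
                              confidence = stream$confidence[i]),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Behavior sequence
#'
#' A fully labeled time grid at frame or second resolution; every tick
#' carries a behavior label or the [OUT_OF_VIEW] sentinel, so total duration
#' is `n_ticks / rate` with no gaps.
#'
#' @param labels Character vector of per-tick labels.
#' @param resolution `"frame"` or `"second"`.
#' @param fps Frames per second of the underlying video (used by
#'   `resolution = "frame"` and for aggregation).
#' @param origin_time Clock time of tick 0.
#' @return A `behavior_sequence` object.
#' @export
behavior_sequence <- function(labels, resolution = c("second", "frame"),
                              fps = 25, origin_time = "22:00:00") {
  resolution <- match.arg(resolution)
  labels <- as.character(labels)
  if (anyNA(labels)) stop("behavior_sequence labels must not be NA; use OUT_OF_VIEW")
  structure(list(labels = labels, resolution = resolution,
                 fps = as.numeric(fps), origin_time = origin_time),
            class = "behavior_sequence")
}

#' @export
print.behavior_sequence <- function(x, ...) {
  cat("<behavior_sequence> ", length(x$labels), " ", x$resolution, "s (",
      round(duration_s(x), 1), " s)\n", sep = "")
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Duration of a behavior sequence in seconds
#' @param seq A [behavior_sequence()].
#' @return Seconds covered by the sequence.
#' @export
duration_s <- function(seq) {
  if (seq$resolution == "second") length(seq$labels)
  else length(seq$labels) / seq$fps
}

#' Read a second-resolution label CSV (manual scoring format)
#'
#' Columns `second` (0-based) and `behavior`; seconds not listed are filled
#' with [OUT_OF_VIEW], matching the convention that un-coded time is
#' unobserved.
#'
#' @param path CSV path.
#' @param n_seconds Total observation length in seconds.
#' @param fps,origin_time Metadata for the returned sequence.
#' @return A second-resolution [behavior_sequence()].
#' @export
read_labels_csv <- function(path, n_seconds, fps = 25,
                            origin_time = "22:00:00") {
  if (!file.exists(path)) stop("label CSV not found: ", path)
  d <- utils::read.csv(path, colClasses = NA)
  if (!all(c("second", "behavior") %in% names(d)))
    stop("label CSV '", path, "' needs columns second,behavior")
  if (anyDuplicated(d$second))
    stop("duplicate label for second ", d$second[duplicated(d$second)][1])
  if (nrow(d) && (min(d$second) < 0 || max(d$second) >= n_seconds))
    stop("second index outside [0, ", n_seconds, ")")
  labels <- rep(OUT_OF_VIEW, n_seconds)
  labels[d$second + 1L] <- as.character(d$behavior)
  behavior_sequence(labels, "second", fps, origin_time)
}

#' Write a label CSV
#'
#' Second-resolution sequences are written as `second,behavior` rows,
#' frame-resolution ones as `frame,behavior`; [OUT_OF_VIEW] ticks are
#' omitted (they are the reader's gap-fill).
#'
#' @param seq A [behavior_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(seq, path) {
  i <- which(seq$labels != OUT_OF_VIEW)
  col <- if (seq$resolution == "second") "second" else "frame"
  d <- data.frame(t = i - 1L, behavior = seq$labels[i])
  names(d)[1] <- col
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
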