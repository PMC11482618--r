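#' Nocturnal time budget
#'
#' Percentage of observation time spent in each behavior, computed from the
#' sums of coded seconds; un-coded time counts as [OUT_OF_VIEW], so the
#' percentages always total 100.
#'
#' @param seq A second-resolution [behavior_sequence()] (a frame-resolution
#'   sequence is accepted and weighted by frames).
#' @param config An [ethogram_config()] fixing the category order.
#' @return A `time_budget` data frame with columns `behavior`, `seconds`,
#'   `percent` and attribute `total_duration_s`.
#' @export
time_budget <- function(seq, config) {
  if (length(seq$labels) == 0L) stop("cannot budget an empty sequence")
  lv <- label_set(config)
  unknown <- setdiff(unique(seq$labels), lv)
  if (length(unknown)) stop("label '", unknown[1], "' not in config label set")
  ticks <- table(factor(seq$labels, levels = lv))
  per_tick <- if (seq$resolution == "second") 1 else 1 / seq$fps
  seconds <- as.numeric(ticks) * per_tick
  out <- data.frame(behavior = lv, seconds = seconds,
                    percent = 100 * seconds / sum(seconds))
  attr(out, "total_duration_s") <- sum(seconds)
  class(out) <- c("time_budget", "data.frame")
  out
}

#' Cumulative behavior curves
#'
#' For each behavior, the running total of seconds spent in it up to each
#' second of the night; the curves are nondecreasing and their final values
#' sum to the total duration.
#'
#' @param seq A second-resolution [behavior_sequence()].
#' @param config Optional [ethogram_config()] fixing the behavior set;
#'   defaults to the labels present.
#' @return A numeric matrix, seconds x behaviors, of cumulative seconds.
#' @export
cumulative_curves <- function(seq, config = NULL) {
  stopifnot(seq$resolution == "second")
  lv <- if (is.null(config)) sort(unique(seq$labels)) else label_set(config)
  n <- length(seq$labels)
  out <- vapply(lv, function(b) cumsum(seq$labels == b), numeric(n))
  matrix(out, nrow = n, dimnames = list(NULL, lv))
}

#' Confusion matrix of predicted vs observed coding
#'
#' Cross-tabulates two aligned behavior sequences: rows are the predicted
#' (automated) labels, columns the observed (manual) labels, counts are
#' seconds (or frames, at frame resolution).
#'
#' @param pred,obs Two [behavior_sequence()]s of equal length and
#'   resolution.
#' @param config Optional [ethogram_config()] fixing the label order;
#'   defaults to the union of labels present.
#' @return A `confusion_matrix`: an integer matrix with dimnames
#'   `predicted` x `observed`.
#' @export
confusion_matrix <- function(pred, obs, config = NULL) {
  if (length(pred$labels) != length(obs$labels))
    stop("sequences differ in length: ", length(pred$labels), " vs ",
         length(obs$labels))
  if (!identical(pred$resolution, obs$resolution))
    stop("sequences differ in resolution")
  lv <- if (is.null(config)) sort(unique(c(pred$labels, obs$labels)))
    else label_set(config)
  m <- table(predicted = factor(pred$labels, levels = lv),
             observed = factor(obs$labels, levels = lv))
  m <- unclass(m)
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Column-normalize a confusion matrix
#'
#' Divides each column by its total so that each observed behavior's column
#' gives the distribution of predictions for it (columns sum to 1; all-zero
#' columns stay zero).
#'
#' @param cm A [confusion_matrix()] (or any numeric matrix).
#' @return A numeric matrix of the same shape.
#' @export
column_normalize <- function(cm) {
  cs <- colSums(cm)
  cs[cs == 0] <- 1
  out <- sweep(unclass(cm), 2L, cs, "/")
  out
}

#' Kendall's coefficient of concordance
#'
#' Agreement among `m` rankings of `n` items. Values are ranked within each
#' row with average ranks for ties; `W` uses the tie-corrected form
#' `W = 12 S / (m^2 (n^3 - n) - m sum(T))` where `S` is the sum of squared
#' deviations of the column rank sums from their mean and
#' `T = sum(t^3 - t)` over each row's tie groups. The p-value comes from the
#' chi-square approximation `chi2 = m (n - 1) W` on `n - 1` degrees of
#' freedom (see [concordance_pvalue()] and the vignette for its small-m
#' accuracy).
#'
#' @param rankings An `m x n` numeric matrix: `m` raters/methods/nights
#'   (rows) scoring `n` items (columns), e.g. time-budget seconds per
#'   behavior. Rows are converted to ranks internally.
#' @return A `concordance` list: `W`, `m`, `n`, `chi2`, `p`,
#'   `tie_corrected`.
#' @export
kendalls_w <- function(rankings) {
  rankings <- as.matrix(rankings)
  m <- nrow(rankings); n <- ncol(rankings)
  if (m < 2L) stop("need at least 2 rankings (rows)")
  if (n < 2L) stop("need at least 2 items (columns)")
  if (anyNA(rankings)) stop("rankings must not contain NA")
  rk <- t(apply(rankings, 1L, rank))        # average ranks for ties
  Rj <- colSums(rk)
  S <- sum((Rj - m * (n + 1) / 2)^2)
  Tsum <- sum(apply(rk, 1L, function(r) {
    t <- table(r); sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * Tsum
  if (denom <= 0) stop("degenerate rankings: all items tied in every row")
  W <- 12 * S / denom
  chi2 <- m * (n - 1) * W
  structure(list(W = W, m = m, n = n, chi2 = chi2,
                 p = stats::pchisq(chi2, df = n - 1, lower.tail = FALSE),
                 tie_corrected = Tsum > 0),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Kendall's W = %.4f (m = %d rankings, n = %d items)\n",
              x$W, x$m, x$n))
  cat(sprintf("chi-square = %.3f, df = %d, p = %.3g%s\n", x$chi2, x$n - 1,
              x$p, if (x$tie_corrected) "  [tie-corrected]" else ""))
  invisible(x)
}

#' Chi-square p-value for a concordance coefficient
#'
#' Upper-tail probability of `chi2 = m (n - 1) W` on `n - 1` degrees of
#' freedom: the standard large-sample approximation for testing W against
#' the null of independent rankings. For small `m` the approximation is
#' conservative in the significance tail (the exact permutation p-value is
#' smaller); see the vignette.
#'
#' @param W Concordance coefficient in \[0, 1\].
#' @param m Number of rankings.
#' @param n Number of ranked items.
#' @return The approximate p-value.
#' @export
concordance_pvalue <- function(W, m, n) {
  stopifnot(W >= 0, W <= 1, m >= 2, n >= 2)
  stats::pchisq(m * (n - 1) * W, df = n - 1, lower.tail = FALSE)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, via
#' `stats::cor(method = "spearman")`. Constant input has no defined rank
#' correlation and raises an error rather than returning `NA` silently.
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return The correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("inputs must not contain NA")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("Spearman correlation undefined for constant input")
  stats::cor(x, y, method = "spearman")
}

#' Pairwise night-to-night correlations
#'
#' Spearman correlations between aligned per-night activity series, e.g.
#' per-minute cumulative lying-down seconds: high correlations indicate a
#' shared circadian pattern (similar sleep onset), low or negative ones a
#' shifted pattern.
#'
#' @param curves Named list of equal-length numeric vectors, one per night
#'   (or per subject-night).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
pairwise_day_correlations <- function(curves) {
  if (length(curves) < 2L) stop("need at least 2 series")
  len <- lengths(curves)
  if (length(unique(len)) != 1L)
    stop("series are misaligned: lengths ", paste(unique(len), collapse = ", "))
  k <- length(curves)
  nm <- names(curves) %||% paste0("night", seq_len(k))
  out <- diag(1, k)
  dimnames(out) <- list(nm, nm)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    out[i, j] <- out[j, i] <- spearman_rho(curves[[i]], curves[[j]])
  }
  out
}

#' Per-minute cumulative series for one behavior
#'
#' Helper for night-to-night correlation: cumulative seconds of `behavior`
#' sampled at the end of each minute.
#'
#' @param seq A second-resolution [behavior_sequence()].
#' @param behavior Behavior label to accumulate.
#' @param step_s Sampling step in seconds (default 60: per minute).
#' @return Numeric vector of cumulative seconds at each sample point.
#' @export
cumulative_minutes <- function(seq, behavior, step_s = 60) {
  stopifnot(seq$resolution == "second", step_s >= 1)
  cs <- cumsum(seq$labels == behavior)
  idx <- seq(step_s, length(cs), by = step_s)
  cs[idx]
}
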