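# Shared fixtures and independent brute-force oracles.
# Oracles deliberately re-derive results with naive scalar code, separate
# from the package's vectorized implementations.

tiny_config <- function(zone_rules = NULL) {
  rules <- zone_rules %||% list(
    zone_rule("Eat", 1, data.frame(bodypart = "nose", x_min = 0, x_max = 100,
                                   y_min = 0, y_max = 100)),
    zone_rule("Drink", 2, data.frame(bodypart = "nose", x_min = 200,
                                     x_max = 300, y_min = 0, y_max = 100)))
  ethogram_config(
    behaviors = rbind(behavior("Stand", is_default = TRUE),
                      behavior("Eat"), behavior("Drink")),
    zone_rules = rules,
    bodyparts = c("head", "nose"),
    anchor_bodyparts = "head",
    fps = 5, p_cutoff = 0.5,
    frame_size = c(width = 400, height = 200),
    geometry = list(Stand = list(head = c(150, 150), nose = c(150, 170)),
                    Eat = list(head = c(60, 120), nose = c(50, 50)),
                    Drink = list(head = c(240, 120), nose = c(250, 50))))
}

random_track <- function(n = 50, bodyparts = c("head", "nose"), fps = 5,
                         na_frac = 0.1) {
  p <- length(bodyparts)
  x <- matrix(runif(n * p, 0, 400), n, p)
  y <- matrix(runif(n * p, 0, 200), n, p)
  lik <- matrix(runif(n * p), n, p)
  drop <- matrix(runif(n * p) < na_frac, n, p)
  x[drop] <- NA; y[drop] <- NA; lik[drop] <- NA
  keypoint_track(x, y, lik, bodyparts, fps)
}

# scalar re-derivation of the per-frame zone-rule semantics
oracle_classify_frame <- function(track, i, cfg, pc = cfg$p_cutoff) {
  valid <- function(p) {
    l <- track$likelihood[i, p]
    !is.na(track$x[i, p]) && !is.na(track$y[i, p]) && !is.na(l) && l >= pc
  }
  rules <- cfg$zone_rules[order(vapply(cfg$zone_rules, `[[`, 1L, "priority"))]
  for (r in rules) {
    ok <- TRUE
    for (k in seq_len(nrow(r$constraints))) {
      cs <- r$constraints[k, ]
      if (!valid(cs$bodypart) ||
          track$x[i, cs$bodypart] < cs$x_min ||
          track$x[i, cs$bodypart] > cs$x_max ||
          track$y[i, cs$bodypart] < cs$y_min ||
          track$y[i, cs$bodypart] > cs$y_max) { ok <- FALSE; break }
    }
    if (ok) return(r$behavior)
  }
  if (any(vapply(cfg$anchor_bodyparts, valid, TRUE)))
    default_behavior(cfg)
  else OUT_OF_VIEW
}

# naive Kendall's W: explicit rank sums and tie groups
oracle_kendall_w <- function(mat) {
  m <- nrow(mat); n <- ncol(mat)
  rk <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) rk[i, ] <- rank(mat[i, ])
  Rj <- numeric(n)
  for (j in seq_len(n)) Rj[j] <- sum(rk[, j])
  S <- sum((Rj - mean(Rj))^2)
  Tsum <- 0
  for (i in seq_len(m)) {
    for (t in as.integer(table(rk[i, ]))) Tsum <- Tsum + (t^3 - t)
  }
  12 * S / (m^2 * (n^3 - n) - m * Tsum)
}

# naive Spearman: rank both sides, then Pearson by the textbook formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# per-bout interval overlap (Jaccard) between two [start, end) intervals
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  inter / union
}

`%||%` <- function(a, b) if (is.null(a)) b else a
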