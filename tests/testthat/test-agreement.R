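mk_sec <- function(labels) behavior_sequence(labels, "second", 25)

test_that("time budgets count seconds and always total 100%", {
  cfg <- default_ethogram_config()
  b <- time_budget(mk_sec(rep("Standing", 25200)), cfg)
  expect_equal(b$percent[b$behavior == "Standing"], 100)
  expect_equal(sum(b$percent), 100)

  b2 <- time_budget(mk_sec(rep(c("Standing", "Lying down"), each = 50)), cfg)
  expect_equal(b2$percent[b2$behavior == "Standing"], 50)
  expect_equal(b2$percent[b2$behavior == "Lying down"], 50)

  # brute-force counting oracle on random sequences
  set.seed(21)
  for (rep in 1:5) {
    labs <- sample(label_set(cfg), 500, replace = TRUE)
    b3 <- time_budget(mk_sec(labs), cfg)
    for (i in seq_len(nrow(b3))) {
      cnt <- 0
      for (l in labs) if (l == b3$behavior[i]) cnt <- cnt + 1
      expect_equal(b3$seconds[i], cnt)
      expect_equal(b3$percent[i], 100 * cnt / 500)
    }
    expect_equal(sum(b3$percent), 100, tolerance = 1e-9)
  }
  expect_error(time_budget(mk_sec(character(0)), cfg), "empty")
})

test_that("cumulative curves are staircases conserving total time", {
  cfg <- default_ethogram_config()
  cc <- cumulative_curves(mk_sec(rep("Standing", 100)), cfg)
  expect_equal(cc[, "Standing"], 1:100)       # straight line to the total
  expect_equal(unname(cc[100, "Foraging"]), 0)  # absent: all-zero series

  alt <- cumulative_curves(mk_sec(rep(c("Standing", "Foraging"), 50)), cfg)
  expect_equal(unname(alt[100, "Standing"]), 50)
  expect_equal(unname(alt[100, "Foraging"]), 50)
  expect_equal(unname(alt[, "Standing"]), rep(1:50, each = 2))  # staircase

  set.seed(22)
  r <- cumulative_curves(mk_sec(sample(label_set(cfg), 300, TRUE)), cfg)
  expect_true(all(apply(r, 2, function(col) all(diff(col) >= 0))))
  expect_equal(sum(r[300, ]), 300)
})

test_that("confusion matrices cross-tabulate predicted rows against observed columns", {
  cfg <- default_ethogram_config()
  a <- mk_sec(rep(c("Standing", "Foraging"), 25))
  cm <- confusion_matrix(a, a, cfg)
  expect_equal(sum(diag(cm)), 50)
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  expect_equal(column_normalize(cm)["Standing", "Standing"], 1)

  # systematic mistake: drinking observed, standing predicted
  pred <- mk_sec(rep("Standing", 30))
  obs <- mk_sec(rep("Drinking", 30))
  cm2 <- confusion_matrix(pred, obs, cfg)
  expect_equal(unname(cm2["Standing", "Drinking"]), 30)
  expect_equal(sum(cm2), 30)
  expect_equal(column_normalize(cm2)["Standing", "Drinking"], 1)

  expect_error(confusion_matrix(mk_sec(rep("Standing", 5)),
                                mk_sec(rep("Standing", 6))),
               "differ in length")

  # brute-force pairwise counting oracle
  set.seed(23)
  p <- sample(label_set(cfg), 200, TRUE)
  o <- sample(label_set(cfg), 200, TRUE)
  cm3 <- confusion_matrix(mk_sec(p), mk_sec(o), cfg)
  for (i in label_set(cfg)) for (j in label_set(cfg)) {
    cnt <- 0
    for (k in 1:200) if (p[k] == i && o[k] == j) cnt <- cnt + 1
    expect_equal(unname(cm3[i, j]), cnt)
  }
  norm <- column_normalize(cm3)
  nonzero <- colSums(cm3) > 0
  expect_equal(unname(colSums(norm)[nonzero]),
               rep(1, sum(nonzero)), tolerance = 1e-12)
})

test_that("Kendall's W spans perfect agreement to perfect disagreement", {
  ident <- matrix(rep(c(10, 20, 30, 40), each = 3), 3, 4, byrow = FALSE)
  r <- kendalls_w(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(r$W, 1)
  expect_equal(r$chi2, 3 * 3 * 1)           # m (n-1) W
  # two exactly reversed rankings: rank sums all equal, W = 0
  r0 <- kendalls_w(rbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(r0$W, 0)
  expect_equal(r0$p, 1)
  expect_error(kendalls_w(matrix(1:3, 1)), "at least 2 rankings")
  expect_error(kendalls_w(matrix(1:2, 2, 1)), "at least 2 items")
  expect_error(kendalls_w(matrix(1, 3, 4)), "degenerate")
})

test_that("Kendall's W matches the naive oracle and vegan on random tables", {
  set.seed(24)
  for (rep in 1:30) {
    m <- sample(2:7, 1); n <- sample(3:8, 1)
    mat <- matrix(sample(0:5, m * n, replace = TRUE), m, n)  # with ties
    if (any(apply(mat, 1, function(r) length(unique(r))) == 1)) next
    r <- kendalls_w(mat)
    expect_equal(r$W, oracle_kendall_w(mat), tolerance = 1e-12)
    expect_gte(r$W, 0); expect_lte(r$W, 1)
    expect_equal(r$p, stats::pchisq(r$chi2, n - 1, lower.tail = FALSE))
  }
  # independent library cross-check (vegan ranks items in columns too)
  skip_if_not_installed("vegan")
  mat <- matrix(c(12, 45, 3, 27, 8, 60,
                  15, 40, 2, 30, 6, 55,
                  10, 50, 5, 20, 9, 58), 3, 6, byrow = TRUE)
  r <- kendalls_w(mat)
  v <- vegan::kendall.global(t(mat))
  expect_equal(r$W, unname(v$Concordance_analysis["W", 1]), tolerance = 1e-10)
  expect_equal(r$p, unname(v$Concordance_analysis["Prob.F", 1]),
               tolerance = 1) # only W is compared; vegan's p uses an F test
})

test_that("concordance p-values use the chi-square upper tail", {
  expect_equal(concordance_pvalue(1, 3, 4),
               stats::pchisq(9, 3, lower.tail = FALSE))
  expect_gt(concordance_pvalue(0.2, 3, 6), concordance_pvalue(0.9, 3, 6))
  expect_error(concordance_pvalue(1.2, 3, 6), "W")
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, rev(sort(x))[rank(x)]), -1)
  set.seed(25)
  for (rep in 1:20) {
    a <- rnorm(sample(3:12, 1))
    b <- rnorm(length(a))
    expect_equal(spearman_rho(a, b), oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:3, 1:4), "length")
})

test_that("pairwise night correlations form a symmetric unit-diagonal table", {
  set.seed(26)
  base <- cumsum(runif(120))
  cors <- pairwise_day_correlations(list(d1 = base, d2 = base,
                                         d3 = rev(base)))
  expect_equal(unname(cors["d1", "d2"]), 1)
  expect_equal(unname(cors["d1", "d3"]), -1)
  expect_equal(cors, t(cors))
  expect_equal(unname(diag(cors)), rep(1, 3))
  expect_error(pairwise_day_correlations(list(a = 1:5, b = 1:6)),
               "misaligned")
})

test_that("shared sleep onset correlates nights more than shifted onset", {
  cfg <- default_ethogram_config()
  lie <- function(onset_s) {
    bouts <- data.frame(behavior = "Lying down", start_s = onset_s,
                        duration_s = 9000)
    rasterize_script(simulation_script(bouts, 25200), cfg)
  }
  curves <- list(
    n1 = cumulative_minutes(lie(7200), "Lying down"),
    n2 = cumulative_minutes(lie(7500), "Lying down"),   # near-shared onset
    n3 = cumulative_minutes(lie(14400), "Lying down"))  # shifted onset
  cors <- pairwise_day_correlations(curves)
  expect_gt(cors["n1", "n2"], cors["n1", "n3"])
  expect_gt(cors["n1", "n2"], 0.9)
})

test_that("cumulative_minutes samples the running total on the minute grid", {
  seq <- mk_sec(rep(c("Lying down", "Standing"), each = 60))
  cm <- cumulative_minutes(seq, "Lying down")
  expect_equal(cm, c(60, 60))
})
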