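test_that("ROC handles separation, ties and the no-information limit", {
  r <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")

  # label-independent values: mean AUC near 1/2
  aucs <- vapply(1:50, function(seed) {
    set.seed(seed)
    roc_curve(stats::rnorm(2000), sample(c(TRUE, FALSE), 2000, TRUE))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)

  # tied values step simultaneously and AUC stays in [0, 1]
  rt <- roc_curve(c(1, 1, 2, 2), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(rt$auc, 0.5)
})

test_that("AUC equals the Mann-Whitney identity U / (n1 n2)", {
  set.seed(20)
  for (i in 1:100) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    pos <- round(stats::rnorm(n1, 1), sample(0:2, 1))   # rounding forces ties
    neg <- round(stats::rnorm(n2, 0), sample(0:2, 1))
    auc <- roc_curve(c(pos, neg), rep(c(TRUE, FALSE), c(n1, n2)))$auc
    u <- suppressWarnings(stats::wilcox.test(pos, neg))$statistic
    expect_equal(auc, unname(u) / (n1 * n2), tolerance = 1e-9)
  }
})

test_that("mean AUC over sampled cohorts matches the binormal closed form", {
  aucs <- vapply(1:500, function(seed) {
    co <- sample_cohort(seed = seed)
    roc_curve(co$stiffness_kpa, co$mutation != "wt")$auc
  }, numeric(1))
  binormal <- stats::pnorm((967 - 751) / sqrt(145^2 + 92^2))
  expect_lt(abs(mean(aucs) - binormal), 0.03)
})

test_that("ROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  v <- round(stats::rnorm(60, 800, 100))
  l <- stats::runif(60) < stats::plogis((v - 800) / 50)
  if (all(l) || !any(l)) l[1:2] <- c(TRUE, FALSE)
  ours <- roc_curve(v, l)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(response = l, predictor = v,
                                           quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("Youden threshold picks the gap midpoint and maximizes J", {
  y <- youden_threshold(roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)))
  expect_equal(y$threshold_kpa, 2.5)
  expect_equal(y$j, 1)

  expect_warning(
    yd <- youden_threshold(roc_curve(c(5, 5, 5, 5),
                                     c(TRUE, FALSE, TRUE, FALSE))),
    "degenerate")
  expect_equal(yd$threshold_kpa, 5)
  expect_equal(yd$j, 0)

  # brute-force oracle: J at the returned threshold equals the sweep maximum
  set.seed(22)
  for (i in 1:20) {
    v <- stats::rnorm(40, rep(c(0, 1), 20))
    l <- rep(c(FALSE, TRUE), 20)
    roc <- roc_curve(v, l)
    y <- youden_threshold(roc)
    j_at <- function(t) {
      m <- metrics_at_threshold(v, l, t)
      m$sensitivity + m$specificity - 1
    }
    best <- max(vapply(sort(unique(v)), j_at, numeric(1)))
    expect_equal(j_at(y$threshold_kpa), best, tolerance = 1e-12)
  }
})

test_that("median Youden threshold sits at the weighted density crossing", {
  th <- vapply(1:500, function(seed) {
    co <- sample_cohort(seed = seed)
    youden_threshold(roc_curve(co$stiffness_kpa,
                               co$mutation != "wt"))$threshold_kpa
  }, numeric(1))
  med <- stats::median(th)
  expect_gt(med, 751)
  expect_lt(med, 967)
  expect_lt(abs(med - density_crossing_threshold()), 80)
})

test_that("confusion metrics arithmetic matches the study's 91/80/85 pattern", {
  # 24 mutant (22 above / 2 below), 30 wild type (6 above / 24 below)
  v <- c(rep(900, 22), rep(700, 2), rep(900, 6), rep(700, 24))
  l <- rep(c(TRUE, FALSE), c(24, 30))
  m <- metrics_at_threshold(v, l, 803)
  expect_identical(c(m$tp, m$fn, m$tn, m$fp), c(22L, 2L, 24L, 6L))
  expect_equal(m$sensitivity, 22 / 24)
  expect_equal(m$specificity, 24 / 30)
  expect_equal(m$accuracy, 46 / 54)
  expect_identical(round(100 * c(m$sensitivity, m$specificity, m$accuracy)),
                   c(92, 80, 85))

  # degenerate cuts; the boundary value itself is called negative
  lo <- metrics_at_threshold(v, l, min(v) - 1)
  expect_equal(c(lo$sensitivity, lo$specificity), c(1, 0))
  hi <- metrics_at_threshold(v, l, max(v))
  expect_equal(c(hi$sensitivity, hi$specificity), c(0, 1))
})

test_that("raising the threshold never raises sensitivity nor lowers specificity", {
  set.seed(23)
  v <- stats::rnorm(80, rep(c(0, 1), 40)); l <- rep(c(FALSE, TRUE), 40)
  ths <- sort(unique(v))
  sens <- vapply(ths, function(t) metrics_at_threshold(v, l, t)$sensitivity,
                 numeric(1))
  spec <- vapply(ths, function(t) metrics_at_threshold(v, l, t)$specificity,
                 numeric(1))
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("morphological patterns as markers give the study baselines", {
  co <- sample_cohort(seed = 1)
  solid <- pattern_marker_metrics(co, "solid")
  expect_equal(solid$accuracy, 36 / 54)
  expect_identical(round(100 * solid$accuracy), 67)
  tub <- pattern_marker_metrics(co, "complex_tubular")
  expect_equal(tub$accuracy, 18 / 54)
  expect_identical(round(100 * tub$accuracy), 33)
  expect_error(pattern_marker_metrics(co[co$pattern != "mucinous", ],
                                      "mucinous"), "absent")

  # a cohort where pattern coincides with mutation is classified perfectly
  fake <- co
  fake$mutation <- ifelse(fake$pattern == "solid", "KRAS", "wt")
  expect_equal(pattern_marker_metrics(fake, "solid")$accuracy, 1)
})

test_that("stiffness at 803 kPa outperforms both pattern baselines", {
  wins <- vapply(1:200, function(seed) {
    co <- sample_cohort(seed = seed)
    acc <- metrics_at_threshold(co$stiffness_kpa, co$mutation != "wt",
                                803)$accuracy
    acc > 36 / 54 && acc > 18 / 54
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("heterogeneous cases are flagged by discordant threshold calls", {
  co <- sample_cohort(seed = 4)
  # pin the designated case to the stiffness values reported for it
  co$stiffness_kpa[co$case_id == 21 & co$pattern == "complex_tubular"] <- 937.7
  co$stiffness_kpa[co$case_id == 21 & co$pattern == "mucinous"] <- 840.8
  fl <- flag_heterogeneous_cases(co)
  r21 <- fl[fl$case_id == 21, ]
  expect_identical(r21$calls_kras, "pos,neg")
  expect_true(r21$discordant_kras)

  # concordant multi-ROI case
  co$stiffness_kpa[co$case_id == 1] <- 900
  fl2 <- flag_heterogeneous_cases(co)
  expect_false(fl2$discordant_kras[fl2$case_id == 1])
  expect_false(fl2$discordant_any_driver[fl2$case_id == 1])

  # single-ROI cases are not reported
  expect_true(all(fl$n_roi > 1))
  expect_false(40 %in% fl$case_id)
})
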