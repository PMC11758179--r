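test_that("Mann-Whitney AUC matches exhaustive pair counting", {
  s <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  l <- c(1, 1, 1, 0, 0, 0)
  expect_equal(auc_mann_whitney(s, l), 8 / 9)

  set.seed(42)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    scores <- round(rnorm(n), 1) # coarse rounding forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_mann_whitney(scores, labels),
                 oracle_auc_pairs(scores, labels))
  }
})

test_that("AUC degenerate cases and errors", {
  expect_equal(auc_mann_whitney(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(auc_mann_whitney(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_error(auc_mann_whitney(1:3, c(1, 1, 1)), "single-class")
  expect_error(auc_mann_whitney(c(1, NA, 3), c(1, 0, 1)), "NA")
})

test_that("AUC orientation flip is exactly complementary and monotone-invariant", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(8:40, 1)
    scores <- sample(round(rnorm(n), 1))
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    a <- auc_mann_whitney(scores, labels)
    expect_equal(a + auc_mann_whitney(scores, labels, "lower_is_positive"), 1)
    # strictly increasing transforms leave the AUC unchanged
    f <- sample(list(function(x) exp(x), function(x) x^3 + 2 * x,
                     function(x) atan(x), function(x) 2^x), 1)[[1]]
    expect_equal(auc_mann_whitney(f(scores), labels), a)
  }
})

test_that("DeLong interval: degenerate separation, shrink rate, pROC agreement", {
  ci <- delong_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(ci), c(1, 1))

  set.seed(99)
  width_at <- function(n) {
    d <- sqrt(2) * qnorm(0.8)
    s <- c(rnorm(n, d), rnorm(n))
    l <- rep(c(1, 0), each = n)
    ci <- delong_ci(s, l)
    ci[["high"]] - ci[["low"]]
  }
  w200 <- mean(replicate(20, width_at(200)))
  w800 <- mean(replicate(20, width_at(800)))
  expect_equal(w200 / w800, 2, tolerance = 0.15) # ~1/sqrt(n)

  # agreement with the reference DeLong implementation
  library(pROC)
  set.seed(5)
  for (i in 1:10) {
    s <- round(rnorm(60), 1)
    l <- rbinom(60, 1, 0.5)
    if (sum(l) < 2 || sum(1 - l) < 2) next
    r <- suppressMessages(pROC::roc(l, s, direction = "<", quiet = TRUE))
    ref <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
    ours <- delong_ci(s, l)
    expect_equal(unname(ours[["low"]]), max(0, ref[1]), tolerance = 1e-8)
    expect_equal(unname(ours[["high"]]), min(1, ref[3]), tolerance = 1e-8)
  }
})

test_that("ROC curve is a valid staircase with correct endpoints", {
  set.seed(3)
  s <- round(rnorm(30), 1)
  l <- rbinom(30, 1, 0.5)
  r <- roc_curve(s, l)
  expect_true(all(diff(r$sensitivity) <= 1e-12))
  expect_true(all(diff(r$specificity) >= -1e-12))
  expect_equal(r$sensitivity[1], 1)
  expect_equal(r$specificity[1], 0)
  expect_equal(r$sensitivity[length(r$sensitivity)], 0)
  expect_equal(r$specificity[length(r$specificity)], 1)
  expect_true(r$auc >= r$auc_ci[["low"]] && r$auc <= r$auc_ci[["high"]])
})

test_that("top-left threshold selection equals a brute-force scan", {
  # perfectly separated toy set: midpoint of 0.4 and 0.6
  r <- roc_curve(c(0.2, 0.4, 0.6, 0.8), c(0, 0, 1, 1))
  cut <- select_threshold_topleft(r)
  expect_equal(cut$threshold, 0.5)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)

  set.seed(21)
  for (i in 1:40) {
    n <- sample(10:40, 1)
    s <- sample(seq(0, 1, by = 1 / 7), n, replace = TRUE) # vote-like ties
    l <- rbinom(n, 1, 0.6)
    if (length(unique(l)) < 2 || length(unique(s)) < 2) next
    got <- select_threshold_topleft(roc_curve(s, l))
    want <- oracle_topleft_scan(s, l)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
  }
})

test_that("equal-distance threshold ties resolve toward higher specificity", {
  # sens/spec tradeoff symmetric around two cuts: (1,0.5) vs (0.5,1)
  s <- c(1, 2, 3, 4)
  l <- c(0, 1, 0, 1)
  got <- select_threshold_topleft(roc_curve(s, l))
  # d2 = 0.25 at both; the higher-specificity cut is between 3 and 4
  expect_equal(got$specificity, 1)
  expect_equal(got$threshold, 3.5)
})

test_that("published vote-score thresholds are midpoints of adjacent levels", {
  expect_equal(round(vote_level_midpoint(7, 4), 3), 0.643) # 9/14
  expect_equal(round(vote_level_midpoint(6, 3), 3), 0.583) # 7/12
  expect_equal(vote_level_midpoint(4, 2), 0.625)
  expect_equal(vote_level_midpoint(5, 2), 0.5)
})

test_that("confusion metrics: counts, Bayes override, trivial identities", {
  s <- c(0.1, 0.4, 0.6, 0.9)
  l <- c(0, 0, 1, 1)
  cm <- confusion_at(s, l, 0.5)
  expect_equal(cm$tp, 2); expect_equal(cm$tn, 2)
  expect_equal(cm$sensitivity, cm$tp / (cm$tp + cm$fn))
  expect_equal(cm$ppv, 1); expect_equal(cm$npv, 1)
  # with a supplied prevalence, sens=spec=1 still gives ppv=npv=1
  cm2 <- confusion_at(s, l, 0.5, prevalence_override = 0.3)
  expect_equal(cm2$ppv, 1); expect_equal(cm2$npv, 1)
  # equality classifies low
  cm3 <- confusion_at(s, l, 0.6)
  expect_equal(cm3$tp, 1); expect_equal(cm3$fn, 1)
  # Bayes formula against a hand computation
  cm4 <- confusion_at(s, l, 0.5, prevalence_override = 0.8)
  expect_equal(cm4$ppv, 1 * 0.8 / (1 * 0.8 + 0 * 0.2))
  expect_error(confusion_at(s, l, Inf), "finite")
})

test_that("tidy, glance and autoplot work on ROC results", {
  r <- roc_curve(c(0.2, 0.4, 0.6, 0.8), c(0, 0, 1, 1))
  td <- tidy(r)
  expect_named(td, c("threshold", "sensitivity", "specificity"))
  gl <- glance(r)
  expect_equal(gl$auc, 1)
  expect_s3_class(autoplot(r), "ggplot")
})
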