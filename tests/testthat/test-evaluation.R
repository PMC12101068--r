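# Diagnostic evaluation: confusion metrics, ROC/AUC, Youden threshold.

counts_to_vectors <- function(tp, fn, fp, tn) {
  list(calls = c(rep("WM", tp), rep("MZL", fn), rep("WM", fp), rep("MZL", tn)),
       truth = c(rep("WM", tp + fn), rep("MZL", fp + tn)))
}

test_that("confusion counts and proportions follow their definitions", {
  v <- counts_to_vectors(95, 2, 2, 8)
  m <- confusion(v$calls, v$truth)
  expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(95, 2, 2, 8))
  expect_equal(m$sensitivity, 95 / 97)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$ppv, 95 / 97)
  expect_equal(m$npv, 0.8)
  perfect <- confusion(c("WM", "MZL"), c("WM", "MZL"))
  expect_equal(c(perfect$sensitivity, perfect$specificity,
                 perfect$ppv, perfect$npv), rep(1, 4))
  expect_error(confusion("WM", c("WM", "MZL")), "mismatch")
  expect_error(confusion(character(), character()), "empty")
  und <- confusion(c("MZL", "MZL"), c("MZL", "MZL"))
  expect_true(is.na(und$sensitivity))
  expect_true("sensitivity_undefined" %in% und$flags)
})

test_that("PPV follows from sensitivity, specificity and prevalence", {
  set.seed(51)
  for (i in 1:20) {
    tp <- sample(0:50, 1); fn <- sample(0:20, 1)
    fp <- sample(0:20, 1); tn <- sample(0:50, 1)
    if (tp + fn == 0 || tn + fp == 0 || tp + fp == 0) next
    v <- counts_to_vectors(tp, fn, fp, tn)
    m <- confusion(v$calls, v$truth)
    pi <- m$prevalence
    expect_equal(m$ppv,
                 m$sensitivity * pi /
                   (m$sensitivity * pi + (1 - m$specificity) * (1 - pi)))
  }
})

test_that("ROC handles perfect separation and pure ties", {
  sep <- roc_curve(c(6, 6, 6, 0, 0), c("WM", "WM", "WM", "MZL", "MZL"),
                   max_total = 6)
  expect_equal(sep$auc, 1.0)
  ties <- roc_curve(rep(3, 10), rep(c("WM", "MZL"), 5), max_total = 6)
  expect_equal(ties$auc, 0.5)
  expect_error(roc_curve(1:3, rep("WM", 3)), "single-class")
})

test_that("trapezoidal AUC equals pairwise concordance on small cohorts", {
  r <- roc_curve(c(5, 4, 3, 2, 4), c("WM", "WM", "WM", "MZL", "MZL"),
                 max_total = 6)
  expect_equal(r$auc, concordance_auc(c(5, 4, 3, 2, 4),
                                      c("WM", "WM", "WM", "MZL", "MZL")))
  set.seed(52)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    truth <- sample(c("WM", "MZL"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- sample(0:7, n, replace = TRUE)
    r <- roc_curve(scores, truth, max_total = 7)
    expect_equal(r$auc, concordance_auc(scores, truth), tolerance = 1e-12)
  }
})

test_that("unachievable thresholds do not change the AUC", {
  set.seed(53)
  scores <- sample(0:6, 40, replace = TRUE)
  truth <- rep(c("WM", "MZL"), 20)
  expect_equal(roc_curve(scores, truth, max_total = 6)$auc,
               roc_curve(scores, truth, max_total = 25)$auc)
})

test_that("swapping class labels mirrors the AUC and swaps Se and Sp", {
  set.seed(54)
  scores <- sample(0:6, 30, replace = TRUE)
  truth <- sample(c("WM", "MZL"), 30, replace = TRUE, prob = c(.6, .4))
  truth[1:2] <- c("WM", "MZL")
  flipped <- ifelse(truth == "WM", "MZL", "WM")
  expect_equal(roc_curve(scores, flipped, max_total = 6)$auc,
               1 - roc_curve(scores, truth, max_total = 6)$auc)
  calls <- ifelse(scores >= 3, "WM", "MZL")
  m <- confusion(calls, truth)
  mf <- confusion(ifelse(calls == "WM", "MZL", "WM"), flipped)
  expect_equal(mf$sensitivity, m$specificity)
  expect_equal(mf$specificity, m$sensitivity)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  scores <- sample(0:7, 60, replace = TRUE)
  truth <- sample(c("WM", "MZL"), 60, replace = TRUE)
  truth[1:2] <- c("WM", "MZL")
  ours <- roc_curve(scores, truth, max_total = 7)$auc
  theirs <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(truth, scores, levels = c("MZL", "WM"),
                        direction = "<"))))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("Youden selection matches exhaustive maximisation and breaks ties upward", {
  # perfectly separated: every threshold 1..6 ties at J = 1; pick 6
  r <- roc_curve(c(6, 6, 0, 0), c("WM", "WM", "MZL", "MZL"), max_total = 6)
  expect_equal(youden_optimal(r)$threshold, 6L)
  expect_equal(youden_optimal(r)$j, 1.0)
  set.seed(56)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    truth <- c("WM", "MZL", sample(c("WM", "MZL"), n - 2, replace = TRUE))
    scores <- sample(0:6, n, replace = TRUE)
    r <- roc_curve(scores, truth, max_total = 6)
    # independent brute force over all thresholds
    js <- vapply(0:7, function(t) {
      mean(scores[truth == "WM"] >= t) + mean(scores[truth == "MZL"] < t) - 1
    }, numeric(1))
    best <- max(js)
    expect_equal(youden_optimal(r)$j, best)
    expect_equal(youden_optimal(r)$threshold, max((0:7)[js == best]))
  }
})
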