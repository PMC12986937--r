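# Anomaly scoring algebra, Youden threshold and evaluation metrics.

test_that("per-timepoint scores follow the closed form", {
  x <- matrix(c(0.2, -0.1, 0.4, 0), 2, 2)
  perfect <- list(x_hat = x, sigma = matrix(0, 2, 2))
  expect_equal(score_timepoints(perfect, x),
               matrix(1e-10, 2, 2))
  off <- list(x_hat = x + 0.1, sigma = matrix(0, 2, 2))
  expect_equal(score_timepoints(off, x), matrix(0.01 + 1e-10, 2, 2))
  # fixed error, increasing sigma: scores strictly decrease
  sig <- seq(-2, 2, length.out = 5)
  s <- vapply(sig, function(sg)
    score_timepoints(list(x_hat = x + 0.1,
                          sigma = matrix(sg, 2, 2)), x)[1, 1], numeric(1))
  expect_true(all(diff(s) < 0))
  expect_error(score_timepoints(list(x_hat = x, sigma = matrix(0, 1, 4)), x),
               "shape")
})

test_that("the sample score is the mean over leads and time", {
  expect_equal(score_sample(matrix(c(0, 0.2), 1, 2)), 0.1)
  expect_equal(score_sample(matrix(3.3, 4, 7)), 3.3)
  set.seed(31)
  m <- matrix(rexp(60), 3, 20)
  expect_equal(score_sample(m), sum(m) / 60, tolerance = 1e-12)
  expect_error(score_sample(numeric(0)), "empty")
})

test_that("min-max normalization maps endpoints and preserves ranking", {
  expect_equal(normalize_scores(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(32)
  s <- rnorm(40)
  n <- normalize_scores(s)
  expect_identical(order(n), order(s))
  expect_equal(range(n), c(0, 1))
  expect_warning(out <- normalize_scores(c(2, 2, 2)), "equal")
  expect_equal(out, rep(0.5, 3))
  expect_error(normalize_scores(1), "at least 2")
})

test_that("AUC is invariant under min-max normalization", {
  set.seed(33)
  for (i in 1:5) {
    s <- rnorm(100)
    l <- rbinom(100, 1, 0.4)
    if (length(unique(l)) < 2) next
    a1 <- evaluate_scores(s, l)$auc
    a2 <- evaluate_scores(normalize_scores(s), l)$auc
    expect_lt(abs(a1 - a2), 1e-9)
  }
})

test_that("Youden threshold equals an exhaustive scan", {
  scan_youden <- function(scores, labels) {
    # brute force over every candidate threshold
    cand <- c(-Inf, sort(unique(scores)), Inf)
    cand <- sort(unique(c(cand,
                          (head(sort(unique(scores)), -1) +
                           tail(sort(unique(scores)), -1)) / 2)))
    best <- -Inf; best_th <- NA
    for (th in rev(cand)) {
      tpr <- sum(scores >= th & labels == 1) / sum(labels == 1)
      tnr <- sum(scores < th & labels == 0) / sum(labels == 0)
      if (tpr + tnr - 1 > best) {
        best <- tpr + tnr - 1
        best_th <- th
      }
    }
    list(threshold = best_th, J = best)
  }
  # the spec'd example
  got <- youden_threshold(c(0.1, 0.35, 0.4, 0.8), c(0, 1, 0, 1))
  want <- scan_youden(c(0.1, 0.35, 0.4, 0.8), c(0, 1, 0, 1))
  expect_equal(got$J, want$J)
  set.seed(34)
  for (i in 1:40) {
    n <- sample(4:120, 1)
    s <- round(rnorm(n), 2)  # ties likely
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    got <- youden_threshold(s, l)
    want <- scan_youden(s, l)
    expect_equal(got$J, want$J, tolerance = 1e-12)
    # at the returned threshold, J is attained
    cm <- stae:::confusion_at(s, l, got$threshold)
    expect_equal(unname(cm["TP"] / (cm["TP"] + cm["FN"]) +
                        cm["TN"] / (cm["TN"] + cm["FP"]) - 1), got$J)
  }
})

test_that("perfect separation yields J = 1 with a threshold in the gap", {
  s <- c(0.1, 0.2, 0.3, 0.7, 0.8)
  l <- c(0, 0, 0, 1, 1)
  yt <- youden_threshold(s, l)
  expect_equal(yt$J, 1)
  expect_gt(yt$threshold, 0.3)
  expect_lt(yt$threshold, 0.7)
})

test_that("negating scores and flipping labels preserves the maximal J", {
  set.seed(35)
  for (i in 1:10) {
    s <- rnorm(60)
    l <- rbinom(60, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(youden_threshold(s, l)$J,
                 youden_threshold(-s, 1 - l)$J, tolerance = 1e-12)
  }
})

test_that("evaluation metrics follow the confusion-count definitions", {
  # scores/labels realizing TP=2, TN=1, FP=1, FN=0 at threshold 0.5
  rep <- evaluate_scores(c(0.9, 0.8, 0.7, 0.2), c(1, 1, 0, 0),
                         threshold = 0.5)
  expect_identical(unname(rep$confusion),
                   c(2L, 1L, 1L, 0L))  # TP TN FP FN
  expect_equal(rep$accuracy, 0.75)
  expect_equal(rep$precision, 2 / 3)
  expect_equal(rep$recall, 1)
  expect_equal(rep$f1, 0.8)
})

test_that("AUC matches the pairwise-comparison oracle and pROC", {
  pairwise_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
  }
  set.seed(36)
  for (i in 1:5) {
    n <- 200
    s <- round(rnorm(n), 1)  # heavy ties
    l <- rbinom(n, 1, 0.5)
    a <- evaluate_scores(s, l)$auc
    expect_lt(abs(a - pairwise_auc(s, l)), 1e-9)
    if (requireNamespace("pROC", quietly = TRUE))
      expect_lt(abs(a - as.numeric(pROC::auc(pROC::roc(l, s,
                                                       quiet = TRUE,
                                                       direction = "<")))),
                1e-9)
  }
  # perfectly ranked labels give AUC 1
  expect_equal(evaluate_scores(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
})

test_that("F1 is the harmonic mean of reported precision and recall", {
  set.seed(37)
  for (i in 1:10) {
    s <- rnorm(50)
    l <- rbinom(50, 1, 0.5)
    if (length(unique(l)) < 2) next
    rep <- evaluate_scores(s, l)
    if (rep$precision + rep$recall > 0)
      expect_equal(rep$f1, 2 * rep$precision * rep$recall /
                             (rep$precision + rep$recall))
  }
})

test_that("single-class label vectors are rejected", {
  expect_error(evaluate_scores(c(1, 2), c(1, 1)), "both classes")
  expect_error(youden_threshold(c(1, 2), c(0, 0)), "both classes")
})
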