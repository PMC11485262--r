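# pairwise Mann-Whitney oracle: fraction of positive-negative pairs with the
# positive ranked higher, ties counting one half
auroc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("AUROC equals the pairwise Mann-Whitney oracle", {
  bm <- binary_curve_metrics(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(bm$auroc, 0.75)                         # 3 of 4 ordered pairs
  # perfectly separated and degenerate-tie cases
  expect_equal(binary_curve_metrics(c(1, 2, 3, 4), c(0, 0, 1, 1))$auroc, 1)
  expect_equal(binary_curve_metrics(c(1, 2, 3, 4), c(0, 0, 1, 1))$aupr, 1)
  expect_equal(binary_curve_metrics(rep(0.3, 6), c(0, 1, 0, 1, 1, 0))$auroc,
               0.5)
  # random instances with heavy ties, exact agreement
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(5:50, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_identical(binary_curve_metrics(s, y)$auroc, auroc_pairwise(s, y))
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  for (seed in 1:10) {
    set.seed(seed)
    s <- runif(60); y <- rbinom(60, 1, 0.4)
    expect_equal(binary_curve_metrics(s, y)$auroc,
                 as.numeric(suppressMessages(pROC::auc(y, s,
                                                       direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("single-class inputs are undefined, not zero", {
  bm <- binary_curve_metrics(c(0.2, 0.8), c(1, 1))
  expect_true(is.na(bm$auroc) && is.na(bm$aupr))
})

test_that("macro, weighted and micro averaging behave as specified", {
  # two labels: AUROC 1.0 with 10 positives, 0.5 with 30 positives
  set.seed(1)
  n <- 80
  s1 <- c(runif(10, 0.8, 1), runif(70, 0, 0.5)); y1 <- c(rep(1, 10), rep(0, 70))
  s2 <- rep(0.4, n); y2 <- c(rep(1, 30), rep(0, 50))
  scores <- cbind(s1, s2); labels <- cbind(y1, y2)
  expect_equal(average_metrics(scores, labels, "macro", "auroc"), 0.75)
  expect_equal(average_metrics(scores, labels, "weighted", "auroc"), 0.625)
  # micro equals the curve on the pooled concatenation
  pooled <- binary_curve_metrics(as.numeric(scores), as.numeric(labels))
  expect_equal(average_metrics(scores, labels, "micro", "auroc"),
               pooled$auroc)
  expect_equal(average_metrics(scores, labels, "micro", "aupr"), pooled$aupr)
  # one label only: all three schemes reduce to the per-label value
  one <- binary_curve_metrics(s1, y1)$auroc
  for (sch in c("micro", "macro", "weighted"))
    expect_equal(average_metrics(cbind(s1), cbind(y1), sch, "auroc"), one)
  # weighted average is a convex combination of the per-label values
  for (seed in 1:10) {
    set.seed(seed)
    sc <- matrix(runif(3 * 40), 40, 3)
    lb <- matrix(rbinom(3 * 40, 1, 0.4), 40, 3)
    per <- sapply(1:3, function(j) binary_curve_metrics(sc[, j], lb[, j])$auroc)
    if (any(is.na(per))) next
    wavg <- average_metrics(sc, lb, "weighted", "auroc")
    expect_gte(wavg, min(per) - 1e-12)
    expect_lte(wavg, max(per) + 1e-12)
  }
})

test_that("confusion metrics reproduce the hand-computed table", {
  # TP=6, FP=1, TN=3, FN=0 at threshold 0.5
  scores <- c(rep(0.9, 6), 0.7, rep(0.2, 3))
  labels <- c(rep(1, 6), 0, rep(0, 3))
  cm <- confusion_metrics(scores, labels, 0.5)
  expect_equal(cm$tp, 6); expect_equal(cm$fp, 1)
  expect_equal(cm$tn, 3); expect_equal(cm$fn, 0)
  expect_equal(cm$mcc, (6 * 3 - 1 * 0) / sqrt(7 * 6 * 4 * 3),
               tolerance = 1e-10)
  expect_equal(round(cm$mcc, 4), 0.8018)
  perfect <- confusion_metrics(labels, labels, 0.5)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  inverted <- confusion_metrics(1 - labels, labels, 0.5)
  expect_equal(inverted$mcc, -1)
})

test_that("the variance bound sets the minimum positive count", {
  expect_identical(min_positive_samples(0.01), 25L)
  expect_identical(min_positive_samples(0.25), 1L)
  expect_identical(min_positive_samples(0.005), 50L)
  expect_error(min_positive_samples(0), "positive")
  expect_error(min_positive_samples(-1), "positive")
  # monotone non-increasing in the bound
  bounds <- sort(runif(20, 0.001, 0.25))
  counts <- sapply(bounds, min_positive_samples)
  expect_true(all(diff(counts) <= 0))
})

test_that("co-occurrence admission follows the positive-count floor", {
  set.seed(3)
  n <- 400
  labels <- matrix(0, n, 13, dimnames = list(NULL, diagnostic_labels()))
  probs_names <- diagnostic_labels()
  labels[, "DE"] <- 1
  labels[1:30, c("AD", "VD")] <- 1          # 30 joint positives: admitted
  labels[31:40, c("LBD", "PSY")] <- 1       # 10 joint positives: excluded
  labels[41:250, "AD"] <- 1
  probs <- matrix(runif(n * 13), n, 13,
                  dimnames = list(NULL, probs_names))
  # make AD&VD separable: the model scores both labels high on positives
  probs[1:30, c("AD", "VD")] <- runif(60, 0.8, 1)
  probs[-(1:30), c("AD", "VD")] <- runif((n - 30) * 2, 0, 0.6)
  rep1 <- cooccurrence_report(probs, labels)
  expect_true("AD&VD" %in% rep1$combination)
  expect_false("LBD&PSY" %in% rep1$combination)
  expect_equal(attr(rep1, "min_positive"), 25L)
  row <- rep1[rep1$combination == "AD&VD", ]
  expect_equal(row$n_pos, 30)
  expect_gt(row$auroc, 0.9)                 # planted signal recovered
  # unknown labels in the combination drop the subject from both classes
  labels2 <- labels; labels2[1:5, "VD"] <- NA
  rep2 <- cooccurrence_report(probs, labels2)
  expect_equal(rep2[rep2$combination == "AD&VD", "n_pos"], 25)
})

test_that("the missingness sweep masks groups and recovers the baseline", {
  fx <- fixture_checkpoint()
  x <- fx$test
  sw <- missingness_sweep(fx$ck, x,
                          list(noop = character(0), mri = "MRI",
                               core = c("NP tests", "FAQ")))
  base <- sw[sw$scenario == "baseline", ]
  noop <- sw[sw$scenario == "noop", ]
  expect_equal(noop$auroc, base$auroc)       # empty scenario == baseline
  # masking the signal-bearing cognitive/functional groups hurts DE sharply
  de_base <- base$auroc[base$label == "DE"]
  de_core <- sw$auroc[sw$scenario == "core" & sw$label == "DE"]
  expect_lt(de_core, de_base)
  expect_error(missingness_sweep(fx$ck, x, list(bad = "NoSuchGroup")),
               "unknown group")
})

test_that("clinician fusion is the mean of the rescaled scores", {
  expect_equal(augment_confidence(100, 1), 1)
  expect_equal(augment_confidence(80, 0.6), 0.7)
  expect_equal(augment_confidence(0, 0), 0)
  # symmetric in the rescaled arguments and idempotent at agreement
  c1 <- c(20, 55, 90); p1 <- c(0.9, 0.55, 0.2)
  expect_equal(augment_confidence(c1, p1),
               augment_confidence(100 * p1, c1 / 100))
  expect_equal(augment_confidence(100 * p1, p1), p1)
  expect_error(augment_confidence(120, 0.5), "0, 100")
})

test_that("the metric report stratifies by cohort metadata", {
  fx <- fixture_checkpoint()
  x <- fx$test
  pr <- predict_cohort(fx$ck, x)
  rep1 <- metric_report(pr$probs, x$labels, strata = x$strata)
  expect_equal(nrow(rep1$per_label), 13)
  expect_true(all(rep1$averages$value >= 0 & rep1$averages$value <= 1,
                  na.rm = TRUE))
  expect_true(any(grepl("^gender=", names(rep1$strata))))
  expect_true(any(grepl("^age_bin=", names(rep1$strata))))
})
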