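test_that("identity rows of the metric table are reproduced exactly", {
  # balanced half-right prediction: chance level
  m <- compute_metrics(confusion_counts(25, 25, 25, 25))
  expect_identical(m$acc, 0.5)
  expect_identical(m$mcc, 0)
  # no positive missed
  m <- compute_metrics(confusion_counts(tp = 10, tn = 5, fp = 3, fn = 0))
  expect_identical(m$sn, 1)
  # everything wrong
  m <- compute_metrics(confusion_counts(tp = 0, tn = 0, fp = 7, fn = 9))
  expect_identical(m$acc, 0)
  expect_identical(m$mcc, -1)
  # everything right
  m <- compute_metrics(confusion_counts(tp = 7, tn = 9, fp = 0, fn = 0))
  expect_identical(m$acc, 1)
  expect_identical(m$mcc, 1)
})

test_that("zero denominators give undefined sentinels except MCC which is 0", {
  m <- compute_metrics(confusion_counts(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(is.na(m$sn))
  expect_identical(m$sp, 1)
  expect_identical(m$mcc, 0)
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "zero")
})

test_that("Chou conversion is an exact bijection on random counts", {
  set.seed(31)
  for (rep in 1:1000) {
    cc <- confusion_counts(sample(0:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(0:50, 1))
    if (cc$tp + cc$tn + cc$fp + cc$fn == 0) next
    ch <- chou_counts(cc)
    expect_identical(chou_to_confusion(ch), cc)
    expect_lte(ch$y_plus_as_minus, ch$y_plus)
    expect_lte(ch$y_minus_as_plus, ch$y_minus)
  }
})

test_that("conventional and Chou metric formulations agree to 1e-12", {
  set.seed(37)
  for (rep in 1:1000) {
    cc <- confusion_counts(sample(0:60, 1), sample(0:60, 1),
                           sample(0:60, 1), sample(0:60, 1))
    if (cc$tp + cc$tn + cc$fp + cc$fn == 0) next
    conv <- compute_metrics(cc)
    chou <- metrics_chou(chou_counts(cc))
    for (f in c("sn", "sp", "acc", "mcc")) {
      a <- conv[[f]]
      b <- chou[[f]]
      if (is.na(a) || is.na(b)) next   # both-defined cases only
      expect_lt(abs(a - b), 1e-12)
    }
  }
})

test_that("adding one correct prediction never decreases accuracy", {
  set.seed(41)
  for (rep in 1:200) {
    cc <- confusion_counts(sample(0:20, 1), sample(0:20, 1),
                           sample(0:20, 1), sample(0:20, 1))
    if (cc$tp + cc$tn + cc$fp + cc$fn == 0) next
    acc0 <- compute_metrics(cc)$acc
    acc1 <- compute_metrics(confusion_counts(cc$tp + 1, cc$tn, cc$fp, cc$fn))$acc
    expect_gte(acc1, acc0)
  }
})

test_that("score curves reproduce the analytic limits", {
  perfect <- score_curves(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), positive = "1")
  expect_identical(perfect$auc, 1)
  expect_identical(perfect$aupr, 1)
  flat <- score_curves(c(1, 0, 1, 0), rep(0.5, 4), positive = "1")
  expect_identical(flat$auc, 0.5)
  mixed <- score_curves(c(1, 0, 1), c(0.9, 0.8, 0.3), positive = "1")
  expect_identical(mixed$auc, 0.5)
  expect_error(score_curves(c(1, 1), c(0.2, 0.4), positive = "1"), "both classes")
})

test_that("AUC equals the Mann-Whitney pair statistic and matches pROC", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), 2)   # ties included
    sc <- score_curves(ifelse(truth, "pos", "neg"), scores, positive = "pos")
    expect_equal(sc$auc, oracle_auc(truth, scores), tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    truth <- c(1, 1, 1, 0, 0, 1, 0, 0, 1, 0)
    scores <- c(0.9, 0.7, 0.65, 0.6, 0.4, 0.8, 0.3, 0.55, 0.2, 0.1)
    sc <- score_curves(truth, scores, positive = "1")
    ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE)))
    expect_equal(sc$auc, ref, tolerance = 1e-12)
  }
})

test_that("k-fold partitions cover every row once with near-equal folds", {
  tab <- tiny_sep_table[1:100, ]
  cv <- cross_validate(tab, 1, k = 5, config = forest_config(n_trees = 40, seed = 8))
  expect_identical(nrow(cv$predictions), 100L)
  expect_identical(sort(unique(cv$predictions$fold)), 1:5)
  expect_true(all(abs(table(cv$predictions$fold) - 20) <= 1))
  expect_identical(cv$metrics$n, 100)
  # pooled counts total the dataset size
  ct <- cv$counts
  expect_identical(ct$tp + ct$tn + ct$fp + ct$fn, 100L)
})

test_that("leave-one-out produces one single-row fold per observation", {
  tab <- tiny_sep_table[c(1:15, 106:120), ]
  cv <- cross_validate(tab, 1, k = "loo", config = forest_config(n_trees = 30, seed = 6))
  expect_identical(cv$k, 30L)
  expect_identical(nrow(cv$per_fold), 30L)
  expect_true(all(table(cv$predictions$fold) == 1))
})

test_that("an oversized k is rejected against the smallest class", {
  tab <- tiny_sep_table[c(1:3, 61:120), ]
  expect_error(cross_validate(tab, 1, k = 5), "smallest class")
})

test_that("cross-validation on the separable fixture is highly accurate", {
  cv <- cross_validate(tiny_sep_table, 1, k = 5, config = fast_config)
  expect_gte(cv$metrics$acc, 0.9)
  expect_gte(cv$metrics$auc, 0.95)
})
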