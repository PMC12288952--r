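test_that("confusion counting with the ties-are-positive rule", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(.9, .8, .1, .2), 0.5)
  expect_equal(as.list(cc), list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cc2 <- confusion_counts(c(1, 0), c(.4, .6), 0.5)
  expect_equal(as.list(cc2), list(TP = 0L, TN = 0L, FP = 1L, FN = 1L))
  # a probability exactly at the threshold is called positive
  cc3 <- confusion_counts(c(1, 0), c(.5, .5), 0.5)
  expect_equal(cc3$TP, 1L)
  expect_equal(cc3$FP, 1L)
  expect_error(confusion_counts(c(1, 0), c(.5)), "different lengths")
  expect_error(confusion_counts(integer(0), numeric(0)), "empty")
})

test_that("threshold metrics match hand-computed and oracle values", {
  perfect <- metrics_from_confusion(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  m <- metrics_from_confusion(list(TP = 3, FN = 1, TN = 2, FP = 2))
  expect_equal(m$accuracy, 0.625)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.5)
  o <- oracle_metrics(3, 2, 2, 1)
  expect_equal(m$mcc, o$mcc)
})

test_that("zero-denominator metrics are undefined with a reason, never 0", {
  m <- metrics_from_confusion(list(TP = 0, TN = 4, FP = 0, FN = 2))
  expect_true(is.na(m$mcc))
  expect_match(attr(m, "undefined")[["mcc"]], "margin is zero")
  m2 <- metrics_from_confusion(list(TP = 3, TN = 0, FP = 0, FN = 1))
  expect_true(is.na(m2$specificity))
  expect_match(attr(m2, "undefined")[["specificity"]], "no actual negatives")
})

test_that("all metrics agree with brute-force oracles on 500 random inputs", {
  withr::with_seed(123, {
    for (i in 1:500) {
      n <- sample(4:30, 1)
      truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
      prob <- round(runif(n), 2) # rounding forces frequent ties
      cc <- confusion_counts(truth, prob, 0.5)
      m <- metrics_from_confusion(cc)
      o <- oracle_metrics(cc$TP, cc$TN, cc$FP, cc$FN)
      expect_equal(m$accuracy, o$accuracy)
      expect_equal(m$sensitivity, o$sensitivity)
      expect_equal(m$specificity, o$specificity)
      expect_equal(m$mcc, o$mcc)
      expect_equal(as.numeric(auc_roc(truth, prob)), oracle_auc(truth, prob))
    }
  })
})

test_that("AUC matches an established independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(5, {
    for (i in 1:20) {
      truth <- c(rep(1, 8), rep(0, 12))
      prob <- round(runif(20), 1)
      ref <- suppressMessages(as.numeric(pROC::auc(truth, prob,
                                                   direction = "<", quiet = TRUE)))
      expect_equal(as.numeric(auc_roc(truth, prob)), ref)
    }
  })
})

test_that("AUC boundary conventions: separation, ties, single class", {
  expect_equal(as.numeric(auc_roc(c(1, 1, 0, 0), c(.9, .8, .2, .1))), 1)
  expect_equal(as.numeric(auc_roc(c(1, 0, 1, 0), rep(.5, 4))), 0.5)
  a <- auc_roc(c(1, 1), c(.2, .9))
  expect_true(is.na(a))
  expect_match(attr(a, "reason"), "one class")
})

test_that("metric symmetry laws hold under class relabeling and score transforms", {
  withr::with_seed(99, {
    for (i in 1:50) {
      n <- sample(6:40, 1)
      truth <- rbinom(n, 1, 0.5)
      if (length(unique(truth)) < 2) next
      prob <- runif(n)
      m <- metrics_from_confusion(confusion_counts(truth, prob, 0.5))
      # relabel classes and flip scores around the threshold
      m_swap <- metrics_from_confusion(confusion_counts(1 - truth,
                                                        1 - prob - 1e-9, 0.5))
      expect_equal(m_swap$accuracy, m$accuracy)
      expect_equal(m_swap$sensitivity, m$specificity)
      expect_equal(m_swap$specificity, m$sensitivity)
      expect_equal(m_swap$mcc, m$mcc, tolerance = 1e-12)
      # AUC: negation flips, monotone transform preserves
      a <- as.numeric(auc_roc(truth, prob))
      expect_equal(as.numeric(auc_roc(truth, -prob)), 1 - a)
      expect_equal(as.numeric(auc_roc(truth, exp(3 * prob))), a)
    }
  })
})

test_that("ROC points integrate to the rank AUC", {
  withr::with_seed(21, {
    truth <- rbinom(30, 1, 0.5)
    prob <- round(runif(30), 1)
    pts <- roc_points(truth, prob)
    trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
    expect_equal(trap, as.numeric(auc_roc(truth, prob)))
    expect_equal(pts$tpr[nrow(pts)], 1)
    expect_equal(pts$fpr[nrow(pts)], 1)
  })
})

test_that("normal-approximation CI matches the closed form", {
  ci <- confidence_interval(c(0.8, 0.9), level = 0.95)
  mu <- 0.85
  half <- stats::qnorm(0.975) * stats::sd(c(0.8, 0.9)) / sqrt(2)
  expect_equal(ci$mean, mu)
  expect_equal(ci$lower, mu - half)
  expect_equal(ci$upper, mu + half)
  cz <- confidence_interval(rep(0.7, 5))
  expect_equal(cz$lower, 0.7)
  expect_equal(cz$upper, 0.7)
  expect_error(confidence_interval(0.5), "at least 2")
})

test_that("bootstrap CI is seeded and reproducible", {
  x <- c(0.71, 0.78, 0.83, 0.69, 0.90)
  a <- confidence_interval(x, method = "bootstrap", seed = 7)
  b <- confidence_interval(x, method = "bootstrap", seed = 7)
  expect_identical(a, b)
  expect_lte(a$lower, a$mean)
  expect_gte(a$upper, a$mean)
})

test_that("aggregation is the unweighted mean with undefined entries disclosed", {
  reports <- dplyr::bind_rows(
    evaluate_predictions(c(1, 1, 0, 0), c(.9, .8, .1, .2), scope = "chr1"),
    evaluate_predictions(c(1, 0, 1, 0), c(.9, .4, .6, .2), scope = "chr2"),
    evaluate_predictions(c(1, 1, 0, 0), c(.6, .9, .4, .1), scope = "chr3"))
  agg <- aggregate_metrics(reports)
  expect_equal(agg$mean[agg$metric == "accuracy"], mean(reports$accuracy))
  expect_equal(agg$n_used[agg$metric == "auc"], 3L)
  # one undefined AUC is excluded, not zero-imputed
  reports$auc[2] <- NA
  agg2 <- aggregate_metrics(reports)
  expect_equal(agg2$mean[agg2$metric == "auc"],
               mean(reports$auc, na.rm = TRUE))
  expect_equal(agg2$n_undefined[agg2$metric == "auc"], 1L)
  expect_equal(aggregate_metrics(tibble::tibble(accuracy = c(0.8, 0.9, 1.0),
                                                sensitivity = NA_real_,
                                                specificity = NA_real_,
                                                mcc = NA_real_, auc = NA_real_))$mean[1],
               0.9)
})
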