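#' Confusion counts at a decision threshold
#'
#' Thresholds predicted probabilities into hard calls (a probability exactly
#' at the threshold counts as a positive call — the documented tie rule) and
#' tallies the four confusion-matrix cells.
#'
#' @param truth Binary vector of true labels (0/1).
#' @param prob Predicted probabilities, same length.
#' @param threshold Decision threshold in (0, 1); default 0.5.
#' @return One-row tibble with integer columns `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, prob, threshold = 0.5) {
  if (length(truth) != length(prob)) {
    stop("truth and prob have different lengths (", length(truth), " vs ",
         length(prob), ")", call. = FALSE)
  }
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  truth <- as.integer(truth)
  if (!all(truth %in% c(0L, 1L))) stop("truth must be 0/1", call. = FALSE)
  call_pos <- prob >= threshold
  tibble::tibble(
    TP = sum(call_pos & truth == 1L),
    TN = sum(!call_pos & truth == 0L),
    FP = sum(call_pos & truth == 0L),
    FN = sum(!call_pos & truth == 1L)
  )
}

#' Threshold metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA` with the reason
#' recorded in the `"undefined"` attribute (a named character vector) —
#' never silently coerced to 0.
#'
#' @param counts A one-row tibble/list with `TP`, `TN`, `FP`, `FN`.
#' @return One-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `mcc`, `n`; attribute `"undefined"` names any metric
#'   that could not be computed and why.
#' @export
metrics_from_confusion <- function(counts) {
  TP <- as.numeric(counts$TP); TN <- as.numeric(counts$TN)
  FP <- as.numeric(counts$FP); FN <- as.numeric(counts$FN)
  n <- TP + TN + FP + FN
  undefined <- character(0)

  acc <- if (n > 0) (TP + TN) / n else NA_real_
  sens <- if (TP + FN > 0) TP / (TP + FN) else {
    undefined["sensitivity"] <- "no true positives or false negatives (no actual positives)"
    NA_real_
  }
  spec <- if (TN + FP > 0) TN / (TN + FP) else {
    undefined["specificity"] <- "no true negatives or false positives (no actual negatives)"
    NA_real_
  }
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom > 0) (TP * TN - FP * FN) / sqrt(denom) else {
    undefined["mcc"] <- "a confusion-matrix margin is zero"
    NA_real_
  }
  out <- tibble::tibble(accuracy = acc, sensitivity = sens,
                        specificity = spec, mcc = mcc, n = as.integer(n))
  attr(out, "undefined") <- undefined
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with midrank tie correction, which
#' equals the trapezoidal integral of the ROC curve on finite samples: the
#' probability that a randomly chosen positive outscores a randomly chosen
#' negative, counting ties as one half. Invariant under any strictly
#' increasing transform of the scores. With a single class present the AUC
#' is undefined and returned as `NA` with a `"reason"` attribute.
#'
#' @inheritParams confusion_counts
#' @return A number in `[0, 1]`, or `NA` with attribute `"reason"`.
#' @export
auc_roc <- function(truth, prob) {
  if (length(truth) != length(prob)) {
    stop("truth and prob have different lengths", call. = FALSE)
  }
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0 || n0 == 0) {
    out <- NA_real_
    attr(out, "reason") <- "AUC undefined: only one class present"
    return(out)
  }
  r <- rank(prob, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' False-positive and true-positive rates at every distinct score cut,
#' suitable for plotting or CSV export.
#'
#' @inheritParams confusion_counts
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, ordered from the
#'   all-negative to the all-positive call.
#' @export
roc_points <- function(truth, prob) {
  truth <- as.integer(truth)
  ord <- order(prob, decreasing = TRUE)
  truth <- truth[ord]; prob <- prob[ord]
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  keep <- !duplicated(prob, fromLast = TRUE) # last index of each distinct score
  tibble::tibble(
    threshold = c(Inf, prob[keep]),
    tpr = c(0, cumsum(truth == 1L)[keep] / max(n1, 1)),
    fpr = c(0, cumsum(truth == 0L)[keep] / max(n0, 1))
  )
}

#' Confidence interval for a series of metric values
#'
#' Default is the normal approximation `mean +/- z * sd / sqrt(n)` with `z`
#' the standard normal quantile at `(1 + level) / 2` and `sd` the sample
#' standard deviation (n - 1 denominator). `method = "bootstrap"` gives a
#' seeded percentile bootstrap of the mean instead.
#'
#' @param values Numeric series of at least 2 values (e.g. a metric across
#'   folds, chromosomes, or replicates).
#' @param level Confidence level in (0, 1); default 0.95.
#' @param method `"normal"` or `"bootstrap"`.
#' @param n_boot Bootstrap draws.
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `mean`, `lower`, `upper`, `level`, `n`, `method`.
#' @export
confidence_interval <- function(values, level = 0.95,
                                method = c("normal", "bootstrap"),
                                n_boot = 2000, seed = 1) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop("need at least 2 values for a confidence interval", call. = FALSE)
  }
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)", call. = FALSE)
  mu <- mean(values)
  if (method == "normal") {
    z <- stats::qnorm((1 + level) / 2)
    half <- z * stats::sd(values) / sqrt(length(values))
    lo <- mu - half; hi <- mu + half
  } else {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        mean(sample(values, replace = TRUE))
      }, numeric(1))
    })
    qs <- stats::quantile(boots, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble::tibble(mean = mu, lower = lo, upper = hi, level = level,
                 n = length(values), method = method)
}

#' Full threshold + ranking metric report for one prediction set
#'
#' Convenience wrapper producing the standard report row: confusion-derived
#' metrics at the given threshold plus AUC-ROC, tagged with a free-text
#' `scope` (fold, chromosome, or replicate identity).
#'
#' @inheritParams confusion_counts
#' @param scope Free-text identity of what was evaluated.
#' @return One-row tibble: `scope`, `accuracy`, `sensitivity`,
#'   `specificity`, `mcc`, `auc`, `n`, and the raw `TP`/`TN`/`FP`/`FN`.
#' @export
evaluate_predictions <- function(truth, prob, threshold = 0.5, scope = "all") {
  cc <- confusion_counts(truth, prob, threshold)
  m <- metrics_from_confusion(cc)
  auc <- suppressWarnings(as.numeric(auc_roc(truth, prob)))
  dplyr::bind_cols(tibble::tibble(scope = scope), m["accuracy"],
                   m["sensitivity"], m["specificity"], m["mcc"],
                   tibble::tibble(auc = auc), m["n"], cc)
}

#' Aggregate metric reports across folds, chromosomes, or replicates
#'
#' The summary statistic is the unweighted arithmetic mean of each metric
#' across reports (the convention for LOCO: average the per-chromosome test
#' metrics), with a confidence interval computed from the cross-report
#' series. Undefined (`NA`) entries are excluded from the mean and their
#' count disclosed — they are never imputed as zero.
#'
#' @param reports Tibble of per-unit report rows as produced by
#'   [evaluate_predictions()] (one row per fold/chromosome/replicate).
#' @param metrics Which metric columns to aggregate.
#' @param level Confidence level.
#' @param method CI method, see [confidence_interval()].
#' @return Long tibble: `metric`, `mean`, `lower`, `upper`, `n_used`,
#'   `n_undefined`.
#' @export
aggregate_metrics <- function(reports,
                              metrics = c("accuracy", "sensitivity",
                                          "specificity", "mcc", "auc"),
                              level = 0.95, method = "normal") {
  if (nrow(reports) == 0) stop("no reports to aggregate", call. = FALSE)
  purrr::map_dfr(metrics, function(m) {
    vals <- reports[[m]]
    ok <- vals[!is.na(vals)]
    if (length(ok) == 0) {
      return(tibble::tibble(metric = m, mean = NA_real_, lower = NA_real_,
                            upper = NA_real_, n_used = 0L,
                            n_undefined = length(vals)))
    }
    if (length(ok) >= 2) {
      ci <- confidence_interval(ok, level = level, method = method)
      tibble::tibble(metric = m, mean = ci$mean, lower = ci$lower,
                     upper = ci$upper, n_used = length(ok),
                     n_undefined = sum(is.na(vals)))
    } else {
      tibble::tibble(metric = m, mean = ok, lower = NA_real_, upper = NA_real_,
                     n_used = 1L, n_undefined = sum(is.na(vals)))
    }
  })
}
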