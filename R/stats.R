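# Evaluation statistics: ROC/AUC, sensitivity/specificity/F1, percentile
# bootstrap confidence intervals, DeLong and McNemar tests, ordinal
# operating points, reader-study arithmetic.

check_binary_labels <- function(labels) {
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be coded {0, 1}")
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  as.integer(labels)
}

#' Area under the ROC curve
#'
#' Concordant-pair probability (Mann-Whitney form): the probability a random
#' positive scores above a random negative, with 0.5 credit for ties.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores)                      # midranks give 0.5 tie credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity, specificity and F1 from binary predictions
#'
#' Degenerate denominators yield `NA` (undefined), not 0.
#'
#' @param predictions 0/1 predicted labels.
#' @param labels 0/1 truth.
#' @return named list: `sensitivity`, `specificity`, `precision`, `f1`,
#'   `accuracy` and the confusion counts.
#' @export
sens_spec_f1 <- function(predictions, labels) {
  labels <- check_binary_labels(labels)
  if (!all(predictions %in% c(0L, 1L))) stopf("predictions must be coded {0, 1}")
  stopifnot(length(predictions) == length(labels))
  tp <- sum(predictions == 1L & labels == 1L)
  fn <- sum(predictions == 0L & labels == 1L)
  tn <- sum(predictions == 0L & labels == 0L)
  fp <- sum(predictions == 1L & labels == 0L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
       accuracy = (tp + tn) / length(labels),
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

#' Percentile bootstrap confidence interval
#'
#' Nonparametric bootstrap at the record (lesion) level: `B` resamples with
#' replacement, percentile interval. Resamples on which the statistic is
#' undefined (error or non-finite, e.g. a single-class resample for an AUC)
#' are redrawn, up to `max_redraws` in total.
#'
#' @param statistic_fn function of one resampled data object.
#' @param data vector or data.frame (rows are resampled).
#' @param B number of bootstrap resamples.
#' @param level confidence level.
#' @param seed optional integer seed.
#' @param max_redraws cap on redraws of degenerate resamples.
#' @return object of class `metric_result`: `point` (statistic on the full
#'   data), `lower`, `upper`, `B`, `level`, `redraws`.
#' @export
bootstrap_ci <- function(statistic_fn, data, B = 1000L, level = 0.95,
                         seed = NULL, max_redraws = 10L * B) {
  stopifnot(B >= 2L)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 1L) stopf("empty data")
  take <- function(idx) if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
  point <- statistic_fn(data)
  with_seed_or_stream(seed, {
    stats <- numeric(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        v <- tryCatch(statistic_fn(take(sample.int(n, n, replace = TRUE))),
                      error = function(e) NA_real_)
        if (length(v) == 1L && is.finite(v)) break
        redraws <- redraws + 1L
        if (redraws > max_redraws)
          stopf("statistic undefined on too many bootstrap resamples")
      }
      stats[b] <- v
    }
    q <- stats::quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE)
    structure(list(point = point, lower = q[1L], upper = q[2L],
                   B = as.integer(B), level = level, redraws = redraws),
              class = "metric_result")
  })
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%.4f (%g%% CI %.4f-%.4f, B = %d)\n",
              x$point, 100 * x$level, x$lower, x$upper, x$B))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors on the same cases using the
#' structural-components variance estimator with a two-sided normal
#' reference. Identical score vectors give a zero difference and p = 1.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels 0/1 labels.
#' @return list: `auc_a`, `auc_b`, `delta` (a - b), `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  auc_a <- roc_auc(scores_a, labels)
  auc_b <- roc_auc(scores_b, labels)
  if (isTRUE(all.equal(scores_a, scores_b)))
    return(list(auc_a = auc_a, auc_b = auc_b, delta = 0, p = 1))
  ra <- pROC::roc(labels, scores_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, scores_b, quiet = TRUE, direction = "<")
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  p <- as.numeric(tst$p.value)
  if (!is.finite(p)) p <- 1
  list(auc_a = auc_a, auc_b = auc_b, delta = auc_a - auc_b, p = p)
}

#' McNemar test on paired correct/incorrect decisions
#'
#' Builds the discordant counts `b` (condition A correct only) and `c`
#' (condition B correct only). Uses the exact two-sided binomial test when
#' `b + c < 25` and the continuity-corrected chi-square otherwise. All
#' concordant pairs (`b = c = 0`) give p = 1, flagged degenerate.
#'
#' @param correct_a,correct_b logical (or 0/1) vectors: whether each paired
#'   decision was correct under condition A / B.
#' @return list: `b`, `c`, `p`, `method`.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b), length(correct_a) > 0L)
  correct_a <- as.logical(correct_a)
  correct_b <- as.logical(correct_b)
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0L)
    return(list(b = b, c = cc, p = 1, method = "degenerate (no discordant pairs)"))
  if (b + cc < 25L) {
    p <- stats::binom.test(min(b, cc), b + cc, p = 0.5)$p.value
    method <- "exact binomial"
  } else {
    tab <- matrix(c(sum(correct_a & correct_b), b, cc,
                    sum(!correct_a & !correct_b)), 2L, 2L)
    p <- stats::mcnemar.test(tab, correct = TRUE)$p.value
    method <- "chi-square with continuity correction"
  }
  list(b = b, c = cc, p = min(p, 1), method = method)
}

GRADE_ORD <- stats::setNames(seq_along(GRADE_LEVELS), GRADE_LEVELS)

#' Binarize ordinal ratings at the three operating points
#'
#' Converts 5-level ordinal ratings (3, 4a, 4b, 4c, 5) into the three
#' standard positive calls: `4a+` (rating >= 4a), `4b+`, `4c+`.
#'
#' @param ratings character vector of ratings.
#' @return integer matrix with columns `4a+`, `4b+`, `4c+`.
#' @export
birads_operating_points <- function(ratings) {
  ratings <- as.character(ratings)
  bad <- setdiff(ratings, GRADE_LEVELS)
  if (length(bad)) stopf("unknown rating symbol(s): %s", paste(unique(bad), collapse = ", "))
  v <- GRADE_ORD[ratings]
  out <- cbind(`4a+` = as.integer(v >= GRADE_ORD["4a"]),
               `4b+` = as.integer(v >= GRADE_ORD["4b"]),
               `4c+` = as.integer(v >= GRADE_ORD["4c"]))
  rownames(out) <- NULL
  out
}

#' Reader accuracy increment
#'
#' Mean accuracy with AI assistance minus mean accuracy solo, rounded half
#' up to one decimal (the convention of printed reader-study tables). For
#' the ordinal-rating mode the inputs are the three operating-point
#' accuracies; for the forced benign/malignant mode a single accuracy each.
#'
#' @param solo_accuracies,ai_accuracies accuracy percentages, equal length.
#' @return increment in percentage points (one decimal).
#' @export
reader_increment <- function(solo_accuracies, ai_accuracies) {
  if (length(solo_accuracies) != length(ai_accuracies))
    stopf("solo and AI accuracy lists must have equal length")
  round_half_up(mean(ai_accuracies) - mean(solo_accuracies), 1)
}

#' Biopsy rate from ordinal ratings
#'
#' Fraction of lesions rated at or above the biopsy-recommendation cut
#' (4a+), as a percentage rounded half up to one decimal.
#'
#' @param ratings character ratings.
#' @return percentage.
#' @export
biopsy_rate <- function(ratings) {
  if (!length(ratings)) stopf("empty ratings")
  pos <- birads_operating_points(ratings)[, "4a+"]
  round_half_up(100 * mean(pos), 1)
}

#' Category percentages of a cohort table
#'
#' Percentage of lesions in each ordinal category, rounded half up to one
#' decimal — the arithmetic used in cohort-characteristics tables.
#'
#' @param counts named integer vector of category counts.
#' @return named percentages.
#' @export
cohort_percentages <- function(counts) {
  round_half_up(100 * counts / sum(counts), 1)
}
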