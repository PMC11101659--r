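# Model-level evaluation: held-out metrics with bootstrap CIs, the
# modality-perturbation ablation, and reader-study summaries.

#' Evaluate a fitted model on a dataset split
#'
#' Scores every lesion of the split, computes AUC with a lesion-level
#' percentile-bootstrap confidence interval, and binary metrics at the
#' decision threshold.
#'
#' @param model a fitted `mupnet`.
#' @param dataset a `lesion_dataset`.
#' @param split which split to evaluate (`NULL` scores all lesions).
#' @param B bootstrap resamples for the AUC CI (0 suppresses the CI).
#' @param threshold probability threshold for binary metrics; `"youden"`
#'   picks the Youden-optimal threshold on this data.
#' @param seed seed for the bootstrap.
#' @return list: `auc` (a `metric_result` when `B > 0`), `threshold`,
#'   `metrics` (see [sens_spec_f1()]), `predictions` data frame.
#' @export
evaluate_model <- function(model, dataset, split = "test", B = 1000L,
                           threshold = model$config$threshold, seed = NULL) {
  ds <- if (is.null(split)) dataset else dataset_split(dataset, split)
  pred <- predict(model, ds)
  pred$label <- ds$manifest$label
  auc <- roc_auc(pred$p_malignant, pred$label)
  ci <- NULL
  if (B > 0L)
    ci <- bootstrap_ci(function(d) roc_auc(d$p_malignant, d$label),
                       pred, B = B, seed = seed)
  if (identical(threshold, "youden")) threshold <- youden_threshold(pred$p_malignant, pred$label)
  metrics <- sens_spec_f1(as.integer(pred$p_malignant >= threshold), pred$label)
  list(auc = auc, auc_ci = ci, threshold = threshold, metrics = metrics,
       predictions = pred, n = nrow(pred))
}

#' Youden-optimal probability threshold
#'
#' @param scores probabilities.
#' @param labels 0/1 labels.
#' @return the candidate threshold maximising sensitivity + specificity - 1.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    p <- as.integer(scores >= t)
    m <- sens_spec_f1(p, labels)
    s <- m$sensitivity + m$specificity - 1
    if (is.na(s)) -Inf else s
  }, numeric(1))
  cand[which.max(j)]
}

# Replace one modality image of a sample according to the ablation strategy.
perturb_modality <- function(sample, m, strategy, opposite_pool) {
  img <- sample$images[[m]]
  if (strategy == "noise") {
    mu <- mean(img); sdv <- stats::sd(img)
    repl <- array(stats::rnorm(length(img), mu, sdv), dim = dim(img))
    sample$images[[m]] <- clip01(repl)
  } else if (strategy == "swap") {
    donor <- opposite_pool[[sample.int(length(opposite_pool), 1L)]]
    sample$images[[m]] <- donor
  } else stopf("unknown ablation strategy '%s'", strategy)
  sample
}

#' Modality-perturbation ablation
#'
#' Measures the dependence of the model on one modality: for each ratio, a
#' random fraction of test lesions has that modality's image replaced —
#' either by Gaussian noise matched to the image's intensity statistics, or
#' by the same modality image of a randomly drawn lesion of the opposite
#' class — and the metrics are recomputed.
#'
#' @param model a fitted `mupnet`.
#' @param dataset a `lesion_dataset`.
#' @param modality_name modality to perturb.
#' @param ratios fractions of lesions perturbed.
#' @param strategy `"noise"` or `"swap"`.
#' @param split evaluated split.
#' @param threshold binary decision threshold.
#' @param seed seed controlling lesion selection and replacements.
#' @return data.frame: ratio, auc, sensitivity, specificity, n_perturbed.
#' @export
modality_ablation <- function(model, dataset, modality_name,
                              ratios = c(0, 0.25, 0.5, 0.75, 1),
                              strategy = c("noise", "swap"), split = "test",
                              threshold = model$config$threshold, seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(all(ratios >= 0 & ratios <= 1))
  ds <- dataset_split(dataset, split)
  m <- match(modality_name, names(ds$samples[[1L]]$images))
  if (is.na(m)) stopf("unknown modality '%s'", modality_name)
  n <- length(ds$samples)
  labels <- ds$manifest$label
  with_seed_or_stream(seed, {
    rows <- lapply(ratios, function(ratio) {
      k <- round(ratio * n)
      idx <- if (k > 0) sample.int(n, k) else integer(0)
      p <- numeric(n)
      for (i in seq_len(n)) {
        s <- ds$samples[[i]]
        if (i %in% idx) {
          pool <- lapply(which(labels != labels[i]),
                         function(j) ds$samples[[j]]$images[[m]])
          s <- perturb_modality(s, m, strategy, pool)
        }
        p[i] <- model_forward(model, s)$cls$p_malignant
      }
      mt <- sens_spec_f1(as.integer(p >= threshold), labels)
      data.frame(ratio = ratio, auc = roc_auc(p, labels),
                 sensitivity = mt$sensitivity, specificity = mt$specificity,
                 n_perturbed = k)
    })
    do.call(rbind, rows)
  })
}

#' Read a reader-decision table
#'
#' CSV with one row per (reader, lesion, phase): columns `reader_id`,
#' `lesion_id`, `phase` (`solo` or `ai`), `birads_rating` (3, 4a, 4b, 4c,
#' 5), `bm_preference` (`B` or `M`) and `label` (0/1 ground truth).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_reader_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(birads_rating = "character"))
  need <- c("reader_id", "lesion_id", "phase", "birads_rating",
            "bm_preference", "label")
  if (!all(need %in% names(tab)))
    stopf("reader table lacks column(s): %s", paste(setdiff(need, names(tab)), collapse = ", "))
  if (!all(tab$phase %in% c("solo", "ai"))) stopf("phase must be 'solo' or 'ai'")
  if (!all(tab$bm_preference %in% c("B", "M"))) stopf("bm_preference must be 'B' or 'M'")
  if (anyDuplicated(tab[, c("reader_id", "lesion_id", "phase")]))
    stopf("duplicate (reader, lesion, phase) rows")
  invisible(birads_operating_points(tab$birads_rating))  # validates ratings
  tab
}

#' Per-reader reader-study summary
#'
#' For each reader: accuracy at the three ordinal operating points and in
#' the forced benign/malignant mode, solo and AI-assisted; the accuracy
#' increments; biopsy rates; and a McNemar comparison of the solo versus
#' AI-assisted benign/malignant decisions.
#'
#' @param table a reader-decision table (see [read_reader_table()]).
#' @return data.frame, one row per reader.
#' @export
reader_study_metrics <- function(table) {
  acc_pct <- function(pred, lab) round_half_up(100 * mean(pred == lab), 1)
  out <- lapply(split(table, table$reader_id), function(tr) {
    ph <- split(tr, tr$phase)
    ph <- lapply(ph, function(d) d[order(d$lesion_id), , drop = FALSE])
    acc <- lapply(ph, function(d) {
      op <- birads_operating_points(d$birads_rating)
      c(apply(op, 2L, acc_pct, lab = d$label),
        bm = acc_pct(as.integer(d$bm_preference == "M"), d$label))
    })
    mc <- mcnemar_test(
      (ph$solo$bm_preference == "M") == (ph$solo$label == 1L),
      (ph$ai$bm_preference == "M") == (ph$ai$label == 1L))
    data.frame(reader_id = tr$reader_id[1L],
               solo_4a = acc$solo[["4a+"]], solo_4b = acc$solo[["4b+"]],
               solo_4c = acc$solo[["4c+"]], solo_bm = acc$solo[["bm"]],
               ai_4a = acc$ai[["4a+"]], ai_4b = acc$ai[["4b+"]],
               ai_4c = acc$ai[["4c+"]], ai_bm = acc$ai[["bm"]],
               increment_birads = reader_increment(
                 acc$solo[c("4a+", "4b+", "4c+")], acc$ai[c("4a+", "4b+", "4c+")]),
               increment_bm = reader_increment(acc$solo[["bm"]], acc$ai[["bm"]]),
               biopsy_rate_solo = biopsy_rate(ph$solo$birads_rating),
               biopsy_rate_ai = biopsy_rate(ph$ai$birads_rating),
               mcnemar_p_bm = mc$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
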