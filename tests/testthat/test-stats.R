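test_that("AUC matches hand counts, the pairwise oracle and pROC", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  # reversing scores reflects the AUC
  withr::with_seed(60, {
    for (rep in 1:5) {
      n <- sample(10:50, 1)
      labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
      scores <- round(rnorm(n), 1)           # coarse values force ties
      auc <- roc_auc(scores, labels)
      # exhaustive pairwise count with half credit for ties
      pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
      cnt <- 0
      for (p in pos) for (q in neg)
        cnt <- cnt + (p > q) + 0.5 * (p == q)
      expect_equal(auc, cnt / (length(pos) * length(neg)), tolerance = 1e-12)
      expect_equal(roc_auc(-scores, labels), 1 - auc, tolerance = 1e-12)
      # rank-preserving transforms leave the AUC unchanged
      expect_equal(roc_auc(exp(scores) + 2, labels), auc, tolerance = 1e-12)
      # independent library cross-check
      expect_equal(auc, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                       quiet = TRUE,
                                                       direction = "<"))),
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("confusion metrics follow their definitions", {
  # TP=9, FN=3, TN=11, FP=1
  labels <- c(rep(1L, 12), rep(0L, 12))
  preds <- c(rep(1L, 9), rep(0L, 3), rep(0L, 11), 1L)
  m <- sens_spec_f1(preds, labels)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 11 / 12, tolerance = 1e-9)
  expect_equal(m$f1, 2 * (0.9 * 0.75) / (0.9 + 0.75), tolerance = 1e-9)
  expect_equal(unname(m$counts), c(9L, 1L, 3L, 11L))

  all_right <- sens_spec_f1(labels, labels)
  expect_equal(c(all_right$sensitivity, all_right$specificity, all_right$f1),
               c(1, 1, 1))

  # degenerate denominator is undefined, not zero
  und <- sens_spec_f1(c(0L, 0L, 0L, 1L), c(0L, 0L, 0L, 1L))
  expect_equal(und$precision, 1)
  und2 <- sens_spec_f1(c(0L, 0L), c(0L, 1L))
  expect_true(is.na(und2$precision))

  expect_error(sens_spec_f1(c(1, 2), c(0, 1)), "coded")
  expect_error(sens_spec_f1(c("B", "M"), c(0, 1)), "coded")
})

test_that("bootstrap intervals are seeded, ordered and degenerate-safe", {
  x <- rnorm(50)
  ci <- bootstrap_ci(mean, x, B = 200, seed = 61L)
  ci2 <- bootstrap_ci(mean, x, B = 200, seed = 61L)
  expect_identical(ci[c("lower", "upper")], ci2[c("lower", "upper")])
  expect_lte(ci$lower, ci$point)
  expect_gte(ci$upper, ci$point)

  # constant statistic: zero-width interval
  cc <- bootstrap_ci(function(d) 1.5, x, B = 50, seed = 62L)
  expect_equal(cc$lower, 1.5)
  expect_equal(cc$upper, 1.5)

  # undefined resamples are redrawn (statistic requiring both classes)
  d <- data.frame(s = c(0.1, 0.9, 0.8), y = c(0L, 1L, 1L))
  cb <- bootstrap_ci(function(dd) roc_auc(dd$s, dd$y), d, B = 100, seed = 63L)
  expect_gt(cb$redraws, 0L)
  expect_true(is.finite(cb$lower) && is.finite(cb$upper))
})

test_that("DeLong comparisons behave at the identity and against a bootstrap", {
  withr::with_seed(65, {
    n <- 200L
    labels <- rep(0:1, each = n / 2)
    a <- labels + rnorm(n, sd = 0.8)
    b <- labels + rnorm(n, sd = 1.2)

    same <- delong_test(a, a, labels)
    expect_equal(same$delta, 0)
    expect_equal(same$p, 1)

    fw <- delong_test(a, b, labels)
    bw <- delong_test(b, a, labels)
    expect_equal(fw$delta, -bw$delta)          # antisymmetric
    expect_equal(fw$p, bw$p)
    expect_true(fw$p >= 0 && fw$p <= 1)

    # agreement with a paired-bootstrap two-sided p on the AUC difference
    B <- 2000L
    dobs <- fw$delta
    deltas <- replicate(B, {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) < 2) NA_real_ else
        roc_auc(a[idx], labels[idx]) - roc_auc(b[idx], labels[idx])
    })
    deltas <- deltas[is.finite(deltas)]
    p_boot <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
    expect_lt(abs(fw$p - min(p_boot, 1)), 0.05)
  })
})

test_that("McNemar test uses the exact and asymptotic branches correctly", {
  # b = 5, c = 1: exact two-sided binomial
  a_correct <- c(rep(TRUE, 5), FALSE, rep(TRUE, 10))
  b_correct <- c(rep(FALSE, 5), TRUE, rep(TRUE, 10))
  r <- mcnemar_test(a_correct, b_correct)
  expect_equal(r$b, 5L)
  expect_equal(r$c, 1L)
  expect_equal(r$p, 0.21875, tolerance = 1e-12)
  expect_match(r$method, "exact")

  # symmetric discordance: p = 1
  sym <- mcnemar_test(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE))
  expect_equal(sym$p, 1)

  # all concordant: degenerate convention
  deg <- mcnemar_test(c(TRUE, TRUE), c(TRUE, TRUE))
  expect_equal(deg$p, 1)
  expect_match(deg$method, "degenerate")

  # exact and chi-square branches agree for large discordance
  withr::with_seed(66, {
    for (rep in 1:5) {
      n <- 400L
      a <- runif(n) < 0.75
      b <- runif(n) < 0.72
      r <- mcnemar_test(a, b)
      bb <- r$b; cc <- r$c
      if (bb + cc >= 25) {
        p_exact <- stats::binom.test(min(bb, cc), bb + cc, 0.5)$p.value
        expect_lt(abs(r$p - p_exact), 0.05)
      }
    }
  })
  expect_error(mcnemar_test(logical(0), logical(0)), ">")
})

test_that("ordinal operating points binarize at the three cuts", {
  ratings <- c("3", "4a", "4b", "4c", "5")
  op <- birads_operating_points(ratings)
  expect_equal(unname(op[, "4a+"]), c(0L, 1L, 1L, 1L, 1L))
  expect_equal(unname(op[, "4b+"]), c(0L, 0L, 1L, 1L, 1L))
  expect_equal(unname(op[, "4c+"]), c(0L, 0L, 0L, 1L, 1L))
  expect_true(all(birads_operating_points(rep("3", 4)) == 0L))
  expect_error(birads_operating_points(c("3", "2")), "unknown rating")
})

test_that("reader increments and biopsy rates reproduce table arithmetic", {
  expect_equal(reader_increment(c(74.1, 71.6, 55.0), c(78.3, 85.8, 63.3)), 8.9)
  expect_equal(reader_increment(63.3, 75.8), 12.5)
  expect_equal(reader_increment(c(50, 60), c(50, 60)), 0.0)
  expect_error(reader_increment(c(1, 2), 3), "equal length")

  expect_equal(biopsy_rate(c("3", "4a", "4b")), 66.7)
  expect_equal(biopsy_rate(rep("3", 5)), 0)
  expect_equal(biopsy_rate(rep("5", 3)), 100)
  expect_error(biopsy_rate(character(0)), "empty")
})

test_that("reader-study summaries assemble per-reader metrics", {
  tab <- make_reader_table()
  res <- reader_study_metrics(tab)
  expect_equal(res$reader_id, c("R1", "R2"))
  expect_true(all(res$ai_bm >= res$solo_bm - 20))
  expect_true(all(res$mcnemar_p_bm >= 0 & res$mcnemar_p_bm <= 1))
  expect_equal(res$increment_bm, round_half_up(res$ai_bm - res$solo_bm, 1))

  dir <- withr::local_tempdir()
  path <- file.path(dir, "readers.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  expect_equal(read_reader_table(path)$birads_rating, tab$birads_rating)
})

test_that("modality ablation degrades with the perturbed fraction", {
  fit <- get_smoke_fit()
  tab <- modality_ablation(fit$model, fit$dataset, "elasto",
                           ratios = c(0, 1), strategy = "noise", seed = 67L)
  # ratio 0 reproduces the unperturbed evaluation exactly
  ev <- evaluate_model(fit$model, fit$dataset, B = 0)
  expect_equal(tab$auc[1], ev$auc)
  expect_equal(tab$n_perturbed, c(0L, nrow(ev$predictions)))
  # full perturbation of an informative modality cannot help
  expect_lte(tab$auc[2], tab$auc[1])

  tab2 <- modality_ablation(fit$model, fit$dataset, "elasto",
                            ratios = c(0, 1), strategy = "noise", seed = 67L)
  expect_identical(tab, tab2)                  # seeded determinism

  swap <- modality_ablation(fit$model, fit$dataset, "bmode", ratios = 0.5,
                            strategy = "swap", seed = 68L)
  expect_equal(swap$n_perturbed, nrow(ev$predictions) %/% 2L)
  expect_error(modality_ablation(fit$model, fit$dataset, "bmode",
                                 strategy = "zero"), "arg")
})

test_that("cohort percentages use half-up rounding to one decimal", {
  expect_equal(unname(cohort_percentages(c(9, 48, 27, 19, 17))),
               c(7.5, 40.0, 22.5, 15.8, 14.2))
  expect_equal(round_half_up(c(5.85, -5.85, 2.349), 1), c(5.9, -5.9, 2.3))
})
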