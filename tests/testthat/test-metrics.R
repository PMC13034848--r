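test_that("curve metrics match brute-force oracles on random inputs", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(5:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))  # both classes guaranteed
    scores <- if (rep %% 3 == 0) sample(seq(0, 1, 0.1), n, TRUE)  # heavy ties
              else runif(n)
    m <- sg_curve_metrics(scores, labels)
    expect_equal(m$auroc, oracle_auroc(scores, labels), tolerance = 1e-9)
    expect_equal(m$auprc, oracle_auprc(scores, labels), tolerance = 1e-9)
  }
})

test_that("curve metric edge cases follow the tie and perfect-ranking conventions", {
  expect_equal(sg_curve_metrics(c(.9, .8, .2, .1), c(1, 1, 0, 0))$auprc, 1)
  expect_equal(sg_curve_metrics(c(.9, .8, .2, .1), c(1, 1, 0, 0))$auroc, 1)
  # brute-forced: pairs (0.9 vs 0.8, 0.4) and (0.3 vs 0.8, 0.4) -> (1+0)/2
  expect_equal(sg_curve_metrics(c(.9, .8, .4, .3), c(1, 0, 0, 1))$auroc, 0.5)
  expect_equal(sg_curve_metrics(rep(.5, 6), c(1, 0, 1, 0, 0, 1))$auroc, 0.5)
  expect_error(sg_curve_metrics(runif(5), rep(1, 5)),
               class = "crispr_single_class")
})

test_that("threshold metrics follow confusion-matrix formulas with degenerate flags", {
  perf <- threshold_metrics(c(.9, .9, .1, .1), c(1, 1, 0, 0))
  expect_equal(unlist(perf[c("precision", "recall", "f1", "mcc")]),
               c(precision = 1, recall = 1, f1 = 1, mcc = 1))
  # TP=1 FP=1 FN=1 TN=1
  m <- threshold_metrics(c(.9, .9, .1, .1), c(1, 0, 1, 0))
  expect_equal(unlist(m[c("precision", "recall", "f1", "mcc")]),
               c(precision = .5, recall = .5, f1 = .5, mcc = 0))
  expect_false(m$degenerate)
  allneg <- threshold_metrics(c(.1, .2, .3), c(1, 0, 1))
  expect_equal(allneg$recall, 0)
  expect_true(allneg$degenerate)
})

test_that("dataset evaluation averages per-sgRNA metrics, excluding no-positive guides", {
  preds <- tibble::tibble(
    sgrna_id = rep(c("a", "b", "c"), each = 4),
    label = c(1, 0, 0, 0,  1, 1, 0, 0,  0, 0, 0, 0),
    p_ensemble = c(.9, .5, .4, .1,  .2, .8, .9, .1,  .5, .4, .3, .2))
  dm <- evaluate_dataset(preds)
  expect_identical(dm$N, 2L)  # sgRNA c has no positives
  expect_false("c" %in% dm$records$sgrna_id)
  a <- sg_curve_metrics(preds$p_ensemble[1:4], preds$label[1:4])
  b <- sg_curve_metrics(preds$p_ensemble[5:8], preds$label[5:8])
  expect_equal(dm$auprc, mean(c(a$auprc, b$auprc)))
  expect_equal(dm$auroc, mean(c(a$auroc, b$auroc)))
  # permutation invariance in sgRNA order
  dm2 <- evaluate_dataset(preds[sample(nrow(preds)), ])
  expect_equal(dm2$auprc, dm$auprc)
  # single eligible guide equals its record
  dm3 <- evaluate_dataset(preds[1:4, ])
  expect_equal(dm3$auprc, a$auprc)
  expect_error(evaluate_dataset(preds[9:12, ]), class = "crispr_empty_eval")
})

test_that("exact signed-rank p-values match enumeration for all 32 sign patterns at n=5", {
  base <- c(0.11, 0.23, 0.05, 0.42, 0.31)
  for (mask in 0:31) {
    signs <- ifelse(bitwAnd(mask, 2^(0:4)) > 0, 1, -1)
    d <- base * signs
    p_pkg <- wilcoxon_one_sided(d + 1, rep(1, 5))
    expect_equal(p_pkg, oracle_signed_rank_p(d), tolerance = 1e-12,
                 label = sprintf("mask %d", mask))
  }
})

test_that("five uniformly favorable seeds give the 1/32 headline p-value", {
  x <- c(0.545, 0.493, 0.633, 0.433, 0.578)
  y <- x - c(0.01, 0.02, 0.015, 0.03, 0.005)
  expect_equal(wilcoxon_one_sided(x, y), 1 / 32)
  expect_equal(round(wilcoxon_one_sided(x, y), 3), 0.031)
  # all unfavorable: V = 0 is the full support, p = 1
  expect_equal(wilcoxon_one_sided(y, x), 1)
})

test_that("signed-rank conventions: zeros dropped, ties midranked, degenerate error", {
  expect_error(wilcoxon_one_sided(1:4, 1:4), class = "crispr_undefined_test")
  # zeros dropped: effective n = 3, all positive -> 1/8
  expect_equal(wilcoxon_one_sided(c(1, 2, 3, 4, 5), c(1, 2, 2, 3, 4)), 1 / 8)
  # tied |differences| agree with wilcox.test exact logic on untied parts
  x <- c(3, 5, 1, 9, 6); y <- c(1, 2, 0, 4, 2)
  expect_equal(wilcoxon_one_sided(x, y),
               oracle_signed_rank_p(x - y), tolerance = 1e-12)
})

test_that("signed-rank matches the reference implementation on untied data", {
  set.seed(33)
  for (rep in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, alternative = "greater",
                         exact = TRUE)$p.value)
    expect_equal(wilcoxon_one_sided(x, y), ref, tolerance = 1e-12)
  }
})
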