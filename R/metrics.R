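#' Step-function area under the precision-recall curve
#'
#' Scores are sorted decreasingly, tied scores grouped, and precision
#' integrated against recall as a step function (the average-precision
#' estimator): `sum over groups of (delta recall) * precision`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @return AUPRC in `[0, 1]`.
#' @export
auprc_step <- function(scores, labels) {
  .check_two_class(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  ctp <- cumsum(tp); cn <- cumsum(n_g)
  P <- sum(labels)
  prec <- ctp / cn
  rec <- ctp / P
  drec <- diff(c(0, rec))
  sum(drec * prec)
}

#' Rank-statistic area under the ROC curve
#'
#' Computed from the Mann-Whitney statistic with midranks, so tied
#' scores contribute 1/2.
#'
#' @inheritParams auprc_step
#' @return AUROC in `[0, 1]`.
#' @export
auroc_rank <- function(scores, labels) {
  .check_two_class(labels)
  r <- rank(scores)  # midranks
  P <- sum(labels == 1); N <- sum(labels == 0)
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

.check_two_class <- function(labels) {
  if (!all(labels %in% c(0, 1))) abort("labels must be binary 0/1")
  if (length(unique(labels)) < 2) {
    abort("both classes are required (single-class input)",
          class = "crispr_single_class")
  }
  invisible(TRUE)
}

#' Curve metrics for one sgRNA
#'
#' @inheritParams auprc_step
#' @return A list with `auprc` and `auroc`.
#' @export
sg_curve_metrics <- function(scores, labels) {
  .check_two_class(labels)
  list(auprc = auprc_step(scores, labels),
       auroc = auroc_rank(scores, labels))
}

#' Confusion-matrix metrics at a classification threshold
#'
#' Predictions are positive when `score >= threshold`.  Division-by-
#' zero cases (e.g. no predicted positives) return 0 with the
#' `degenerate` flag set.
#'
#' @inheritParams auprc_step
#' @param threshold Decision threshold (default 0.5).
#' @return A list with `precision`, `recall`, `f1`, `mcc`,
#'   `degenerate`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  if (!all(labels %in% c(0, 1))) abort("labels must be binary 0/1")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  degenerate <- FALSE
  div <- function(a, b) {
    if (b == 0) { degenerate <<- TRUE; 0 } else a / b
  }
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- div(2 * precision * recall, precision + recall)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- div(tp * tn - fp * fn, mcc_den)
  list(precision = precision, recall = recall, f1 = f1, mcc = mcc,
       degenerate = degenerate)
}

#' Per-sgRNA evaluation of a prediction set
#'
#' Implements the single-sgRNA protocol: metrics are computed for every
#' sgRNA that has at least one true off-target site (positive label)
#' and at least one negative, then averaged unweighted across sgRNAs.
#'
#' @param predictions Tibble with columns `sgrna_id`, `label` and a
#'   score column.
#' @param score_col Name of the score column (default `"p_ensemble"`,
#'   falling back to `"score"`).
#' @param threshold Threshold for [threshold_metrics()].
#' @return A `dataset_metrics` list: `records` (per-sgRNA tibble),
#'   `auprc`, `auroc`, `precision`, `recall`, `f1`, `mcc`, `N`,
#'   `threshold`.
#' @export
evaluate_dataset <- function(predictions, score_col = NULL,
                             threshold = 0.5) {
  stopifnot(is.data.frame(predictions),
            all(c("sgrna_id", "label") %in% names(predictions)))
  if (is.null(score_col)) {
    score_col <- intersect(c("p_ensemble", "score"), names(predictions))[1]
    if (is.na(score_col)) abort("no score column found")
  }
  if (!(threshold > 0 && threshold < 1)) abort("threshold must be in (0,1)")
  recs <- predictions |>
    dplyr::group_by(.data$sgrna_id) |>
    dplyr::group_map(function(d, key) {
      n_pos <- sum(d$label == 1); n_neg <- sum(d$label == 0)
      if (n_pos < 1 || n_neg < 1) return(NULL)
      s <- d[[score_col]]
      cm <- sg_curve_metrics(s, d$label)
      tm <- threshold_metrics(s, d$label, threshold)
      tibble::tibble(sgrna_id = key$sgrna_id, n_pos = n_pos, n_neg = n_neg,
                     sg_auprc = cm$auprc, sg_auroc = cm$auroc,
                     precision = tm$precision, recall = tm$recall,
                     f1 = tm$f1, mcc = tm$mcc, degenerate = tm$degenerate)
    }) |>
    dplyr::bind_rows()
  if (nrow(recs) == 0) {
    abort("no sgRNA with both classes present", class = "crispr_empty_eval")
  }
  structure(list(records = recs,
                 auprc = mean(recs$sg_auprc), auroc = mean(recs$sg_auroc),
                 precision = mean(recs$precision), recall = mean(recs$recall),
                 f1 = mean(recs$f1), mcc = mean(recs$mcc),
                 N = nrow(recs), threshold = threshold),
            class = "dataset_metrics")
}

#' @export
print.dataset_metrics <- function(x, ...) {
  cat(sprintf(
    "<dataset_metrics> N=%d sgRNAs | AUPRC=%.4f AUROC=%.4f | P=%.3f R=%.3f F1=%.3f MCC=%.3f (thr %.2f)\n",
    x$N, x$auprc, x$auroc, x$precision, x$recall, x$f1, x$mcc, x$threshold))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dataset_metrics <- function(x, ...) x$records

#' @exportS3Method generics::glance
glance.dataset_metrics <- function(x, ...) {
  tibble::tibble(N = x$N, auprc = x$auprc, auroc = x$auroc,
                 precision = x$precision, recall = x$recall,
                 f1 = x$f1, mcc = x$mcc, threshold = x$threshold)
}

#' One-sided exact Wilcoxon signed-rank test
#'
#' Tests whether the paired differences `x - y` are centered above
#' zero.  Zero differences are dropped (standard signed-rank
#' convention); absolute differences are ranked with midranks; the
#' p-value is `P(V >= v_obs)` under the exact null distribution of the
#' positive-rank sum `V`, obtained by generating-function convolution
#' over all `2^n` sign assignments (exact for `n <= 20`, normal
#' approximation with continuity correction beyond).
#'
#' Five uniformly favorable differences give `p = 1/32 = 0.03125`.
#'
#' @param x,y Equal-length paired numeric vectors.
#' @return The one-sided p-value.
#' @export
wilcoxon_one_sided <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) {
    abort("all paired differences are zero: test undefined",
          class = "crispr_undefined_test")
  }
  n <- length(d)
  r <- rank(abs(d))          # midranks
  v_obs <- sum(r[d > 0])
  if (n <= 20) {
    # distribution of V over sign assignments; work on doubled ranks so
    # midranks (k + 1/2) become integers
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)  # f[s+1] = number of assignments with 2V = s
    f[1] <- 1
    for (rk in r2) {
      g <- numeric(total + 1)
      g[seq_len(total + 1 - rk) + rk] <- f[seq_len(total + 1 - rk)]
      f <- f + g
    }
    s_obs <- as.integer(round(2 * v_obs))
    sum(f[(s_obs + 1):(total + 1)]) / 2^n
  } else {
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4
    stats::pnorm((v_obs - 0.5 - mu) / sqrt(sig2), lower.tail = FALSE)
  }
}
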