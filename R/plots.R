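#' Violin plot of per-position mismatch embedding distributions
#'
#' @param object A [position_stats()] result (or a list of them, e.g.
#'   origin and update stages, combined beforehand with
#'   `dplyr::bind_rows` on their `values`).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.position_stats <- function(object, ...) {
  ggplot2::ggplot(object$values,
                  ggplot2::aes(x = factor(.data$bio_pos), y = .data$value)) +
    ggplot2::geom_violin(fill = "grey80", scale = "width") +
    ggplot2::geom_jitter(width = 0.12, size = 0.4, alpha = 0.5) +
    ggplot2::labs(x = "biological position (1 = PAM-proximal)",
                  y = "embedding value",
                  title = paste("mismatch value distribution -",
                                object$values$stage[1])) +
    ggplot2::theme_minimal()
}

#' Heatmap of the weighted mismatch similarity matrix
#'
#' Tokens are ordered by mismatch group (rA, rC, rG, rT) so intra-group
#' blocks sit on the diagonal.
#'
#' @param object A [pair_similarity()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.similarity_matrix <- function(object, ...) {
  d <- tidy(object)
  ord <- rownames(object$phi)[order(mismatch_group(rownames(object$phi)))]
  d$token1 <- factor(d$token1, ord)
  d$token2 <- factor(d$token2, ord)
  ggplot2::ggplot(d, ggplot2::aes(.data$token1, .data$token2,
                                  fill = .data$phi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0.5) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Φ",
                  title = sprintf("mismatch similarity (%s region, alpha=%.2f)",
                                  object$region, object$alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' Validation trace of a seed run
#'
#' @param object A `seed_run`.
#' @param ... Unused.
#' @return A ggplot of validation AUPRC per epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.seed_run <- function(object, ...) {
  ggplot2::ggplot(object$val_history,
                  ggplot2::aes(.data$epoch, .data$val_auprc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "validation AUPRC",
                  title = sprintf("seed %d", object$seed)) +
    ggplot2::theme_minimal()
}
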