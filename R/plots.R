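# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_boxplot geom_line
#'   geom_hline geom_vline geom_abline geom_errorbar geom_errorbarh labs
#'   theme_bw
NULL

#' @export
ggplot2::autoplot

#' Volcano plot of a signature differential test
#'
#' @param object A [mannwhitney_bh()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sig_difftest <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$delta_median, y = -log10(.data$p_adj),
                 colour = .data$tier)) +
    geom_point() +
    geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    labs(x = "Difference of median scores", y = "-log10 FDR",
         colour = "Tier") +
    theme_bw()
}

#' Score distribution per signature
#'
#' @param object A [score_table()] result.
#' @param ... Unused.
#' @export
autoplot.sig_scores <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$signature, y = .data$score)) +
    geom_boxplot() +
    labs(x = NULL, y = "Single-sample score") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Rank location/dispersion plot of a consistency report
#'
#' Median panel relative rank against median whole-transcriptome relative
#' rank, with MAD error bars on both axes; points coloured by average
#' consistency.
#'
#' @param object A [genewise_consistency()] result.
#' @param ... Unused.
#' @export
autoplot.consistency_tbl <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$ns_median_rr, y = .data$wts_median_rr,
                 colour = .data$avg_consistency)) +
    geom_errorbar(aes(ymin = .data$wts_median_rr - .data$wts_mad,
                      ymax = .data$wts_median_rr + .data$wts_mad),
                  alpha = 0.3, width = 0) +
    geom_errorbarh(aes(xmin = .data$ns_median_rr - .data$ns_mad,
                       xmax = .data$ns_median_rr + .data$ns_mad),
                   alpha = 0.3, height = 0) +
    geom_point() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    labs(x = "Panel median relative rank", y = "WTS median relative rank",
         colour = "Avg consistency") +
    theme_bw()
}

#' Per-sample agreement by comparison pair
#'
#' @param object A [comparison_suite()] result.
#' @param ... Unused.
#' @export
autoplot.xplatform_suite <- function(object, ...) {
  ggplot(object$per_sample, aes(x = .data$pair, y = .data$spearman_r)) +
    geom_boxplot() +
    labs(x = NULL, y = "Per-sample Spearman r") +
    theme_bw()
}

#' Training ROC of a response model
#'
#' @param object A [fit_logistic()] `stability_model`.
#' @param ... Unused.
#' @export
autoplot.stability_model <- function(object, ...) {
  df <- object$roc_train
  ggplot(df, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("Training AUC = %.3f", object$auc_train)) +
    theme_bw()
}
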