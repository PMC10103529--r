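# Cross-platform score agreement: per-sample and per-signature comparisons
# between a panel score table and a whole-transcriptome score table, for the
# four calibration pairings.

spearman <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Per-sample cross-platform score agreement
#'
#' For each sample present in both score tables, correlates and regresses the
#' two platforms' scores across the shared signatures. The default
#' orientation fits the panel score as the response on the
#' whole-transcriptome score (`ns ~ wts`); `orientation = "wts_on_ns"` flips
#' it.
#'
#' @param ns_scores,wts_scores `sig_scores` tibbles (see [score_table()]).
#' @param pair Optional label stored in the `pair` column.
#' @param orientation `"ns_on_wts"` (default) or `"wts_on_ns"`.
#' @return Tibble: `sample`, `spearman_r`, `r_squared`, `slope`, `intercept`,
#'   `n`, `pair`.
#' @export
per_sample_agreement <- function(ns_scores, wts_scores, pair = NA_character_,
                                 orientation = c("ns_on_wts", "wts_on_ns")) {
  orientation <- match.arg(orientation)
  a <- score_matrix(ns_scores); b <- score_matrix(wts_scores)
  sigs <- intersect(rownames(a), rownames(b))
  samples <- intersect(colnames(a), colnames(b))
  if (length(sigs) < 3) abort("Need at least 3 shared signatures.")
  if (length(samples) < 1) abort("No shared samples between the score tables.")
  purrr::map_dfr(samples, function(s) {
    ns <- a[sigs, s]; wt <- b[sigs, s]
    if (orientation == "ns_on_wts") { yv <- ns; xv <- wt } else { yv <- wt; xv <- ns }
    fit <- lm(yv ~ xv)
    tibble(sample = s,
           spearman_r = spearman(ns, wt),
           r_squared = suppressWarnings(summary(fit)$r.squared),
           slope = unname(coef(fit)[2]),
           intercept = unname(coef(fit)[1]),
           n = length(sigs), pair = pair)
  })
}

#' Per-signature cross-platform correlation
#'
#' Spearman correlation of each shared signature's scores across the shared
#' samples, with the highly correlated subset (`r >= r_min`, default 0.8)
#' flagged. A constant score vector has no defined correlation and is
#' recorded as missing with a warning.
#'
#' @inheritParams per_sample_agreement
#' @param r_min High-correlation threshold (default 0.8).
#' @return Tibble: `signature`, `spearman_r`, `n_genes`, `n`, `high`, `pair`.
#' @export
per_signature_correlation <- function(ns_scores, wts_scores, r_min = 0.8,
                                      pair = NA_character_) {
  a <- score_matrix(ns_scores); b <- score_matrix(wts_scores)
  sigs <- intersect(rownames(a), rownames(b))
  samples <- intersect(colnames(a), colnames(b))
  if (length(samples) < 3) abort("Need at least 3 shared samples.")
  sizes <- dplyr::distinct(as_tibble(ns_scores)[c("signature", "n_genes")])
  out <- purrr::map_dfr(sigs, function(sg) {
    r <- spearman(a[sg, samples], b[sg, samples])
    tibble(signature = sg, spearman_r = r, n = length(samples), pair = pair)
  })
  if (anyNA(out$spearman_r)) {
    warn(sprintf("Constant score vector(s); correlation undefined for: %s",
                 paste(out$signature[is.na(out$spearman_r)], collapse = ", ")))
  }
  out |>
    dplyr::left_join(sizes, by = "signature") |>
    dplyr::mutate(high = !is.na(.data$spearman_r) & .data$spearman_r >= r_min) |>
    dplyr::select("signature", "spearman_r", "n_genes", "n", "high", "pair")
}

#' The four cross-platform comparison pairs
#'
#' Builds the four score-table pairings between a targeted panel and a
#' whole-transcriptome matrix of the same cohort and runs both agreement
#' analyses for each:
#'
#' 1. `NS_to_WTS_HK` — stable-gene (housekeeping) calibration on both
#'    platforms;
#' 2. `NS_to_WTS_all` — uncalibrated panel ranks vs whole-transcriptome
#'    ranks over all genes;
#' 3. `NS_to_WTS_part` — uncalibrated panel ranks vs whole-transcriptome
#'    ranks restricted to the overlap genes;
#' 4. `NSskew_to_WTS_all` — skew-calibrated panel ranks vs
#'    whole-transcriptome ranks over all genes (the skew transform is fitted
#'    here from the overlap genes' median whole-transcriptome ranks).
#'
#' @param panel_counts Panel genes-x-samples count matrix (endogenous +
#'   housekeeping probes).
#' @param wts_counts Whole-transcriptome genes-x-samples count matrix.
#' @param signatures Named list of gene sets.
#' @param stable_genes Housekeeping genes (present on both platforms).
#' @param overlap Overlap gene universe (panel genes matched in the
#'   transcriptome).
#' @param r_min High-correlation threshold for the per-signature analysis.
#' @param skew_exclude_bottom Passed to [fit_skew_transform()].
#' @param orientation Passed to [per_sample_agreement()].
#' @return An `xplatform_suite` list: `per_sample`, `per_signature`,
#'   `summary` (quartiles of r and r-squared by pair), `skew` (the fitted
#'   transform), `tables` (the six score tables).
#' @export
comparison_suite <- function(panel_counts, wts_counts, signatures, stable_genes,
                             overlap, r_min = 0.8, skew_exclude_bottom = 0,
                             orientation = "ns_on_wts") {
  panel_counts <- as_count_matrix(panel_counts, "panel_counts")
  wts_counts <- as_count_matrix(wts_counts, "wts_counts")
  overlap <- intersect(overlap, rownames(wts_counts))

  wts_rel <- relative_rank_matrix(wts_counts, "no_stable")
  skew <- fit_skew_transform(reference_order(wts_rel, overlap),
                             exclude_bottom = skew_exclude_bottom)

  tables <- list(
    ns_hk    = score_table(panel_counts, signatures, "hk_genes",
                           stable_genes = stable_genes, platform = "NS"),
    ns_plain = score_table(panel_counts, signatures, "no_stable", platform = "NS"),
    ns_skew  = score_table(panel_counts, signatures, "skewed",
                           transform = skew, platform = "NS"),
    wts_hk   = score_table(wts_counts, signatures, "hk_genes",
                           stable_genes = stable_genes, platform = "WTS"),
    wts_all  = score_table(wts_counts, signatures, "no_stable", platform = "WTS"),
    wts_part = score_table(wts_counts, signatures, "part",
                           universe = overlap, platform = "WTS")
  )
  pairs <- list(
    NS_to_WTS_HK      = c("ns_hk", "wts_hk"),
    NS_to_WTS_all     = c("ns_plain", "wts_all"),
    NS_to_WTS_part    = c("ns_plain", "wts_part"),
    NSskew_to_WTS_all = c("ns_skew", "wts_all")
  )
  per_sample <- purrr::imap_dfr(pairs, function(p, nm) {
    per_sample_agreement(tables[[p[1]]], tables[[p[2]]], pair = nm,
                         orientation = orientation)
  })
  per_signature <- purrr::imap_dfr(pairs, function(p, nm) {
    per_signature_correlation(tables[[p[1]]], tables[[p[2]]], r_min = r_min, pair = nm)
  })
  summary <- per_sample |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      r_q1 = quantile(.data$spearman_r, 0.25, na.rm = TRUE),
      r_median = median(.data$spearman_r, na.rm = TRUE),
      r_q3 = quantile(.data$spearman_r, 0.75, na.rm = TRUE),
      r2_q1 = quantile(.data$r_squared, 0.25, na.rm = TRUE),
      r2_median = median(.data$r_squared, na.rm = TRUE),
      r2_q3 = quantile(.data$r_squared, 0.75, na.rm = TRUE),
      n_samples = dplyr::n(), .groups = "drop")
  structure(list(per_sample = per_sample, per_signature = per_signature,
                 summary = summary, skew = skew, tables = tables),
            class = "xplatform_suite")
}

#' @export
print.xplatform_suite <- function(x, ...) {
  cat("Cross-platform agreement suite\n")
  print(x$summary)
  invisible(x)
}
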