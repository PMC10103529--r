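# Cross-platform gene-rank consistency: how well the panel platform
# preserves, sample by sample, the pairwise gene order implied by the
# whole-transcriptome reference.

#' Reference gene order from whole-transcriptome ranks
#'
#' Per-gene median of the relative ranks across the whole-transcriptome
#' samples; the resulting ordering is the reference against which the panel
#' platform's pairwise orders are checked.
#'
#' @param wts_rel Genes-x-samples relative rank matrix (e.g. from
#'   [relative_rank_matrix()]).
#' @param genes Genes to report (default: all rows).
#' @return Named numeric vector of median relative ranks.
#' @export
reference_order <- function(wts_rel, genes = rownames(wts_rel)) {
  miss <- setdiff(genes, rownames(wts_rel))
  if (length(miss)) abort(sprintf("Genes absent from the rank matrix: %s",
                                  paste(miss, collapse = ", ")))
  apply(wts_rel[genes, , drop = FALSE], 1, median)
}

#' Pairwise order-preservation score
#'
#' For a gene pair (g, h) with untied reference order, the fraction of panel
#' samples in which the within-sample rank order of g and h equals the
#' reference order. A within-sample tie between g and h counts as not
#' preserving the (strict) reference order; a tied reference makes the pair
#' unusable and returns `NA`.
#'
#' @param g,h Gene names.
#' @param ns_rel Panel relative rank matrix.
#' @param reference Named reference ranks from [reference_order()].
#' @return Fraction in `[0, 1]`, or `NA` for a tied reference pair.
#' @export
pairwise_consistency <- function(g, h, ns_rel, reference) {
  ref_sign <- sign(reference[[g]] - reference[[h]])
  if (ref_sign == 0) return(NA_real_)
  s <- sign(ns_rel[g, ] - ns_rel[h, ])
  mean(s == ref_sign)
}

#' Gene-wise rank consistency report
#'
#' For every gene, the average pairwise order-preservation score against all
#' other genes (tied-reference pairs skipped), plus the per-platform median
#' and MAD (unscaled) of each gene's relative ranks.
#'
#' @param ns_rel Panel genes-x-samples relative rank matrix.
#' @param wts_rel Whole-transcriptome relative rank matrix (used for the
#'   reference order and the WTS-side median/MAD). Must contain the panel
#'   genes.
#' @param genes Genes to analyse (default: rows of `ns_rel`).
#' @param keep_pairwise Also return the full pairwise matrix.
#' @return A `consistency_tbl` tibble: `gene`, `avg_consistency`,
#'   `ns_median_rr`, `ns_mad`, `wts_median_rr`, `wts_mad`; pairwise matrix in
#'   the `pairwise` attribute when requested.
#' @export
genewise_consistency <- function(ns_rel, wts_rel, genes = rownames(ns_rel),
                                 keep_pairwise = FALSE) {
  if (length(genes) < 2) abort("Need at least 2 genes.")
  reference <- reference_order(wts_rel, genes)
  sub <- ns_rel[genes, , drop = FALSE]
  G <- length(genes); S <- ncol(sub)
  ref_sign <- sign(outer(reference, reference, `-`))
  preserved <- matrix(0, G, G, dimnames = list(genes, genes))
  for (j in seq_len(S)) {
    d <- sign(outer(sub[, j], sub[, j], `-`))
    preserved <- preserved + (d == ref_sign)
  }
  frac <- preserved / S
  frac[ref_sign == 0] <- NA   # tied reference pairs are skipped
  diag(frac) <- NA            # self-pairs are skipped
  avg <- rowMeans(frac, na.rm = TRUE)
  out <- tibble(
    gene = genes,
    avg_consistency = unname(avg),
    ns_median_rr = apply(sub, 1, median),
    ns_mad = apply(sub, 1, plain_mad),
    wts_median_rr = unname(reference),
    wts_mad = apply(wts_rel[genes, , drop = FALSE], 1, plain_mad)
  )
  out <- structure(out, class = c("consistency_tbl", class(out)))
  if (keep_pairwise) attr(out, "pairwise") <- frac
  out
}

#' Stable-gene candidate screen
#'
#' Genes whose average cross-platform consistency exceeds
#' `consistency_min` (default 0.7), annotated with membership in the
#' `top_k_mad` (default 50) smallest-MAD genes on the panel platform.
#'
#' @param report A [genewise_consistency()] tibble.
#' @param consistency_min Minimum average consistency (exclusive).
#' @param top_k_mad Size of the low-MAD annotation set.
#' @return Tibble of candidates (`gene`, `avg_consistency`, `ns_mad`,
#'   `low_mad`), sorted by decreasing consistency; empty with a warning when
#'   nothing passes.
#' @export
stable_candidates <- function(report, consistency_min = 0.7, top_k_mad = 50) {
  report <- as_tibble(report)
  low_mad_genes <- report$gene[order(report$ns_mad)][seq_len(min(top_k_mad, nrow(report)))]
  out <- report |>
    dplyr::filter(.data$avg_consistency > consistency_min) |>
    dplyr::mutate(low_mad = .data$gene %in% low_mad_genes) |>
    dplyr::arrange(dplyr::desc(.data$avg_consistency)) |>
    dplyr::select("gene", "avg_consistency", "ns_mad", "low_mad")
  if (nrow(out) == 0) warn("No gene passes the consistency threshold.")
  out
}
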