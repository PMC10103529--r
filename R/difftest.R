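# Responder differential testing of signature scores and cohort
# contingency statistics.

#' Derive binary response labels from RECIST categories
#'
#' Responders are complete response, partial response, or stable disease
#' lasting more than 6 months without progression; non-responders are
#' progressive disease or stable disease of 6 months or less.
#'
#' @param df Data frame with columns `recist` (`CR`/`PR`/`SD`/`PD`) and, for
#'   `SD` rows, `sd_duration_months`.
#' @return The input tibble with a `response` column (`"R"`/`"NR"`).
#' @export
derive_response <- function(df) {
  df <- as_tibble(df)
  if (!"recist" %in% names(df)) abort("`df` must have a `recist` column.")
  bad <- setdiff(unique(df$recist), c("CR", "PR", "SD", "PD"))
  if (length(bad)) abort(sprintf("Unknown RECIST categories: %s", paste(bad, collapse = ", ")))
  dur <- if ("sd_duration_months" %in% names(df)) df$sd_duration_months else
    rep(NA_real_, nrow(df))
  if (any(df$recist == "SD" & is.na(dur))) {
    abort("SD rows must carry `sd_duration_months`.")
  }
  df$response <- ifelse(
    df$recist %in% c("CR", "PR") | (df$recist == "SD" & dur > 6), "R", "NR")
  df
}

# One sample per patient: drop technical repeats, then keep the first sample
# (by sample ID sort order) for each patient.
dedupe_patients <- function(metadata) {
  if (!"is_repeat" %in% names(metadata)) metadata$is_repeat <- FALSE
  metadata |>
    dplyr::filter(!.data$is_repeat) |>
    dplyr::arrange(.data$sample_id) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE)
}

#' Rank-sum differential test over signatures with BH adjustment
#'
#' For every signature, a two-sided Mann-Whitney (Wilcoxon rank-sum) test of
#' its scores between the two groups, followed by Benjamini-Hochberg
#' adjustment over all tested signatures. The exact null distribution is used
#' for combined group sizes up to 25 without ties, the tie-corrected normal
#' approximation otherwise. Repeat samples are removed and each patient
#' contributes one sample (first by sample ID).
#'
#' Rows are tiered: `"top"` for adjusted p <= `top_p` and |median
#' difference| >= `top_delta`, `"fdr05"` for adjusted p <= `fdr`, else
#' `"ns"`.
#'
#' @param scores A `sig_scores` tibble ([score_table()]).
#' @param metadata Per-sample metadata with `sample_id`, `patient_id`, and
#'   the grouping column; an `is_repeat` column is honoured when present.
#' @param group `"response"` (R vs NR) or `"lymph_node"` (lymph-node biopsies
#'   vs all other sites, from `biopsy_site`).
#' @param fdr FDR significance threshold (default 0.05).
#' @param top_p,top_delta Thresholds for the `"top"` tier (defaults 2e-4 and
#'   0.1).
#' @return A `sig_difftest` tibble: `signature`, `median_1`, `median_2`,
#'   `delta_median`, `statistic`, `p_value`, `p_adj`, `tier`, plus attributes
#'   `groups` and `n_per_group`.
#' @export
mannwhitney_bh <- function(scores, metadata, group = c("response", "lymph_node"),
                           fdr = 0.05, top_p = 2e-4, top_delta = 0.1) {
  group <- match.arg(group)
  metadata <- dedupe_patients(as_tibble(metadata))
  if (group == "response") {
    g1 <- metadata$sample_id[metadata$response == "R"]
    g2 <- metadata$sample_id[metadata$response == "NR"]
    labels <- c("R", "NR")
  } else {
    is_ln <- metadata$biopsy_site == "lymph_node"
    g1 <- metadata$sample_id[is_ln]
    g2 <- metadata$sample_id[!is_ln]
    labels <- c("lymph_node", "other")
  }
  m <- score_matrix(scores)
  g1 <- intersect(g1, colnames(m)); g2 <- intersect(g2, colnames(m))
  if (length(g1) == 0 || length(g2) == 0) abort("Both groups must be non-empty.")
  rows <- purrr::map_dfr(rownames(m), function(sg) {
    x <- m[sg, g1]; y <- m[sg, g2]
    if (length(unique(c(x, y))) == 1) {
      # degenerate all-tied scores carry no ordering information
      u <- length(x) * length(y) / 2
      pv <- 1
    } else {
      exact <- (length(x) + length(y)) <= 25 && !any(duplicated(c(x, y)))
      ht <- suppressWarnings(wilcox.test(x, y, exact = exact))
      u <- unname(ht$statistic)
      pv <- ht$p.value
    }
    tibble(signature = sg,
           median_1 = median(x), median_2 = median(y),
           delta_median = median(x) - median(y),
           statistic = u,
           p_value = pv)
  })
  rows$p_adj <- p.adjust(rows$p_value, method = "BH")
  rows$tier <- dplyr::case_when(
    rows$p_adj <= top_p & abs(rows$delta_median) >= top_delta ~ "top",
    rows$p_adj <= fdr ~ "fdr05",
    TRUE ~ "ns"
  )
  structure(rows, class = c("sig_difftest", class(rows)),
            groups = labels, n_per_group = c(length(g1), length(g2)))
}

#' Chi-squared contingency test
#'
#' Classical Pearson chi-squared test on an r x c contingency table of
#' non-negative integer counts, with or without Yates' continuity correction
#' (the correction applies only to 2 x 2 tables). Low expected counts (< 5)
#' produce a warning but do not block the test.
#'
#' @param tab Matrix (or table) of counts.
#' @param correction `"yates"` or `"none"`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `correction`,
#'   `min_expected`.
#' @export
contingency_test <- function(tab, correction = c("yates", "none")) {
  correction <- match.arg(correction)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) abort("Cells must be non-negative integers.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Zero row or column margin in the contingency table.")
  }
  if (correction == "yates" && !all(dim(tab) == c(2, 2))) {
    abort("Yates' continuity correction applies only to 2 x 2 tables.")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correction == "yates"))
  min_exp <- min(ht$expected)
  if (min_exp < 5) {
    warn(sprintf("Minimum expected count %.2f < 5; chi-squared approximation may be poor.",
                 min_exp))
  }
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, correction = correction, min_expected = min_exp)
}
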