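# Emulation of the documented nCounter QC/normalisation chain:
# background flooring -> positive-control scaling -> housekeeping screen ->
# content normalisation -> per-cartridge panel-standard calibration.
# The vendor software's exact defaults are proprietary; this implements the
# publicly documented geometric-mean scheme. Because every step is a
# per-sample positive rescaling (plus flooring ties), within-sample gene
# ranks -- and therefore the rank-based signature scores -- are unchanged on
# tie-free data.

#' Background threshold
#'
#' Floors every count below `floor` at `floor` (the documented default floor
#' is 20 counts), creating ties at the floor among low-signal probes.
#'
#' @param x Counts (vector or matrix).
#' @param floor Non-negative background floor; default 20.
#' @return Floored counts.
#' @export
background_threshold <- function(x, floor = 20) {
  check_positive_scalar(floor, "floor", allow_zero = TRUE)
  pmax(x, floor)
}

#' Positive-control normalisation
#'
#' Per sample, computes the geometric mean of the positive-control probes;
#' the scaling factor is the cohort's arithmetic mean of those geometric
#' means divided by the sample's own. All counts in the sample are
#' multiplied by the factor. Samples whose factor falls outside
#' `flag_range` receive the positive-normalisation flag.
#'
#' @param x Probes-x-samples count matrix.
#' @param positive_probes Names of positive-control probes (>= 1).
#' @param flag_range Length-2 numeric; factors outside it are flagged.
#'   Default `c(0.25, 4)`.
#' @return List: `counts` (scaled matrix), `factors` (per-sample), `flagged`
#'   (character vector of flagged sample IDs).
#' @export
positive_control_scale <- function(x, positive_probes, flag_range = c(0.25, 4)) {
  x <- as_count_matrix(x)
  miss <- setdiff(positive_probes, rownames(x))
  if (length(miss)) abort(sprintf("Positive probes absent: %s", paste(miss, collapse = ", ")))
  gm <- apply(x[positive_probes, , drop = FALSE], 2, geometric_mean)
  if (any(gm == 0)) {
    abort(sprintf("Zero positive-control geometric mean in sample(s): %s",
                  paste(colnames(x)[gm == 0], collapse = ", ")))
  }
  factors <- mean(gm) / gm
  flagged <- colnames(x)[factors < flag_range[1] | factors > flag_range[2]]
  list(counts = sweep(x, 2, factors, `*`), factors = factors, flagged = flagged)
}

#' Housekeeping %CV screen
#'
#' Computes each housekeeping gene's percent coefficient of variation across
#' samples and excludes outlying genes: those on an explicit `drop` list, and
#' (by default) those whose %CV exceeds mean + 2 SD of the housekeeping %CV
#' distribution. Set `cv_limit` to use a fixed %CV cutoff instead.
#'
#' @param x Probes-x-samples count matrix (normalised counts).
#' @param hkgs Housekeeping gene names (>= 2).
#' @param cv_limit Optional fixed %CV cutoff overriding the mean + 2 SD rule.
#' @param drop Optional character vector of genes to exclude regardless.
#' @return List: `retained`, `excluded` (tibble `gene`, `cv_pct`, `reason`),
#'   `cv` (named vector of all %CVs).
#' @export
hkg_screen <- function(x, hkgs, cv_limit = NULL, drop = NULL) {
  x <- as_count_matrix(x)
  if (length(hkgs) < 2) abort("Need at least 2 housekeeping genes.")
  miss <- setdiff(hkgs, rownames(x))
  if (length(miss)) abort(sprintf("Housekeeping genes absent: %s", paste(miss, collapse = ", ")))
  sub <- x[hkgs, , drop = FALSE]
  cv <- 100 * apply(sub, 1, sd) / rowMeans(sub)
  cutoff <- cv_limit %||% (mean(cv) + 2 * sd(cv))
  out <- names(cv)[cv > cutoff]
  excluded <- tibble(
    gene = c(intersect(drop, hkgs), setdiff(out, drop)),
    cv_pct = cv[c(intersect(drop, hkgs), setdiff(out, drop))],
    reason = c(rep("explicit", length(intersect(drop, hkgs))),
               rep("high %CV", length(setdiff(out, drop))))
  )
  retained <- setdiff(hkgs, excluded$gene)
  if (length(retained) == 0) abort("All housekeeping genes excluded by the %CV screen.")
  list(retained = retained, excluded = excluded, cv = cv)
}

#' Content (housekeeping) normalisation
#'
#' Per sample, the content factor is the cohort mean of the housekeeping
#' geometric means divided by the sample's housekeeping geometric mean; all
#' counts are multiplied by it. Samples with factor >= `flag_ratio`
#' (default 10: overall low expression relative to the cohort) receive the
#' content-normalisation flag.
#'
#' @param x Probes-x-samples count matrix.
#' @param hkgs Retained housekeeping genes (non-empty).
#' @param flag_ratio Flagging threshold on the factor; default 10. `Inf`
#'   disables flagging.
#' @return List: `counts`, `factors`, `flagged`.
#' @export
content_normalise <- function(x, hkgs, flag_ratio = 10) {
  x <- as_count_matrix(x)
  if (length(hkgs) == 0) abort("Need a non-empty retained housekeeping set.")
  miss <- setdiff(hkgs, rownames(x))
  if (length(miss)) abort(sprintf("Housekeeping genes absent: %s", paste(miss, collapse = ", ")))
  gm <- apply(x[hkgs, , drop = FALSE], 2, geometric_mean)
  if (any(gm == 0)) {
    abort(sprintf("All-zero housekeeping counts in sample(s): %s",
                  paste(colnames(x)[gm == 0], collapse = ", ")))
  }
  factors <- mean(gm) / gm
  flagged <- colnames(x)[factors >= flag_ratio]
  list(counts = sweep(x, 2, factors, `*`), factors = factors, flagged = flagged)
}

#' Per-cartridge panel-standard calibration
#'
#' Each cartridge carries one designated panel-standard sample. For every
#' gene, a cartridge's calibration factor is the reference cartridge's
#' standard count divided by this cartridge's standard count (both floored at
#' `background` to avoid division blow-ups); all counts in the cartridge are
#' multiplied gene-wise by the factor. Standard samples are removed from the
#' output unless `keep_standards`.
#'
#' @param x Probes-x-samples count matrix.
#' @param cartridge Named vector/factor mapping each sample to its cartridge.
#' @param standard_samples Character vector of the standard sample IDs, one
#'   per cartridge.
#' @param background Floor applied to standard counts; default 20.
#' @param reference Reference cartridge (default: the first, by sort order).
#' @param keep_standards Keep the standard columns in the output.
#' @return List: `counts`, `factors` (genes x cartridges matrix), `reference`.
#' @export
panel_standard_calibrate <- function(x, cartridge, standard_samples,
                                     background = 20, reference = NULL,
                                     keep_standards = FALSE) {
  x <- as_count_matrix(x)
  cartridge <- setNames(as.character(cartridge), names(cartridge) %||% colnames(x))
  if (!all(colnames(x) %in% names(cartridge))) {
    abort("Every sample must have a cartridge assignment.")
  }
  carts <- sort(unique(cartridge[colnames(x)]))
  std_by_cart <- setNames(rep(NA_character_, length(carts)), carts)
  for (s in standard_samples) {
    if (!s %in% colnames(x)) abort(sprintf("Standard sample '%s' not in the matrix.", s))
    std_by_cart[cartridge[[s]]] <- s
  }
  if (anyNA(std_by_cart)) {
    abort(sprintf("Cartridge(s) missing a panel standard: %s",
                  paste(names(std_by_cart)[is.na(std_by_cart)], collapse = ", ")))
  }
  reference <- reference %||% carts[1]
  ref_std <- pmax(x[, std_by_cart[[reference]]], background)
  if (any(x[, unname(std_by_cart)] <= background)) {
    warn("Panel-standard counts at or below background; factors computed against the floor.")
  }
  factors <- vapply(carts, function(cc) {
    ref_std / pmax(x[, std_by_cart[[cc]]], background)
  }, numeric(nrow(x)))
  out <- x
  for (cc in carts) {
    cols <- colnames(x)[cartridge[colnames(x)] == cc]
    out[, cols] <- out[, cols, drop = FALSE] * factors[, cc]
  }
  if (!keep_standards) out <- out[, setdiff(colnames(out), unname(std_by_cart)), drop = FALSE]
  list(counts = out, factors = factors, reference = reference)
}

#' Full NanoString-style normalisation chain
#'
#' Runs, in order: background flooring, positive-control scaling,
#' housekeeping %CV screen, content normalisation, and (when cartridge and
#' standard information is supplied) panel-standard calibration. Samples
#' carrying either normalisation flag are removed when `filter_flagged`.
#'
#' @param x Probes-x-samples count matrix.
#' @param classes Tibble `probe`, `code_class` with classes `Endogenous`,
#'   `Housekeeping`, `Positive`, `Negative`.
#' @param background Background floor (default 20).
#' @param flag_ratio Content-flag threshold (default 10).
#' @param hkg_drop Explicit housekeeping drop list.
#' @param cartridge,standard_samples Optional panel-standard calibration
#'   inputs (see [panel_standard_calibrate()]).
#' @param filter_flagged Remove flagged samples from the output counts.
#' @return A `ns_normalisation` list: `counts`, `pos_factors`,
#'   `content_factors`, `flags` (tibble `sample`, `flag`), `hkg` (screen
#'   result), `retained_hkgs`.
#' @export
normalise_nanostring <- function(x, classes, background = 20, flag_ratio = 10,
                                 hkg_drop = NULL, cartridge = NULL,
                                 standard_samples = NULL, filter_flagged = TRUE) {
  x <- as_count_matrix(x)
  classes <- as_tibble(classes)
  pick <- function(cl) classes$probe[classes$code_class == cl]
  floored <- background_threshold(x, background)
  pos <- positive_control_scale(floored, pick("Positive"))
  screen <- hkg_screen(pos$counts, pick("Housekeeping"), drop = hkg_drop)
  content <- content_normalise(pos$counts, screen$retained, flag_ratio)
  counts <- content$counts
  if (!is.null(cartridge) && !is.null(standard_samples)) {
    cal <- panel_standard_calibrate(counts, cartridge, standard_samples, background)
    counts <- cal$counts
  }
  flags <- dplyr::bind_rows(
    tibble(sample = pos$flagged, flag = "mRNA_positive_norm_flag"),
    tibble(sample = content$flagged, flag = "mRNA_content_norm_flag")
  )
  if (filter_flagged && nrow(flags)) {
    counts <- counts[, setdiff(colnames(counts), flags$sample), drop = FALSE]
  }
  structure(list(counts = counts, pos_factors = pos$factors,
                 content_factors = content$factors, flags = flags,
                 hkg = screen, retained_hkgs = screen$retained),
            class = "ns_normalisation")
}
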