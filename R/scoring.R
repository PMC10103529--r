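#' Competition ranks from zero
#'
#' Ranks a sample's counts with integer ranks starting at 0 in ascending
#' order of expression. Tied counts share the lowest rank of their block
#' (competition, or "min", ranking), so `c(5, 7, 7, 10)` ranks as
#' `c(0, 1, 1, 3)`. Ranks are invariant under any strictly increasing
#' transform of the counts, which is what makes the downstream single-sample
#' scores insensitive to per-sample scaling and normalisation.
#'
#' @param x Numeric vector of counts for one sample, or a genes-x-samples
#'   numeric matrix (ranked column-wise).
#' @return Integer vector or matrix of ranks in `0..(n-1)`.
#' @export
#' @examples
#' rank_genes(c(5, 7, 7, 10))
rank_genes <- function(x) {
  if (is.matrix(x)) {
    r <- apply(x, 2, function(col) rank(col, ties.method = "min") - 1L)
    rownames(r) <- rownames(x)
    return(r)
  }
  if (!is.numeric(x) || length(x) < 2) {
    abort("`x` must be a numeric vector or matrix with at least 2 genes.")
  }
  r <- rank(x, ties.method = "min") - 1L
  storage.mode(r) <- "integer"
  names(r) <- names(x)
  r
}

# Relative ranks in [0, 1]: integer competition rank divided by the maximum
# rank in the sample. An all-tied sample has no ordering information and maps
# to 0.5 everywhere (with a warning).
relative_ranks <- function(x) {
  r <- rank_genes(x)
  scale_one <- function(col) {
    m <- max(col)
    if (m == 0) {
      warn("All counts equal in a sample; relative ranks set to 0.5.")
      return(rep(0.5, length(col)))
    }
    col / m
  }
  if (is.matrix(r)) {
    out <- apply(r, 2, scale_one)
    dimnames(out) <- dimnames(r)
    out
  } else {
    setNames(scale_one(r), names(r))
  }
}

#' Per-sample relative rank matrix
#'
#' Computes the relative (in `[0, 1]`) competition ranks of every gene in
#' every sample, under one of the ranking calibrations used for scoring:
#' `"no_stable"` plain within-sample ranks; `"stable_genes"` ranks stratified
#' into levels by a set of designated stable genes (see
#' [stable_gene_ranks()]); `"skewed"` plain ranks linearly remapped by a
#' fitted [skew_transform][fit_skew_transform].
#'
#' @param x Genes-x-samples count matrix (or data frame with a gene column).
#' @param method One of `"no_stable"`, `"stable_genes"`, `"skewed"`.
#' @param stable_genes Character vector of stable genes (required for
#'   `"stable_genes"`).
#' @param transform A `skew_transform` (required for `"skewed"`).
#' @return Numeric matrix of relative ranks with attribute `method`.
#' @export
relative_rank_matrix <- function(x, method = c("no_stable", "stable_genes", "skewed"),
                                 stable_genes = NULL, transform = NULL) {
  method <- match.arg(method)
  x <- as_count_matrix(x)
  rel <- switch(method,
    no_stable = relative_ranks(x),
    stable_genes = {
      if (is.null(stable_genes)) abort("`stable_genes` required for the stable-gene calibration.")
      stable_gene_ranks(x, stable_genes)
    },
    skewed = {
      if (is.null(transform)) abort("`transform` required for the skewed calibration.")
      apply_skew(relative_ranks(x), transform)
    }
  )
  if (!is.matrix(rel)) rel <- matrix(rel, ncol = 1, dimnames = list(names(rel), colnames(x)))
  attr(rel, "method") <- method
  rel
}

#' Stable-gene stratified relative ranks
#'
#' Calibrates a sample's ranks against `k` designated stable genes. Each gene
#' falls into level `L` = number of stable genes with strictly lower count;
#' within its level it takes fractional position
#' `f = (competition rank within level + 0.5) / level size` among the
#' non-stable genes of that level, and its relative rank is
#' `(L + f) / (k + 1)`, always inside `(0, 1)`. A gene above all stable
#' genes and alone in its level therefore sits at `(k + 0.5) / (k + 1)`.
#' The stable genes themselves pin the level boundaries at `i / (k + 1)`,
#' `i` their within-sample order.
#'
#' @param x Genes-x-samples count matrix or a single sample's named vector.
#' @param stable_genes Character vector of gene names present in `x`.
#' @return Relative rank matrix (or vector) on the stratified scale.
#' @export
stable_gene_ranks <- function(x, stable_genes) {
  vec_input <- !is.matrix(x)
  if (vec_input) x <- matrix(x, ncol = 1, dimnames = list(names(x), "S1"))
  if (length(stable_genes) < 1) abort("Need at least one stable gene.")
  missing <- setdiff(stable_genes, rownames(x))
  if (length(missing)) {
    abort(sprintf("Stable genes absent from the matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  k <- length(stable_genes)
  is_stable <- rownames(x) %in% stable_genes
  out <- apply(x, 2, function(col) {
    stable <- col[stable_genes]
    rel <- numeric(length(col))
    # stable genes pin the level boundaries at i / (k + 1)
    rel[is_stable] <- rank(col[is_stable], ties.method = "min") / (k + 1)
    # every other gene: level = number of stable genes strictly below it,
    # fractional position within its level among non-stable genes
    lev <- vapply(col[!is_stable], function(v) sum(stable < v), numeric(1))
    relo <- numeric(sum(!is_stable))
    for (L in unique(lev)) {
      idx <- which(lev == L)
      r <- rank(col[!is_stable][idx], ties.method = "min") - 1
      f <- (r + 0.5) / length(idx)
      relo[idx] <- (L + f) / (k + 1)
    }
    rel[!is_stable] <- relo
    rel
  })
  rownames(out) <- rownames(x)
  if (vec_input) out[, 1] else out
}

#' Fit the rank skew transform
#'
#' Fits the linear map that carries a uniform rank scale onto the rank region
#' that a gene panel's members occupy within a whole-transcriptome profile.
#' The `m` per-gene median relative ranks are sorted ascending and regressed
#' (OLS) on the uniform quantiles `(i - 0.5) / m`; the coefficients
#' `(intercept a, slope b)` define the transform `r -> a + b * r`. When panel
#' genes are concentrated in the mid/high rank region of the transcriptome,
#' `a > 0` and `b < 1`.
#'
#' The default regresses the observed median ranks on the uniform quantiles
#' (`orientation = "ranks_on_y"`). The alternative orientation fits the
#' quantiles on the ranks and inverts the fit, giving the same map when the
#' relationship is exactly linear.
#'
#' @param median_relranks Numeric vector of per-gene median relative ranks
#'   (typically of the platform-overlap genes within the whole-transcriptome
#'   data). At least 10 values.
#' @param exclude_bottom Fraction in `[0, 1)` of the lowest-ranked genes to
#'   drop before fitting (the low tail can depart from linearity); default 0,
#'   i.e. fit on all genes.
#' @param orientation `"ranks_on_y"` (default) or `"ranks_on_x"`.
#' @return A `skew_transform`: list with `a`, `b`, `r_squared`, `n`,
#'   `orientation`, `exclude_bottom`.
#' @export
fit_skew_transform <- function(median_relranks, exclude_bottom = 0,
                               orientation = c("ranks_on_y", "ranks_on_x")) {
  orientation <- match.arg(orientation)
  y <- sort(as.numeric(median_relranks))
  m <- length(y)
  if (m < 10) abort("Need at least 10 overlap genes to fit the skew transform.")
  if (exclude_bottom < 0 || exclude_bottom >= 1) {
    abort("`exclude_bottom` must be in [0, 1).")
  }
  x <- (seq_len(m) - 0.5) / m
  if (exclude_bottom > 0) {
    keep <- seq_len(m) > floor(exclude_bottom * m)
    x <- x[keep]; y <- y[keep]
  }
  if (stats::var(y) == 0) abort("Median ranks are constant; skew transform is degenerate.")
  if (orientation == "ranks_on_y") {
    fit <- lm(y ~ x)
    a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  } else {
    fit <- lm(x ~ y)
    bp <- unname(coef(fit)[2])
    if (bp <= 0) abort("Skew fit produced a non-positive slope; ranks are not orientation-preserving.")
    # invert x = a' + b' y  =>  y = -a'/b' + (1/b') x
    a <- -unname(coef(fit)[1]) / bp
    b <- 1 / bp
  }
  if (b <= 0) abort("Skew fit produced a non-positive slope; ranks are not orientation-preserving.")
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn harmlessly
  structure(
    list(a = a, b = b, r_squared = r2, n = length(y),
         orientation = orientation, exclude_bottom = exclude_bottom),
    class = "skew_transform"
  )
}

#' @export
print.skew_transform <- function(x, ...) {
  cat(sprintf("skew_transform: r' = %.4f + %.4f r (r^2 = %.4f, n = %d genes)\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_skew_transform
#' @param x A `skew_transform`.
#' @param ... Unused.
#' @export
tidy.skew_transform <- function(x, ...) {
  tibble(term = c("intercept", "slope"), estimate = c(x$a, x$b))
}

#' @rdname fit_skew_transform
#' @export
glance.skew_transform <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_genes = x$n,
         orientation = x$orientation, exclude_bottom = x$exclude_bottom)
}

#' Apply a skew transform to relative ranks
#'
#' Maps each relative rank `r` to `clip(a + b r, 0, 1)`. The map is monotone
#' (slope is constrained positive), so within-sample rank order is preserved;
#' only the region of the `[0, 1]` scale that the ranks occupy changes.
#'
#' @param rel Relative rank vector or matrix.
#' @param transform A [skew_transform][fit_skew_transform].
#' @return Transformed relative ranks, clipped to `[0, 1]`.
#' @export
apply_skew <- function(rel, transform) {
  if (!inherits(transform, "skew_transform")) abort("`transform` must be a skew_transform.")
  out <- pmin(pmax(transform$a + transform$b * rel, 0), 1)
  attributes(out) <- attributes(rel)
  out
}

# Normalisation bounds for the undirected score: the smallest and largest
# mean absolute deviation from the grid centre achievable by m distinct
# positions on the ideal tie-free relative grid 0/(n-1) .. (n-1)/(n-1).
# Data-independent by design; `achievable = TRUE` instead uses the sample's
# own (possibly tied/transformed) relative ranks and their median.
undirected_bounds <- function(n, m, rel = NULL, centre = NULL) {
  if (is.null(rel)) {
    grid <- (seq_len(n) - 1) / (n - 1)
    d <- sort(abs(grid - median(grid)))
  } else {
    d <- sort(abs(rel - centre))
  }
  c(min = mean(d[seq_len(m)]), max = mean(d[seq(length(d) - m + 1, length(d))]))
}

#' Undirected single-sample signature score
#'
#' Scores a gene set within one sample from the sample's internal gene
#' ranking alone. With `c` the median of the sample's relative ranks, the raw
#' statistic is the mean over set members of `|rank - c|`; it is normalised
#' to `[0, 1]` by the smallest and largest mean deviation achievable by a set
#' of the same size on the ideal tie-free rank grid `0 .. n-1` (mapped to
#' `[0, 1]`), then clipped. A set packed at the centre of the ranking scores
#' 0; a set split across the extremes scores 1.
#'
#' @param rel Relative ranks for one sample (named numeric vector) or a
#'   genes-x-samples relative rank matrix, e.g. from
#'   [relative_rank_matrix()].
#' @param gene_set Character vector of member genes; must all be present in
#'   the ranked universe.
#' @param bounds `"grid"` (default, data-independent tie-free bounds) or
#'   `"achievable"` (bounds from the sample's own rank multiset).
#' @return Numeric score(s) in `[0, 1]`, one per sample.
#' @export
singscore_undirected <- function(rel, gene_set, bounds = c("grid", "achievable")) {
  bounds <- match.arg(bounds)
  vec_input <- !is.matrix(rel)
  if (vec_input) rel <- matrix(rel, ncol = 1, dimnames = list(names(rel), "S1"))
  if (length(gene_set) < 1) abort("`gene_set` must contain at least one gene.")
  missing <- setdiff(gene_set, rownames(rel))
  if (length(missing)) {
    abort(sprintf("Genes absent from the ranked universe: %s",
                  paste(missing, collapse = ", ")))
  }
  n <- nrow(rel)
  m <- length(unique(gene_set))
  set <- unique(gene_set)
  centres <- apply(rel, 2, median)
  raw <- colMeans(abs(sweep(rel[set, , drop = FALSE], 2, centres)))
  scores <- vapply(seq_len(ncol(rel)), function(j) {
    b <- if (bounds == "grid") undirected_bounds(n, m)
         else undirected_bounds(n, m, rel = rel[, j], centre = centres[j])
    if (b["max"] - b["min"] <= 0) return(0.5)
    min(max((raw[j] - b["min"]) / (b["max"] - b["min"]), 0), 1)
  }, numeric(1))
  names(scores) <- colnames(rel)
  if (vec_input) unname(scores) else scores
}

#' Score a signature collection on an expression matrix
#'
#' Computes one undirected single-sample score per (signature, sample) under
#' a chosen ranking calibration:
#'
#' * `"no_stable"` — plain within-sample competition ranks on the full
#'   matrix universe (the whole-transcriptome `"all"` variant is this method
#'   on the full gene list);
#' * `"part"` — plain ranks after restricting the matrix to an overlap
#'   `universe` (ranking only the genes the two platforms share);
#' * `"hk_genes"` — ranks stratified by a supplied stable-gene set
#'   ([stable_gene_ranks()]);
#' * `"skewed"` — plain ranks remapped by a fitted skew transform
#'   ([fit_skew_transform()]).
#'
#' Signatures not fully contained in the scoring universe are excluded (the
#' whole-transcriptome rule; see [restrict_signatures()]) and listed in the
#' `excluded` attribute.
#'
#' @param x Genes-x-samples count matrix (or data frame with gene column).
#' @param signatures Named list of gene sets (see [read_gmt()]).
#' @param method One of `"no_stable"`, `"part"`, `"hk_genes"`, `"skewed"`.
#' @param stable_genes Stable-gene set for `"hk_genes"`.
#' @param transform `skew_transform` for `"skewed"`.
#' @param universe Overlap universe for `"part"`.
#' @param platform Optional platform tag stored on the result.
#' @param bounds Passed to [singscore_undirected()].
#' @return A `sig_scores` tibble with columns `signature`, `sample`, `score`,
#'   `n_genes`, and attributes `method`, `platform`, `n_universe`,
#'   `excluded`.
#' @export
score_table <- function(x, signatures,
                        method = c("no_stable", "part", "hk_genes", "skewed"),
                        stable_genes = NULL, transform = NULL, universe = NULL,
                        platform = NA_character_, bounds = "grid") {
  method <- match.arg(method)
  x <- as_count_matrix(x)
  if (method == "part") {
    if (is.null(universe)) abort("`universe` required for the part (overlap) method.")
    keep <- intersect(rownames(x), universe)
    if (length(keep) < 2) abort("Overlap universe shares fewer than 2 genes with the matrix.")
    x <- x[keep, , drop = FALSE]
  }
  rel <- switch(method,
    no_stable = ,
    part = relative_rank_matrix(x, "no_stable"),
    hk_genes = relative_rank_matrix(x, "stable_genes", stable_genes = stable_genes),
    skewed = relative_rank_matrix(x, "skewed", transform = transform)
  )
  kept <- restrict_signatures(signatures, rownames(x))
  if (length(kept) == 0) {
    abort("No signature is fully contained in the scoring universe.")
  }
  rows <- purrr::imap(kept, function(genes, nm) {
    s <- singscore_undirected(rel, genes, bounds = bounds)
    tibble(signature = nm, sample = colnames(rel), score = unname(s),
           n_genes = length(unique(genes)))
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("sig_scores", class(out)),
            method = method, platform = platform,
            n_universe = nrow(x),
            excluded = attr(kept, "excluded"))
}

#' Widen a score table to a signatures-x-samples matrix
#'
#' @param scores A `sig_scores` tibble from [score_table()].
#' @return Numeric matrix, signatures as rows, samples as columns.
#' @export
score_matrix <- function(scores) {
  wide <- tidyr::pivot_wider(as_tibble(scores)[c("signature", "sample", "score")],
                             names_from = "sample", values_from = "score")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$signature
  m
}
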