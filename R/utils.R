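# Internal helpers shared across modules.

# Coerce a genes-x-samples input to a numeric matrix with dimnames.
# Accepts a matrix or a data frame whose first column is the gene identifier.
as_count_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) {
      abort(sprintf("`%s` must have a gene column plus at least one sample column.", arg))
    }
    genes <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix or a data frame with a gene column.", arg))
  }
  if (is.null(rownames(x))) {
    abort(sprintf("`%s` must have gene identifiers as row names.", arg))
  }
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    abort(sprintf("Duplicated gene identifiers in `%s`: %s", arg,
                  paste(head(dup, 5), collapse = ", ")))
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("S", seq_len(ncol(x)))
  }
  x
}

# Geometric mean on strictly positive values; zeros are an error in the
# normalisation chain because background flooring precludes them.
geometric_mean <- function(x) {
  if (any(x < 0)) abort("Geometric mean requires non-negative values.")
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

check_positive_scalar <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (x > 0 || (allow_zero && x >= 0))
  if (!ok) {
    abort(sprintf("`%s` must be a single %s number.", name,
                  if (allow_zero) "non-negative" else "positive"))
  }
  invisible(x)
}

# Median absolute deviation without the 1.4826 consistency constant:
# reported as the plain dispersion of relative ranks.
plain_mad <- function(x) stats::mad(x, constant = 1)
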