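# Shared fixtures, built in code at test time.

# small named count matrix with distinct values (tie-free)
tiny_matrix <- function(n_genes = 10, n_samples = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(sample(seq_len(n_genes * n_samples * 10), n_genes * n_samples),
              n_genes, n_samples,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%d", seq_len(n_samples))))
  storage.mode(m) <- "double"
  m
}

# endogenous + housekeeping probes of a cohort's panel matrix
panel_expression <- function(cohort) {
  keep <- cohort$classes$probe[cohort$classes$code_class %in%
                                 c("Endogenous", "Housekeeping")]
  cohort$panel_counts[keep, , drop = FALSE]
}

small_cohort <- function(seed = 11, ...) {
  simulate_cohort(cohort_config(
    n_patients = 40, n_wts_genes = 400, n_panel_genes = 60, n_hkg = 10,
    seed = seed, ...))
}

# brute-force undirected score: enumerate every m-subset placement on the
# tie-free grid for the normalisation bounds
brute_force_undirected <- function(rel, gene_set) {
  n <- length(rel)
  m <- length(gene_set)
  centre <- median(rel)
  raw <- mean(abs(rel[gene_set] - centre))
  grid <- (seq_len(n) - 1) / (n - 1)
  means <- combn(grid, m, function(g) mean(abs(g - median(grid))))
  if (max(means) == min(means)) return(0.5)   # no spread achievable
  min(max((raw - min(means)) / (max(means) - min(means)), 0), 1)
}

# nested-loop rank-consistency reference
brute_force_consistency <- function(ns_rel, reference) {
  genes <- rownames(ns_rel)
  avg <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    vals <- c()
    for (h in setdiff(genes, g)) {
      rs <- sign(reference[[g]] - reference[[h]])
      if (rs == 0) next
      pres <- 0
      for (s in seq_len(ncol(ns_rel))) {
        if (sign(ns_rel[g, s] - ns_rel[h, s]) == rs) pres <- pres + 1
      }
      vals <- c(vals, pres / ncol(ns_rel))
    }
    avg[g] <- mean(vals)
  }
  avg
}

# exhaustive two-sided Mann-Whitney p-value by relabelling enumeration
enumerate_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(xs, ys) sum(rank(c(xs, ys))[seq_along(xs)]) - n1 * (n1 + 1) / 2
  obs <- u_stat(x, y)
  mu <- n1 * length(y) / 2
  idx <- combn(length(pooled), n1)
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  mean(abs(us - mu) >= abs(obs - mu))
}

# direct step-up BH implementation
step_up_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# break within-sample count ties with order-consistent sub-integer offsets,
# yielding tie-free expression on the same scale
break_ties <- function(m) {
  apply(m, 2, function(col) col + (rank(col, ties.method = "first") - 1) / (2 * length(col))) |>
    (\(x) {rownames(x) <- rownames(m); x})()
}
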