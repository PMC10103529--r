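test_that("competition ranks start at zero and share the lowest tied rank", {
  expect_identical(rank_genes(c(5, 7, 7, 10)), c(0L, 1L, 1L, 3L))
  expect_identical(rank_genes(1:6), 0:5)
  x <- c(3.2, 9.1, 0.4, 7.7, 7.7)
  expect_identical(rank_genes(log(x)), rank_genes(x))
  expect_identical(rank_genes(x * 3 + 7), rank_genes(x))
})

test_that("an all-tied sample collapses to relative rank 0.5 with a warning", {
  m <- matrix(c(4, 4, 4, 1, 2, 3), ncol = 2,
              dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  expect_warning(rel <- relative_rank_matrix(m), "0.5")
  expect_equal(rel[, "S1"], c(A = 0.5, B = 0.5, C = 0.5))
  expect_equal(rel[, "S2"], c(A = 0, B = 0.5, C = 1))
})

test_that("undirected score hits the closed-form extremes", {
  rel <- setNames((0:4) / 4, paste0("G", 1:5))
  expect_equal(singscore_undirected(rel, c("G1", "G5")), 1)   # extremes
  expect_equal(singscore_undirected(rel, c("G2", "G3")), 0)   # packed centre
  expect_error(singscore_undirected(rel, c("G1", "ZZ")), "ZZ")
})

test_that("undirected score matches the brute-force normaliser on all 3-subsets of 7 genes", {
  rel <- setNames((0:6) / 6, paste0("G", 1:7))
  subsets <- combn(names(rel), 3)
  for (j in seq_len(ncol(subsets))) {
    expect_equal(singscore_undirected(rel, subsets[, j]),
                 brute_force_undirected(rel, subsets[, j]))
  }
})

test_that("stable-gene stratified ranks follow the level formula", {
  x <- c(lo = 1, mid = 50, hi = 500, s1 = 10, s2 = 100)
  rel <- stable_gene_ranks(x, c("s1", "s2"))
  expect_equal(rel[["lo"]], 0.5 / 3)
  expect_equal(rel[["mid"]], 1.5 / 3)
  expect_equal(rel[["hi"]], 2.5 / 3)
  # stable genes pin the level boundaries
  expect_equal(rel[["s1"]], 1 / 3)
  expect_equal(rel[["s2"]], 2 / 3)
  # a gene above all k stable genes and alone in its level: (k + 0.5)/(k + 1)
  k <- 2
  expect_equal(rel[["hi"]], (k + 0.5) / (k + 1))
  expect_error(stable_gene_ranks(x, c("s1", "absent")), "absent")
})

test_that("skew transform recovers closed-form fits", {
  m <- 100
  x <- (seq_len(m) - 0.5) / m
  fit_id <- fit_skew_transform(x)
  expect_lt(abs(fit_id$a), 1e-10)
  expect_lt(abs(fit_id$b - 1), 1e-10)
  fit_half <- fit_skew_transform(0.5 + 0.5 * x)
  expect_equal(fit_half$a, 0.5)
  expect_equal(fit_half$b, 0.5)
  expect_error(fit_skew_transform(rep(0.4, 50)), "degenerate")
})

test_that("noisy skew fit matches a grid-search least-squares oracle", {
  set.seed(3)
  m <- 60
  x <- (seq_len(m) - 0.5) / m
  y <- sort(pmin(pmax(0.3 + 0.6 * x + rnorm(m, 0, 0.02), 0), 1))
  fit <- fit_skew_transform(y)
  grid <- expand.grid(a = seq(0.2, 0.4, by = 5e-4), b = seq(0.5, 0.7, by = 5e-4))
  sse <- mapply(function(a, b) sum((y - a - b * x)^2), grid$a, grid$b)
  best <- grid[which.min(sse), ]
  expect_equal(fit$a, best$a, tolerance = 1e-3)
  expect_equal(fit$b, best$b, tolerance = 1e-3)
})

test_that("both skew fit orientations agree on exactly linear input", {
  m <- 50
  x <- (seq_len(m) - 0.5) / m
  y <- 0.4 + 0.5 * x
  f1 <- fit_skew_transform(y, orientation = "ranks_on_y")
  f2 <- fit_skew_transform(y, orientation = "ranks_on_x")
  expect_equal(f1$a, f2$a, tolerance = 1e-8)
  expect_equal(f1$b, f2$b, tolerance = 1e-8)
})

test_that("applying a skew preserves rank order and the identity is a no-op", {
  m <- tiny_matrix()
  rel <- relative_rank_matrix(m)
  ident <- structure(list(a = 0, b = 1, r_squared = 1, n = 10,
                          orientation = "ranks_on_y", exclude_bottom = 0),
                     class = "skew_transform")
  expect_equal(unclass(apply_skew(rel, ident)), unclass(rel), ignore_attr = TRUE)
  tr <- structure(list(a = 0.5, b = 0.5, r_squared = 1, n = 10,
                       orientation = "ranks_on_y", exclude_bottom = 0),
                  class = "skew_transform")
  skewed <- apply_skew(rel, tr)
  expect_equal(skewed[1, 1], 0.5 + 0.5 * rel[1, 1])
  expect_equal(cor(rel[, 1], skewed[, 1], method = "spearman"), 1)
  expect_equal(unname(apply_skew(c(g = 0), tr)), 0.5)
})

test_that("score tables are single-sample and invariant to per-sample rescaling", {
  m <- tiny_matrix(n_genes = 30, n_samples = 5)
  sigs <- list(A = rownames(m)[1:6], B = rownames(m)[c(2, 9, 15)])
  base <- score_table(m, sigs, "no_stable")
  # duplicating a column changes nothing for the others
  m2 <- cbind(m, S_dup = m[, 1])
  dup <- score_table(m2, sigs, "no_stable")
  expect_equal(dplyr::filter(dup, sample != "S_dup")$score, base$score)
  # positive per-sample rescaling leaves scores identical
  scaled <- score_table(sweep(m, 2, c(0.5, 2, 10, 1, 7), `*`), sigs, "no_stable")
  expect_equal(scaled$score, base$score)
  # monotone per-sample transform too
  expect_equal(score_table(log1p(m), sigs, "no_stable")$score, base$score)
  expect_true(all(base$score >= 0 & base$score <= 1))
})

test_that("part scoring on a matrix already equal to the overlap equals no_stable", {
  m <- tiny_matrix(n_genes = 20, n_samples = 3)
  sigs <- list(A = rownames(m)[1:5])
  a <- score_table(m, sigs, "part", universe = rownames(m))
  b <- score_table(m, sigs, "no_stable")
  expect_equal(a$score, b$score)
})

test_that("signatures not contained in the universe are excluded with a report", {
  m <- tiny_matrix(n_genes = 8, n_samples = 2)
  sigs <- list(ok = rownames(m)[1:3], bad = c(rownames(m)[1], "MISSING"))
  st <- score_table(m, sigs, "no_stable")
  expect_setequal(unique(st$signature), "ok")
  expect_equal(attr(st, "excluded")$signature, "bad")
  expect_match(attr(st, "excluded")$missing, "MISSING")
  expect_error(score_table(m, list(bad = "MISSING"), "no_stable"), "No signature")
})
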