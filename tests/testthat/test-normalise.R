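test_that("background flooring creates ties at the floor and nothing else", {
  expect_equal(background_threshold(c(5, 20, 21), 20), c(20, 20, 21))
  x <- c(3, 40, 100)
  expect_equal(background_threshold(x, 0), x)
  expect_equal(background_threshold(c(1, 5, 19), 20), c(20, 20, 20))
})

test_that("positive-control factors follow the geometric-mean scheme", {
  # two samples with positive geomeans 100 and 400: reference mean 250
  m <- rbind(POS_A = c(50, 200), POS_B = c(200, 800), G1 = c(10, 10))
  colnames(m) <- c("S1", "S2")
  res <- positive_control_scale(m, c("POS_A", "POS_B"))
  expect_equal(unname(res$factors), c(2.5, 0.625))
  expect_equal(res$counts["G1", ], c(S1 = 25, S2 = 6.25))
  # identical samples: all factors 1
  same <- positive_control_scale(cbind(m[, 1], m[, 1]), c("POS_A", "POS_B"))
  expect_equal(unname(same$factors), c(1, 1))
  # single sample: factor 1
  one <- positive_control_scale(m[, 1, drop = FALSE], c("POS_A", "POS_B"))
  expect_equal(unname(one$factors), 1)
  mz <- m; mz["POS_A", 1] <- 0
  expect_error(positive_control_scale(mz, c("POS_A", "POS_B")), "S1")
})

test_that("the %CV screen excludes the dispersed housekeeping gene", {
  set.seed(1)
  flat <- matrix(rep(100, 19 * 20), 19, 20) + matrix(rnorm(19 * 20, 0, 1), 19, 20)
  noisy <- 100 + rnorm(20, 0, 10)
  m <- rbind(flat, noisy)
  rownames(m) <- c(sprintf("HK%02d", 1:19), "HK_BAD")
  colnames(m) <- sprintf("S%02d", 1:20)
  screen <- hkg_screen(m, rownames(m))
  expect_equal(screen$excluded$gene, "HK_BAD")
  expect_length(screen$retained, 19)
  # identical dispersion: nothing excluded
  all_flat <- hkg_screen(m[1:19, ], rownames(m)[1:19])
  expect_equal(nrow(all_flat$excluded), 0)
  # explicit drop list wins regardless of dispersion
  dropped <- hkg_screen(m, rownames(m), drop = "HK01")
  expect_true("HK01" %in% dropped$excluded$gene)
  expect_false("HK01" %in% dropped$retained)
})

test_that("content normalisation flags overall-low samples at the ratio bound", {
  hk <- rbind(HK1 = c(100, 100, 10), HK2 = c(100, 100, 10))
  m <- rbind(hk, G1 = c(5, 6, 7))
  colnames(m) <- c("S1", "S2", "S3")
  res <- content_normalise(m, c("HK1", "HK2"), flag_ratio = 7)
  expect_equal(unname(res$factors), c(0.7, 0.7, 7))
  expect_equal(res$flagged, "S3")
  # homogeneous cohort: factors 1, no flags
  homo <- content_normalise(m[, c(1, 2)], c("HK1", "HK2"))
  expect_equal(unname(homo$factors), c(1, 1))
  expect_length(homo$flagged, 0)
  # infinite ratio: flagging disabled
  expect_length(content_normalise(m, c("HK1", "HK2"), flag_ratio = Inf)$flagged, 0)
  mz <- m; mz[c("HK1", "HK2"), 1] <- 0
  expect_error(content_normalise(mz, c("HK1", "HK2")), "S1")
})

test_that("panel-standard calibration equalises cartridges and is idempotent", {
  genes <- sprintf("G%d", 1:5)
  std1 <- c(100, 200, 400, 50, 80)
  m <- cbind(STD1 = std1, A1 = c(90, 150, 300, 60, 70),
             STD2 = std1 / 2, B1 = c(45, 80, 160, 30, 40))
  rownames(m) <- genes
  cart <- c(STD1 = "c1", A1 = "c1", STD2 = "c2", B1 = "c2")
  res <- panel_standard_calibrate(m, cart, c("STD1", "STD2"))
  # second cartridge's standard is half the reference: counts doubled
  expect_equal(res$counts[, "B1"], m[, "B1"] * 2)
  expect_equal(res$counts[, "A1"], m[, "A1"])
  expect_setequal(colnames(res$counts), c("A1", "B1"))
  # identical standards: identity
  m2 <- m; m2[, "STD2"] <- std1
  same <- panel_standard_calibrate(m2, cart, c("STD1", "STD2"))
  expect_equal(same$counts[, "B1"], m2[, "B1"])
  # idempotence (keeping the standards in the output)
  once <- panel_standard_calibrate(m, cart, c("STD1", "STD2"), keep_standards = TRUE)
  twice <- panel_standard_calibrate(once$counts, cart, c("STD1", "STD2"),
                                    keep_standards = TRUE)
  expect_equal(twice$counts, once$counts)
  # a standard at background triggers the floor rule with a warning
  mlow <- m; mlow["G1", "STD2"] <- 10
  expect_warning(low <- panel_standard_calibrate(mlow, cart, c("STD1", "STD2")),
                 "floor")
  expect_equal(low$counts["G1", "B1"], m["G1", "B1"] * 100 / 20)
  expect_error(panel_standard_calibrate(m, cart, "STD1"), "missing a panel standard")
})

test_that("per-sample scaling steps leave within-sample ranks unchanged", {
  co <- small_cohort(seed = 3)
  m <- co$panel_counts
  res <- normalise_nanostring(m, co$classes, background = 20)
  floored <- background_threshold(m, 20)
  shared <- intersect(colnames(m), colnames(res$counts))
  expect_identical(rank_genes(floored[, shared]), rank_genes(res$counts[, shared]))
})

test_that("raw and normalised counts give exactly equal scores on tie-free data", {
  specs <- tibble::tibble(name = paste0("sig", 1:5), size = c(12L, 8L, 6L, 4L, 3L),
                          effect = c(0.5, 0, 0, 0, 0), direction = "up")
  co <- small_cohort(seed = 5, signature_specs = specs)
  m <- break_ties(panel_expression(co))
  pos_probes <- co$classes$probe[co$classes$code_class == "Positive"]
  pos <- positive_control_scale(
    rbind(m, pmax(co$panel_counts[pos_probes, ], 1)),  # lowest spike can hit 0
    pos_probes)
  norm <- content_normalise(pos$counts[rownames(m), ], co$truth$hkgs)$counts
  raw_scores <- score_table(m, co$signatures, "no_stable")
  norm_scores <- score_table(norm, co$signatures, "no_stable")
  expect_equal(raw_scores$score, norm_scores$score)
  # per-sample regression of raw on normalised: slope 1, intercept 0, r2 1
  agg <- per_sample_agreement(raw_scores, norm_scores)
  expect_true(all(abs(agg$slope - 1) < 1e-12))
  expect_true(all(abs(agg$intercept) < 1e-12))
})

test_that("the full chain filters flagged samples and reports factors", {
  co <- small_cohort(seed = 9)
  m <- co$panel_counts
  # engineer one overall-low sample
  m[, 1] <- round(m[, 1] / 60)
  res <- normalise_nanostring(m, co$classes)
  expect_true(all(res$pos_factors > 0))
  expect_true(all(res$content_factors > 0))
  expect_true(colnames(m)[1] %in% res$flags$sample)
  expect_false(colnames(m)[1] %in% colnames(res$counts))
})
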