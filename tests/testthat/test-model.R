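test_that("rank AUC matches pairwise enumeration and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))$auc, 1)
  # responders {0.9, 0.3}, non-responders {0.5, 0.1}: 3 of 4 pairs ordered
  expect_equal(roc_auc(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_auc(c(0.2, 0.3), c(1, 1)), "Both classes")
})

test_that("rank AUC equals trapezoidal ROC integration and the pROC reference", {
  set.seed(2)
  prob <- runif(60)
  y <- rbinom(60, 1, plogis(3 * (prob - 0.5)))
  skip_if(length(unique(y)) < 2)
  res <- roc_auc(prob, y)
  roc <- res$roc[order(1 - res$roc$specificity, res$roc$sensitivity), ]
  x <- c(0, 1 - roc$specificity, 1); yy <- c(0, roc$sensitivity, 1)
  trap <- sum(diff(x) * (head(yy, -1) + yy[-1]) / 2)
  expect_equal(res$auc, trap, tolerance = 1e-10)
  skip_if_not_installed("pROC")
  ref <- pROC::auc(pROC::roc(y, prob, quiet = TRUE))
  expect_equal(res$auc, as.numeric(ref))
})

test_that("confusion metrics follow the declared conventions", {
  one <- classify_evaluate(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(one$mcc, 1)
  expect_equal(one$sensitivity, 1)
  expect_equal(one$specificity, 1)
  # TP=3, TN=4, FP=1, FN=2: MCC = 10 / sqrt(600)
  prob <- c(0.9, 0.8, 0.7, 0.2, 0.3, 0.6, 0.1, 0.2, 0.3, 0.4)
  y <-    c(1,   1,   1,   1,   1,   0,   0,   0,   0,   0)
  m <- classify_evaluate(prob, y, 0.5)
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(3, 4, 1, 2))
  expect_equal(m$mcc, 10 / sqrt(600))
  expect_equal(m$sensitivity, 3 / 5)
  expect_equal(m$specificity, 4 / 5)
  # nothing classified responder: sensitivity missing (not 0), specificity 1
  none <- classify_evaluate(c(0.1, 0.2, 0.3), c(1, 0, 0), 0.9)
  expect_true(is.na(none$sensitivity))
  expect_equal(none$specificity, 1)
  expect_equal(none$mcc, 0)
  expect_error(classify_evaluate(0.5, 1, 1.5), "0, 1")
})

test_that("the boundary counts as responder", {
  m <- classify_evaluate(c(0.5, 0.4999), c(1, 0), 0.5)
  expect_equal(c(m$tp, m$tn), c(1, 1))
})

test_that("feature selection applies the 50% rule, ties, and the top-2 fallback", {
  fr <- tibble::tibble(feature = c("A", "B", "C"),
                       count = c(990, 870, 120), frequency = c(0.99, 0.87, 0.12))
  expect_equal(select_features(fr), c("A", "B"))
  fr$frequency <- c(0.5, 0.5, 0.12)
  expect_setequal(select_features(fr), c("A", "B"))   # inclusive at the cutoff
  fr$frequency <- c(0.4, 0.3, 0.3)
  expect_warning(sel <- select_features(fr), "top 2")
  expect_setequal(sel, c("A", "B", "C"))   # tie at the fallback boundary kept
  fr$frequency <- c(0.4, 0.3, 0.1)
  expect_warning(sel2 <- select_features(fr), "top 2")
  expect_setequal(sel2, c("A", "B"))
})

test_that("repeated CV-LASSO is deterministic and finds the informative feature", {
  set.seed(10)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  x <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(paste0("s", 1:n), paste0("noise", 1:20)))
  x <- cbind(x, signal = y + rnorm(n, 0, 0.25))
  f1 <- cv_lasso_frequencies(x, y, repeats = 5, folds = 10, seed = 3)
  f2 <- cv_lasso_frequencies(x, y, repeats = 5, folds = 10, seed = 3)
  expect_identical(f1$count, f2$count)
  expect_equal(f1$feature[1], "signal")
  expect_equal(f1$frequency[f1$feature == "signal"], 1)
  expect_error(cv_lasso_frequencies(x, rep(1, n), repeats = 1), "single class")
  w <- capture_warnings(cv_lasso_frequencies(x[1:12, ], y[1:12], repeats = 1,
                                             folds = 10, seed = 1))
  expect_true(any(grepl("stratification relaxed", w)))
})

test_that("most pure-noise features are rarely selected", {
  # with a fixed dataset the single luckiest chance correlation can be
  # selected stably, but the bulk of null features churn across fold splits
  set.seed(11)
  n <- 80
  y <- rbinom(n, 1, 0.5)
  x <- matrix(rnorm(n * 15), n, 15,
              dimnames = list(NULL, paste0("noise", 1:15)))
  fr <- cv_lasso_frequencies(x, y, repeats = 20, folds = 5, seed = 4)
  expect_lte(median(fr$frequency), 0.35)
})

test_that("the logistic fit recovers closed-form and degenerate cases", {
  # intercept-only on 60% positives: constant probability 0.6
  x <- matrix(0, 50, 1, dimnames = list(NULL, "flat"))
  y <- rep(c(1, 0), c(30, 20))
  m <- suppressWarnings(fit_logistic(cbind(x, jitter = rnorm(50, 0, 1e-8)), y,
                                     features = "jitter"))
  expect_equal(unname(plogis(m$coefficients[1])), 0.6, tolerance = 0.01)
  # null features: coefficients near zero, training AUC near 1/2
  set.seed(12)
  xb <- matrix(rnorm(4000), 1000, 4, dimnames = list(NULL, paste0("f", 1:4)))
  yb <- rbinom(1000, 1, 0.5)
  mb <- fit_logistic(xb, yb)
  expect_true(all(abs(mb$coefficients[-1]) < 0.2))
  expect_lt(abs(mb$auc_train - 0.5), 0.06)
  # perfect separation flags the ridge fallback but stays rank-perfect
  xs <- matrix(c(rep(0, 10), rep(1, 10), rnorm(20, 0, 0.01)), 20, 2,
               dimnames = list(NULL, c("sep", "pad")))
  ys <- rep(c(0, 1), each = 10)
  expect_warning(ms <- fit_logistic(xs, ys), "fallback")
  expect_true(ms$separation_fallback)
  expect_equal(ms$auc_train, 1)
})

test_that("the Youden threshold is attained on the ROC and tightening never helps sensitivity", {
  set.seed(14)
  prob <- runif(100)
  y <- rbinom(100, 1, prob)
  skip_if(length(unique(y)) < 2)
  res <- roc_auc(prob, y)
  best <- res$roc[which.max(res$roc$youden), ]
  expect_true(best$threshold %in% c(prob, Inf))
  sens <- res$roc$sensitivity[order(res$roc$threshold)]
  expect_true(all(diff(sens) <= 0))
})

test_that("cross-platform prediction guards leakage and reproduces training metrics", {
  co <- simulate_cohort(cohort_config(n_patients = 80, n_wts_genes = 600,
                                      n_panel_genes = 150, n_hkg = 10, seed = 21))
  sc <- score_table(panel_expression(co), co$signatures, "no_stable")
  m <- t(score_matrix(sc))
  y <- as.integer(co$metadata$response == "R")
  model <- fit_logistic(m, y)
  # identity: evaluating the training table reproduces the training AUC
  ev <- cross_platform_predict(model, m, y)
  expect_equal(unique(ev$auc), model$auc_train)
  expect_setequal(ev$threshold_type, c("default", "optimal"))
  # leakage guard
  expect_error(
    cross_platform_predict(model, m, y,
                           target_patients = c("Pt001", "Pt999"),
                           train_patients = co$metadata$patient_id),
    "leakage")
  # missing signature columns are reported
  expect_error(cross_platform_predict(model, m[, 1, drop = FALSE], y),
               "missing from the target")
})

test_that("build_response_model chains selection into a usable model", {
  co <- simulate_cohort(cohort_config(n_patients = 100, n_wts_genes = 600,
                                      n_panel_genes = 150, n_hkg = 10, seed = 23))
  specs_extra <- purrr::map(1:6, ~ sort(sample(co$truth$endogenous, 8)))
  names(specs_extra) <- paste0("noise", 1:6)
  sigs <- c(co$signatures, specs_extra)
  sc <- score_table(panel_expression(co), sigs, "no_stable")
  model <- build_response_model(sc, co$metadata, repeats = 10, folds = 5, seed = 2)
  expect_s3_class(model, "stability_model")
  expect_true("TIS_like" %in% model$features)
  expect_gt(model$auc_train, 0.6)
  expect_equal(glance(model)$n_features, length(model$features))
  expect_equal(nrow(tidy(model)), length(model$features) + 1)
})
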