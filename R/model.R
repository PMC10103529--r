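# Stability feature selection by repeated cross-validated L1-penalized
# logistic regression, an unpenalized final logistic model, and
# threshold-based cross-platform evaluation.

# samples x features numeric matrix from a score table or data frame
as_feature_matrix <- function(x) {
  if (inherits(x, "sig_scores")) x <- t(score_matrix(x))
  if (is.data.frame(x)) {
    rn <- if ("sample" %in% names(x)) x$sample else rownames(x)
    x <- as.matrix(x[, setdiff(names(x), "sample"), drop = FALSE])
    rownames(x) <- rn
  }
  storage.mode(x) <- "double"
  x
}

as_binary_response <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- as.character(y)
    lev <- sort(unique(y))
    if (all(lev %in% c("NR", "R"))) return(as.integer(y == "R"))
    if (length(lev) != 2) abort("`y` must have exactly two classes.")
    return(as.integer(y == lev[2]))
  }
  if (is.logical(y)) return(as.integer(y))
  if (all(y %in% c(0, 1))) return(as.integer(y))
  abort("`y` must be binary (0/1, logical, or a two-level factor).")
}

# Conventional L1 path: 100 log-spaced values from lambda_max (the smallest
# penalty zeroing every coefficient) down four orders of magnitude.
default_lambda_grid <- function(x, y, n_lambda = 100, ratio = 1e-4) {
  xs <- scale(x)
  xs[is.na(xs)] <- 0
  lambda_max <- max(abs(crossprod(xs, y - mean(y)))) / length(y)
  lambda_max <- max(lambda_max, .Machine$double.eps)
  exp(seq(log(lambda_max), log(lambda_max * ratio), length.out = n_lambda))
}

# Stratified fold assignment: fold labels cycled within each class and
# shuffled, so both classes appear in (nearly) every fold.
stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

#' Selection frequencies from repeated cross-validated LASSO
#'
#' Repeats, `repeats` times: a stratified tenfold (by default) split, an
#' L1-penalized logistic path over the lambda grid, selection of the lambda
#' maximizing the mean out-of-fold AUC, and recording of the features with
#' non-zero coefficients there. Each repeat uses a deterministic sub-seed
#' derived from `seed`, so the whole procedure is reproducible.
#'
#' @param x Samples-x-features matrix, data frame, or a `sig_scores` table
#'   (transposed internally).
#' @param y Binary response (0/1, logical, or two-level factor; `"R"`/`"NR"`
#'   is mapped to 1/0).
#' @param repeats Number of repetitions (the full procedure uses 1000).
#' @param folds Cross-validation folds (default 10). If `folds` exceeds the
#'   minority class count, stratification is relaxed with a warning.
#' @param lambda Optional lambda grid; default 100 log-spaced values from
#'   lambda_max down 4 orders of magnitude.
#' @param seed Master seed.
#' @return A `stability_freq` tibble: `feature`, `count`, `frequency`, with
#'   attributes `repeats`, `lambda_grid`, `chosen_lambda`.
#' @export
cv_lasso_frequencies <- function(x, y, repeats = 1000, folds = 10,
                                 lambda = NULL, seed = 1) {
  x <- as_feature_matrix(x)
  y <- as_binary_response(y)
  if (length(unique(y)) < 2) abort("`y` contains a single class; cannot select features.")
  minority <- min(table(y))
  stratify <- TRUE
  if (folds > minority) {
    warn(sprintf("folds (%d) exceeds the minority class count (%d); stratification relaxed.",
                 folds, minority))
    stratify <- FALSE
  }
  lambda <- lambda %||% default_lambda_grid(x, y)
  counts <- setNames(integer(ncol(x)), colnames(x))
  chosen <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed((seed + r) %% .Machine$integer.max)
    foldid <- if (stratify) stratified_folds(y, folds) else
      sample(rep_len(seq_len(folds), length(y)))
    fit <- glmnet::cv.glmnet(x, y, family = "binomial", type.measure = "auc",
                             foldid = foldid, lambda = lambda,
                             standardize = TRUE, thresh = 1e-5)
    best <- fit$lambda[which.max(fit$cvm)]
    chosen[r] <- best
    beta <- coef(fit$glmnet.fit, s = best)[-1, 1]
    counts[names(beta)[beta != 0]] <- counts[names(beta)[beta != 0]] + 1L
  }
  out <- tibble(feature = names(counts), count = unname(counts),
                frequency = unname(counts) / repeats) |>
    dplyr::arrange(dplyr::desc(.data$count))
  structure(out, class = c("stability_freq", class(out)),
            repeats = repeats, lambda_grid = lambda, chosen_lambda = chosen)
}

#' Select the frequently chosen features
#'
#' Default rule: features selected in at least `min_prop` (50%) of repeats,
#' cutoff inclusive (ties kept). If nothing passes, falls back to the
#' `fallback_top` (2) most frequent features with a warning; ties at the
#' fallback boundary are all kept.
#'
#' @param frequencies A [cv_lasso_frequencies()] tibble.
#' @param min_prop Selection proportion cutoff (default 0.5).
#' @param fallback_top Fallback size when nothing passes (default 2).
#' @return Character vector of selected feature names.
#' @export
select_features <- function(frequencies, min_prop = 0.5, fallback_top = 2) {
  if (nrow(frequencies) == 0) abort("`frequencies` is empty.")
  sel <- frequencies$feature[frequencies$frequency >= min_prop]
  if (length(sel) == 0) {
    warn(sprintf("No feature selected in >= %.0f%% of repeats; falling back to the top %d.",
                 100 * min_prop, fallback_top))
    freq_sorted <- sort(frequencies$frequency, decreasing = TRUE)
    cut <- freq_sorted[min(fallback_top, length(freq_sorted))]
    sel <- frequencies$feature[frequencies$frequency >= cut]
  }
  sel
}

#' ROC curve and rank-based AUC
#'
#' AUC is the Mann-Whitney rank statistic `U / (n1 * n0)` with tied
#' probabilities contributing one half. The ROC is traced at every distinct
#' probability threshold, classifying a sample positive when its probability
#' is `>=` the threshold.
#'
#' @param probabilities Numeric predicted probabilities (any monotone score
#'   works; only ranks matter for the AUC).
#' @param labels Binary truth (see [cv_lasso_frequencies()] conventions).
#' @return List: `auc`, `roc` (tibble `threshold`, `sensitivity`,
#'   `specificity`, `youden`).
#' @export
roc_auc <- function(probabilities, labels) {
  y <- as_binary_response(labels)
  if (length(unique(y)) < 2) abort("Both classes must be present to compute an ROC.")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(probabilities)           # average ranks: ties count one half
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- c(sort(unique(probabilities)), Inf)
  roc <- purrr::map_dfr(thresholds, function(t) {
    pred <- probabilities >= t
    tibble(threshold = t,
           sensitivity = sum(pred & y == 1) / n1,
           specificity = sum(!pred & y == 0) / n0)
  })
  roc$youden <- roc$sensitivity + roc$specificity - 1
  list(auc = auc, roc = roc)
}

#' Final logistic model with training ROC and thresholds
#'
#' Unpenalized maximum-likelihood logistic regression on the selected
#' features. Complete or quasi-complete separation (detected by diverging
#' coefficients or fitted probabilities at the boundary) triggers a
#' ridge-stabilized fallback fit, flagged in the model. The training ROC
#' yields the Youden-optimal threshold (`argmax sensitivity + specificity -
#' 1`; ties broken toward the lowest threshold) alongside the default 0.5.
#'
#' @param x Samples-x-features matrix / data frame / `sig_scores` table.
#' @param y Binary response.
#' @param features Feature names to use (default: all columns of `x`).
#' @param frequencies Optional [cv_lasso_frequencies()] table stored on the
#'   model.
#' @return A `stability_model`: list with `features`, `coefficients`,
#'   `auc_train`, `roc_train`, `threshold_default`, `threshold_optimal`,
#'   `separation_fallback`, `frequencies`, `train_patients`.
#' @export
fit_logistic <- function(x, y, features = NULL, frequencies = NULL) {
  x <- as_feature_matrix(x)
  yb <- as_binary_response(y)
  features <- features %||% colnames(x)
  miss <- setdiff(features, colnames(x))
  if (length(miss)) abort(sprintf("Features absent from `x`: %s", paste(miss, collapse = ", ")))
  xf <- x[, features, drop = FALSE]
  df <- data.frame(.y = yb, xf, check.names = FALSE)
  fallback <- FALSE
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  eps <- 1e-8
  if (!fit$converged || anyNA(coef(fit)) || any(abs(coef(fit)[-1]) > 1e3) ||
      any(fit$fitted.values < eps) || any(fit$fitted.values > 1 - eps)) {
    fallback <- TRUE
    warn("Separation detected in the logistic fit; using a ridge-stabilized fallback.")
    rf <- glmnet::glmnet(cbind(xf, `..pad` = 0), yb, family = "binomial",
                         alpha = 0, lambda = 1e-3, standardize = FALSE)
    cf <- coef(rf)[, 1]
    cf <- cf[names(cf) != "..pad"]
    coefs <- setNames(cf, c("(Intercept)", features))
  } else {
    coefs <- coef(fit)
  }
  eta <- drop(cbind(1, xf) %*% coefs)
  prob <- plogis(eta)
  roc <- roc_auc(prob, yb)
  opt_row <- roc$roc[which(roc$roc$youden == max(roc$roc$youden)), , drop = FALSE]
  threshold_optimal <- min(opt_row$threshold)
  structure(
    list(features = features,
         coefficients = coefs,
         auc_train = roc$auc,
         roc_train = roc$roc,
         threshold_default = 0.5,
         threshold_optimal = threshold_optimal,
         separation_fallback = fallback,
         frequencies = frequencies,
         train_patients = attr(y, "patients")),
    class = "stability_model")
}

#' @export
print.stability_model <- function(x, ...) {
  cat(sprintf("stability_model: %d feature(s); training AUC %.3f; optimal threshold %.3f%s\n",
              length(x$features), x$auc_train, x$threshold_optimal,
              if (x$separation_fallback) " (ridge fallback)" else ""))
  invisible(x)
}

#' @rdname fit_logistic
#' @param object A `stability_model`.
#' @param ... Unused.
#' @export
tidy.stability_model <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname fit_logistic
#' @export
glance.stability_model <- function(x, ...) {
  tibble(n_features = length(x$features), auc_train = x$auc_train,
         threshold_default = x$threshold_default,
         threshold_optimal = x$threshold_optimal,
         separation_fallback = x$separation_fallback)
}

#' Predicted probabilities from a stability model
#'
#' @param object A `stability_model`.
#' @param newdata Samples-x-features input containing the model's features.
#' @param ... Unused.
#' @return Named numeric vector of response probabilities.
#' @export
predict.stability_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  miss <- setdiff(object$features, colnames(x))
  if (length(miss)) {
    abort(sprintf("Signature(s) missing from the target score table: %s",
                  paste(miss, collapse = ", ")))
  }
  xf <- x[, object$features, drop = FALSE]
  setNames(plogis(drop(cbind(1, xf) %*% object$coefficients)), rownames(x))
}

#' Confusion-matrix metrics at a probability threshold
#'
#' A sample is classified responder when its probability is `>=` the
#' threshold. Sensitivity and specificity are reported as missing (`NA`),
#' not zero, when their denominator is empty (e.g. no sample classified
#' responder); the Matthews correlation coefficient is 0 by convention when
#' any of its four factors is zero.
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary truth.
#' @param threshold Classification threshold in `[0, 1]`.
#' @return One-row tibble: `threshold`, `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`, `mcc`.
#' @export
classify_evaluate <- function(probabilities, labels, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1].")
  y <- as_binary_response(labels)
  pred <- probabilities >= threshold
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  # within-prediction denominators: no predicted responder => sensitivity is
  # reported, but a zero MCC factor forces the 0 convention
  if (tp + fp == 0) sens <- NA_real_
  if (tn + fn == 0) spec <- NA_real_
  fac <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(fac == 0)) 0 else
    (tp * tn - fp * fn) / sqrt(prod(fac))
  tibble(threshold = threshold, tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = sens, specificity = spec, mcc = mcc)
}

#' Evaluate a model on a target platform's score table
#'
#' Predicts the target samples and evaluates at both model thresholds
#' (default 0.5 and the training-ROC Youden optimum), plus the rank AUC of
#' the probabilities. When patient metadata is supplied for both sides, any
#' patient appearing in both the training and the target set is an error
#' (leakage guard: overlapping patients and their repeats must be excluded
#' from training).
#'
#' @param model A [fit_logistic()] `stability_model`.
#' @param target_scores `sig_scores` table (or samples-x-features matrix) of
#'   the target platform.
#' @param target_labels Binary truth for the target samples, in target
#'   sample order.
#' @param target_patients,train_patients Optional patient IDs used for the
#'   leakage check.
#' @return Tibble with one row per threshold type (`default`, `optimal`):
#'   the [classify_evaluate()] metrics plus `auc`.
#' @export
cross_platform_predict <- function(model, target_scores, target_labels,
                                   target_patients = NULL, train_patients = NULL) {
  train_patients <- train_patients %||% model$train_patients
  if (!is.null(target_patients) && !is.null(train_patients)) {
    leak <- intersect(unique(target_patients), unique(train_patients))
    if (length(leak)) {
      abort(sprintf("Patient-ID leakage between training and target sets: %s",
                    paste(head(leak, 5), collapse = ", ")))
    }
  }
  prob <- predict(model, target_scores)
  auc <- roc_auc(prob, target_labels)$auc
  dplyr::bind_rows(
    dplyr::mutate(classify_evaluate(prob, target_labels, model$threshold_default),
                  threshold_type = "default", .before = 1),
    dplyr::mutate(classify_evaluate(prob, target_labels, model$threshold_optimal),
                  threshold_type = "optimal", .before = 1)
  ) |>
    dplyr::mutate(auc = auc)
}

#' Train the full response model from a score table
#'
#' Convenience wrapper chaining [cv_lasso_frequencies()],
#' [select_features()], and [fit_logistic()] on one platform's score table.
#'
#' @param train_scores `sig_scores` table of the training platform.
#' @param metadata Per-sample metadata with `sample_id`, `patient_id`,
#'   `response`.
#' @param repeats,folds,min_prop,seed Passed through.
#' @return A `stability_model` carrying the selection frequencies and the
#'   training patient IDs (for the leakage guard).
#' @export
build_response_model <- function(train_scores, metadata, repeats = 1000,
                                 folds = 10, min_prop = 0.5, seed = 1) {
  m <- t(score_matrix(train_scores))
  metadata <- as_tibble(metadata)
  meta <- metadata[match(rownames(m), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) abort("Every scored sample needs a metadata row.")
  y <- as_binary_response(meta$response)
  freqs <- cv_lasso_frequencies(m, y, repeats = repeats, folds = folds, seed = seed)
  feats <- select_features(freqs, min_prop = min_prop)
  model <- fit_logistic(m, y, features = feats, frequencies = freqs)
  model$train_patients <- unique(meta$patient_id)
  model
}
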