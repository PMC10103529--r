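# Synthetic paired-platform cohort generator. Two platforms observe the same
# latent per-patient expression profile: a whole-transcriptome matrix over
# all genes and a targeted panel whose endogenous genes are drawn with a
# bias toward high-baseline (mid/high whole-transcriptome rank) genes. The
# panel carries housekeeping, positive- and negative-control probe classes,
# cartridge/batch effects, and optional technical repeats; designated
# signatures receive response-linked shifts with known ground truth.

#' Cohort generator configuration
#'
#' Defaults are the study conditions used throughout the test suite: a
#' cohort in the low hundreds of patients, a ~2000-gene transcriptome
#' universe with a 150-gene panel (scalable to the real ~20k/770 sizes), 20
#' housekeeping genes, a panel-membership bias toward high-expression genes,
#' and two responder-up signatures mirroring the sizes of an 18-gene tumour
#' inflammation signature and a 3-gene checkpoint-axis signature.
#'
#' @param n_patients Number of patients.
#' @param responder_fraction Proportion of responders in (0, 1).
#' @param n_wts_genes Transcriptome universe size (default 2000).
#' @param n_panel_genes Endogenous panel genes (default 150, <= n_wts_genes).
#' @param n_hkg Housekeeping genes (default 20).
#' @param n_pos_controls,n_neg_controls Control probe counts (defaults 6, 8).
#' @param panel_rank_bias Strength (>= 0) of the preference for
#'   high-expression genes when drawing panel membership; 0 = unbiased.
#' @param signature_specs Tibble with columns `name`, `size`, `effect`
#'   (latent log-units added to responders), `direction` (`"up"`/`"down"`).
#' @param batch_count Number of cartridges/batches (default 3).
#' @param batch_sd SD of the per-batch log scale offset (default 0.15).
#' @param repeat_patients Patients receiving technical repeats (default 0).
#' @param dispersion Negative-binomial overdispersion (> 0; variance = mu +
#'   dispersion * mu^2; default 0.05).
#' @param bio_sd Per-gene biological SD in latent log-units (default 1), so
#'   an `effect` of 0.5 is half a latent SD. Housekeeping genes use
#'   `bio_sd_hkg` (default 0.1).
#' @param bio_sd_hkg Housekeeping biological SD (default 0.1).
#' @param module_sd SD of the per-signature shared activity added to every
#'   member gene of a signature (default 0.25): signature genes are
#'   co-regulated modules, which is what makes larger signatures score more
#'   reproducibly across platforms. 0 disables co-regulation.
#' @param composition_sd SD of the per-sample tissue-composition factors
#'   (default 1): bulk biopsies vary in tumour/stroma/immune content, which
#'   moves large co-regulated blocks of the transcriptome outside the
#'   targeted panel and makes the whole-transcriptome rank reference frame
#'   drift between samples. Applied to non-panel genes in the
#'   whole-transcriptome observation only; 0 disables it.
#' @param overlap_fraction Fraction of samples observed on both platforms
#'   (default 1); the remainder are panel-only.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 120, responder_fraction = 0.5,
                          n_wts_genes = 2000, n_panel_genes = 150, n_hkg = 20,
                          n_pos_controls = 6, n_neg_controls = 8,
                          panel_rank_bias = 4,
                          signature_specs = NULL,
                          batch_count = 3, batch_sd = 0.15,
                          repeat_patients = 0, dispersion = 0.05,
                          bio_sd = 1, bio_sd_hkg = 0.1, module_sd = 0.25,
                          composition_sd = 1,
                          overlap_fraction = 1, seed = 1) {
  signature_specs <- signature_specs %||% tibble(
    name = c("TIS_like", "PIP_PD1_like"),
    size = c(18L, 3L),
    effect = c(0.5, 0.5),
    direction = c("up", "up")
  )
  cfg <- list(n_patients = n_patients, responder_fraction = responder_fraction,
              n_wts_genes = n_wts_genes, n_panel_genes = n_panel_genes,
              n_hkg = n_hkg, n_pos_controls = n_pos_controls,
              n_neg_controls = n_neg_controls, panel_rank_bias = panel_rank_bias,
              signature_specs = as_tibble(signature_specs),
              batch_count = batch_count, batch_sd = batch_sd,
              repeat_patients = repeat_patients, dispersion = dispersion,
              bio_sd = bio_sd, bio_sd_hkg = bio_sd_hkg, module_sd = module_sd,
              composition_sd = composition_sd,
              overlap_fraction = overlap_fraction, seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_patients >= 2, responder_fraction > 0, responder_fraction < 1,
              n_wts_genes >= 10, n_panel_genes <= n_wts_genes,
              n_hkg >= 1, n_pos_controls >= 0, n_neg_controls >= 0,
              panel_rank_bias >= 0, batch_count >= 1, batch_sd >= 0,
              repeat_patients >= 0, dispersion > 0, module_sd >= 0,
              composition_sd >= 0,
              overlap_fraction > 0, overlap_fraction <= 1)
    need <- c("name", "size", "effect", "direction")
    if (!all(need %in% names(signature_specs))) {
      abort("`signature_specs` needs columns name, size, effect, direction.")
    }
    if (sum(signature_specs$size[signature_specs$effect != 0]) > n_panel_genes) {
      abort("Signature gene counts with non-zero effects exceed the panel size.")
    }
    if (any(signature_specs$size > n_panel_genes)) {
      abort("A signature is larger than the endogenous panel.")
    }
  })
  invisible(cfg)
}

#' Simulate a paired-platform cohort
#'
#' Draws a long-tailed (log-normal) latent baseline per gene, per-patient
#' biological variation around it, response-linked shifts on the designated
#' signature genes, and then observes the latent profile twice: as
#' whole-transcriptome counts and as targeted-panel counts, each with its
#' own library-size and overdispersed negative-binomial count noise. Panel
#' membership is drawn with logistic weighting on the baseline expression
#' rank at rate `panel_rank_bias`, reproducing the concentration of panel
#' genes in the mid/high transcriptome rank region. Housekeeping probes get
#' high baseline and low biological variance, but their baselines are
#' shuffled among themselves on the panel platform so their cross-platform
#' rank order is deliberately non-uniform. Cartridge/batch scale offsets
#' apply to the panel platform only.
#'
#' @param config A [cohort_config()].
#' @return A `paired_cohort` list: `wts_counts` (genes x overlap samples),
#'   `panel_counts` (probes x all samples, incl. control probes), `classes`
#'   (probe code classes), `metadata` (per-sample tibble), `signatures`
#'   (named list incl. zero-effect sets), `truth` (injected effects, panel
#'   bias, housekeeping shuffle, overlap samples), `config`.
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  set.seed(cfg$seed)

  genes <- sprintf("G%05d", seq_len(cfg$n_wts_genes))
  mu <- rnorm(cfg$n_wts_genes, mean = 2, sd = 1.5)   # log-normal baseline
  names(mu) <- genes

  # housekeeping genes: high baseline, low biological variance
  top <- genes[order(mu, decreasing = TRUE)][seq_len(max(cfg$n_hkg * 4, cfg$n_hkg))]
  hkgs <- sort(sample(top, cfg$n_hkg))
  bio_sd <- setNames(rep(cfg$bio_sd, cfg$n_wts_genes), genes)
  bio_sd[hkgs] <- cfg$bio_sd_hkg

  # endogenous panel membership: logistic weight on the baseline rank
  pool <- setdiff(genes, hkgs)
  rank_pct <- (rank(mu[pool]) - 0.5) / length(pool)
  w <- plogis(cfg$panel_rank_bias * (rank_pct - 0.5))
  endogenous <- sort(sample(pool, cfg$n_panel_genes, prob = w))

  # signature gene sets are drawn from the upper half of the panel baseline
  # distribution (real signature collections consist of expressed genes, so
  # coherent activity moves the whole set away from the sample's median rank
  # and is visible to the undirected score); non-null sets are disjoint
  specs <- cfg$signature_specs
  upper_half <- endogenous[mu[endogenous] >= median(mu[endogenous])]
  signatures <- list()
  used <- character(0)
  for (i in seq_len(nrow(specs))) {
    if (specs$effect[i] != 0) {
      avail <- setdiff(upper_half, used)
      if (length(avail) < specs$size[i]) {
        abort("Not enough unused upper-half panel genes for the non-null signatures.")
      }
      sel <- sort(sample(avail, specs$size[i]))
      used <- c(used, sel)
    } else {
      sel <- sort(sample(upper_half, specs$size[i]))
    }
    signatures[[specs$name[i]]] <- sel
  }

  # patients, labels, structure
  n <- cfg$n_patients
  patients <- sprintf("Pt%03d", seq_len(n))
  sample_id <- sprintf("S%03d", seq_len(n))
  n_resp <- round(n * cfg$responder_fraction)
  response <- sample(c(rep("R", n_resp), rep("NR", n - n_resp)))
  treatment <- sample(c("anti-PD-1", "anti-PD-1 + anti-CTLA-4"), n, replace = TRUE)
  biopsy_site <- sample(c("subcutaneous", "lymph_node", "brain", "lung", "other"),
                        n, replace = TRUE, prob = c(0.45, 0.28, 0.10, 0.05, 0.12))
  batch <- sample(rep_len(seq_len(cfg$batch_count), n))

  # latent per-sample log-expression with response-linked signature shifts
  z <- matrix(rnorm(cfg$n_wts_genes * n), cfg$n_wts_genes, n) * bio_sd + mu
  dimnames(z) <- list(genes, sample_id)
  # co-regulation: each signature's genes share a per-patient activity
  if (cfg$module_sd > 0) {
    for (i in seq_len(nrow(specs))) {
      activity <- rnorm(n, 0, cfg$module_sd)
      z[signatures[[specs$name[i]]], ] <-
        sweep(z[signatures[[specs$name[i]]], , drop = FALSE], 2, activity, `+`)
    }
  }
  for (i in seq_len(nrow(specs))) {
    if (specs$effect[i] == 0) next
    sgn <- if (specs$direction[i] == "up") 1 else -1
    z[signatures[[specs$name[i]]], response == "R"] <-
      z[signatures[[specs$name[i]]], response == "R"] + sgn * specs$effect[i]
  }

  nb <- function(mu_mat) {
    out <- matrix(rnbinom(length(mu_mat), mu = mu_mat, size = 1 / cfg$dispersion),
                  nrow(mu_mat), ncol(mu_mat), dimnames = dimnames(mu_mat))
    out
  }

  # whole-transcriptome observation on the overlap subset; tissue
  # composition drifts the non-panel reference frame between samples
  n_overlap <- max(1L, ceiling(cfg$overlap_fraction * n))
  overlap_samples <- sample_id[sort(sample(seq_len(n), n_overlap))]
  z_wts <- z[, overlap_samples, drop = FALSE]
  if (cfg$composition_sd > 0) {
    non_panel <- setdiff(genes, c(endogenous, hkgs))
    k <- 3   # coarse tissue programs (e.g. tumour / stroma / other)
    program <- sample.int(k, length(non_panel), replace = TRUE)
    factors <- matrix(rnorm(k * n_overlap, 0, cfg$composition_sd), k, n_overlap)
    z_wts[non_panel, ] <- z_wts[non_panel, , drop = FALSE] + factors[program, ]
  }
  wts_sf <- exp(rnorm(n_overlap, 0, 0.2))
  wts_mu <- sweep(exp(z_wts) * 20, 2, wts_sf, `*`)
  wts_counts <- nb(wts_mu)

  # panel observation: housekeeping baselines shuffled among themselves so
  # the cross-platform housekeeping rank order differs
  # Housekeeping probes behave differently on the panel platform: their
  # ranks are dispersed across the mid/high panel expression range (rather
  # than concentrated at the top as in the transcriptome) and their
  # cross-platform order is shuffled. Each HKG keeps its low per-sample
  # noise but takes a re-drawn panel baseline at a spread-out quantile of
  # the endogenous panel distribution.
  hkg_perm <- sample(hkgs)   # dispersed baselines assigned in shuffled order
  disp_q <- seq(0.25, 0.995, length.out = length(hkgs))
  mu_panel_hkg <- setNames(quantile(mu[endogenous], disp_q, names = FALSE),
                           hkg_perm)
  z_panel <- z
  z_panel[hkgs, ] <- z[hkgs, ] - mu[hkgs] + mu_panel_hkg[hkgs]
  batch_offset <- rnorm(cfg$batch_count, 0, cfg$batch_sd)
  panel_sf <- exp(rnorm(n, 0, 0.2) + batch_offset[batch])
  panel_genes <- c(endogenous, hkgs)
  panel_mu <- sweep(exp(z_panel[panel_genes, , drop = FALSE]) * 20, 2, panel_sf, `*`)
  panel_counts <- nb(panel_mu)

  # control probes
  pos_names <- if (cfg$n_pos_controls > 0) sprintf("POS_%s", LETTERS[seq_len(cfg$n_pos_controls)]) else character(0)
  neg_names <- if (cfg$n_neg_controls > 0) sprintf("NEG_%s", LETTERS[seq_len(cfg$n_neg_controls)]) else character(0)
  if (length(pos_names)) {
    pos_mu <- outer(128 / 4^(seq_along(pos_names) - 1) * 32, panel_sf)
    pos_counts <- nb(matrix(pos_mu, length(pos_names), n,
                            dimnames = list(pos_names, sample_id)))
    panel_counts <- rbind(panel_counts, pos_counts)
  }
  if (length(neg_names)) {
    neg_counts <- nb(matrix(2, length(neg_names), n,
                            dimnames = list(neg_names, sample_id)))
    panel_counts <- rbind(panel_counts, neg_counts)
  }

  classes <- tibble(
    probe = rownames(panel_counts),
    code_class = c(rep("Endogenous", length(endogenous)),
                   rep("Housekeeping", length(hkgs)),
                   rep("Positive", length(pos_names)),
                   rep("Negative", length(neg_names)))
  )
  metadata <- tibble(
    sample_id = sample_id, patient_id = patients, response = response,
    treatment = treatment, biopsy_site = biopsy_site, batch = batch,
    is_repeat = FALSE, in_overlap = sample_id %in% overlap_samples
  )
  truth <- list(
    effects = specs,
    signature_genes = signatures,
    endogenous = endogenous, hkgs = hkgs,
    hkg_shuffle = setNames(hkg_perm, hkgs),
    panel_rank_bias = cfg$panel_rank_bias,
    overlap_samples = overlap_samples,
    baseline_log_mean = mu
  )
  cohort <- structure(
    list(wts_counts = wts_counts, panel_counts = panel_counts,
         classes = classes, metadata = metadata,
         signatures = signatures, truth = truth, config = cfg),
    class = "paired_cohort")
  if (cfg$repeat_patients > 0) {
    cohort <- make_repeats(cohort, cfg$repeat_patients, noise_sd = 0.1)
  }
  cohort
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf(paste0("paired_cohort: %d panel samples x %d probes; ",
                     "%d WTS samples x %d genes; %d signatures\n"),
              ncol(x$panel_counts), nrow(x$panel_counts),
              ncol(x$wts_counts), nrow(x$wts_counts), length(x$signatures)))
  invisible(x)
}

#' Append technical repeats to a cohort
#'
#' Re-observes the panel counts of the first `n_repeats` patients with fresh
#' multiplicative technical noise (`exp(N(0, noise_sd^2))` per gene) and,
#' optionally, a different cartridge whose scale offset is applied. With
#' `noise_sd = 0` and `same_batch = TRUE` the repeat equals its original
#' sample exactly.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param n_repeats Number of patients to repeat (<= number of patients).
#' @param noise_sd Technical log-noise SD (>= 0).
#' @param same_batch Keep the original cartridge (default FALSE: a new
#'   cartridge is drawn and its batch offset applied).
#' @param seed Seed for the repeat draws (default: config seed + 1000).
#' @return The cohort with repeat samples appended to the panel matrix and
#'   metadata (`is_repeat = TRUE`).
#' @export
make_repeats <- function(cohort, n_repeats, noise_sd = 0.1, same_batch = FALSE,
                         seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (n_repeats == 0) return(cohort)
  originals <- cohort$metadata[!cohort$metadata$is_repeat, ]
  if (n_repeats > nrow(originals)) abort("`n_repeats` exceeds the number of patients.")
  set.seed(seed %||% ((cohort$config$seed + 1000) %% .Machine$integer.max))
  chosen <- originals[seq_len(n_repeats), ]
  batch_offset <- rnorm(cohort$config$batch_count, 0, cohort$config$batch_sd)
  new_cols <- list(); new_meta <- list()
  for (i in seq_len(n_repeats)) {
    orig <- chosen$sample_id[i]
    new_id <- paste0(orig, "_rep")
    counts <- cohort$panel_counts[, orig]
    new_batch <- if (same_batch) chosen$batch[i] else
      sample(seq_len(cohort$config$batch_count), 1)
    scale <- exp(rnorm(length(counts), 0, noise_sd))
    if (!same_batch && new_batch != chosen$batch[i]) {
      scale <- scale * exp(batch_offset[new_batch] - batch_offset[chosen$batch[i]])
    }
    new_cols[[new_id]] <- round(counts * scale)
    new_meta[[new_id]] <- dplyr::mutate(chosen[i, ], sample_id = new_id,
                                        batch = new_batch, is_repeat = TRUE,
                                        in_overlap = FALSE)
  }
  rep_mat <- do.call(cbind, new_cols)
  colnames(rep_mat) <- names(new_cols)
  cohort$panel_counts <- cbind(cohort$panel_counts, rep_mat)
  cohort$metadata <- dplyr::bind_rows(cohort$metadata, dplyr::bind_rows(new_meta))
  cohort
}

#' Write a cohort to plain-text files
#'
#' Emits `wts_counts.tsv`, `panel_counts.tsv`, `classes.tsv`,
#' `metadata.tsv`, `signatures.gmt`, and `truth.json` under `dir`.
#'
#' @param cohort A `paired_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_matrix(cohort$wts_counts, file.path(dir, "wts_counts.tsv"))
  write_count_matrix(cohort$panel_counts, file.path(dir, "panel_counts.tsv"))
  readr::write_tsv(cohort$classes, file.path(dir, "classes.tsv"), progress = FALSE)
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  write_gmt(cohort$signatures, file.path(dir, "signatures.gmt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- cohort$truth
    truth$baseline_log_mean <- NULL
    jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}
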