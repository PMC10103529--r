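#' Read a NanoString RCC lane file
#'
#' Parses the plain-text sectioned lane format (`<Tag>` ... `</Tag>`
#' sections). The `Code_Summary` section must be present and contain CSV rows
#' `CodeClass,Name,Accession,Count`; `Header`, `Sample_Attributes` and
#' `Lane_Attributes` key-value sections are collected into the `attributes`
#' element.
#'
#' @param path Path to an RCC file.
#' @return List with `probes` (tibble: `code_class`, `name`, `accession`,
#'   `count`) and `attributes` (named character vector).
#' @export
read_rcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  open <- grep("^<[A-Za-z_]+>\\s*$", lines)
  close <- grep("^</[A-Za-z_]+>\\s*$", lines)
  tags <- sub("^<([A-Za-z_]+)>\\s*$", "\\1", lines[open])
  sections <- list()
  for (i in seq_along(open)) {
    end <- close[close > open[i]][1]
    if (is.na(end)) abort(sprintf("Unclosed section <%s> in %s", tags[i], path))
    body <- if (end - open[i] > 1) lines[(open[i] + 1):(end - 1)] else character(0)
    sections[[tags[i]]] <- list(body = body, start = open[i])
  }
  if (!"Code_Summary" %in% names(sections)) {
    abort(sprintf("RCC format error: missing Code_Summary section in %s", path))
  }
  attrs <- character(0)
  for (tag in intersect(c("Header", "Sample_Attributes", "Lane_Attributes"), names(sections))) {
    kv <- strsplit(sections[[tag]]$body, ",", fixed = TRUE)
    kv <- kv[lengths(kv) >= 1]
    vals <- vapply(kv, function(p) paste(p[-1], collapse = ","), character(1))
    names(vals) <- vapply(kv, `[[`, character(1), 1)
    attrs <- c(attrs, vals)
  }
  body <- sections$Code_Summary$body
  offset <- sections$Code_Summary$start
  body_ln <- offset + seq_along(body)
  keep <- nzchar(trimws(body))
  body <- body[keep]; body_ln <- body_ln[keep]
  if (length(body) && grepl("^CodeClass", body[1], ignore.case = TRUE)) {
    body <- body[-1]; body_ln <- body_ln[-1]
  }
  if (length(body) == 0) {
    warn(sprintf("Empty Code_Summary in %s", path))
    probes <- tibble(code_class = character(), name = character(),
                     accession = character(), count = integer())
    return(list(probes = probes, attributes = attrs))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) < 4)
  if (length(bad)) {
    abort(sprintf("RCC format error: malformed Code_Summary row at line %d of %s",
                  body_ln[bad[1]], path))
  }
  cls <- vapply(parts, `[[`, character(1), 1)
  nm <- vapply(parts, `[[`, character(1), 2)
  acc <- vapply(parts, `[[`, character(1), 3)
  cnt_raw <- trimws(vapply(parts, `[[`, character(1), 4))
  ok <- grepl("^[0-9]+$", cnt_raw)
  if (!all(ok)) {
    abort(sprintf("RCC format error: non-integer count '%s' at line %d of %s",
                  cnt_raw[!ok][1], body_ln[!ok][1], path))
  }
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    abort(sprintf("Duplicated probe name(s) in %s: %s", path,
                  paste(dup, collapse = ", ")))
  }
  list(probes = tibble(code_class = cls, name = nm, accession = acc,
                       count = as.integer(cnt_raw)),
       attributes = attrs)
}

#' Write a NanoString RCC lane file
#'
#' Inverse of [read_rcc()]; used to build fixtures and to verify the
#' round-trip property.
#'
#' @param probes Tibble with `code_class`, `name`, `accession`, `count`.
#' @param path Output path.
#' @param attributes Optional named character vector written into the
#'   `Lane_Attributes` section.
#' @return `path`, invisibly.
#' @export
write_rcc <- function(probes, path, attributes = c(ID = "1")) {
  lines <- c("<Header>", "FileVersion,1.7", "</Header>",
             "<Lane_Attributes>",
             paste0(names(attributes), ",", unname(attributes)),
             "</Lane_Attributes>",
             "<Code_Summary>", "CodeClass,Name,Accession,Count",
             sprintf("%s,%s,%s,%d", probes$code_class, probes$name,
                     probes$accession, as.integer(probes$count)),
             "</Code_Summary>")
  writeLines(lines, path)
  invisible(path)
}

#' Read RCC lane files into a count matrix
#'
#' @param paths Character vector of RCC file paths; sample IDs are taken from
#'   the Lane/Sample `ID` attribute when present, else the file name.
#' @return List with `counts` (probes x samples integer matrix) and `classes`
#'   (tibble `probe`, `code_class`).
#' @export
read_rcc_dir <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.RCC$", ignore.case = TRUE, full.names = TRUE)
  }
  if (length(paths) == 0) abort("No RCC files found.")
  lanes <- purrr::map(paths, read_rcc)
  ids <- purrr::map2_chr(lanes, paths, function(l, p) {
    l$attributes[["ID"]] %||% sub("\\.[^.]*$", "", basename(p))
  })
  ref <- lanes[[1]]$probes
  counts <- vapply(lanes, function(l) {
    if (!identical(l$probes$name, ref$name)) {
      abort("RCC lanes do not share an identical probe set/order.")
    }
    l$probes$count
  }, integer(nrow(ref)))
  counts <- matrix(counts, nrow = nrow(ref),
                   dimnames = list(ref$name, make.unique(ids)))
  list(counts = counts, classes = tibble(probe = ref$name, code_class = ref$code_class))
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member genes. Member
#' order is preserved; duplicate members within a set are removed with a
#' warning; a set with zero members, or two sets with the same name, is an
#' error.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    abort(sprintf("Duplicate signature name(s) in %s: %s", path,
                  paste(unique(names_[duplicated(names_)]), collapse = ", ")))
  }
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1))
  sets <- purrr::map2(parts, names_, function(p, nm) {
    genes <- p[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      abort(sprintf("Signature '%s' has zero member genes.", nm))
    }
    if (anyDuplicated(genes)) {
      warn(sprintf("Signature '%s' has duplicate member genes; deduplicated.", nm))
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- names_
  attr(sets, "descriptions") <- setNames(desc, names_)
  sets
}

#' Write a GMT gene-set file
#'
#' @param signatures Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path, descriptions = NULL) {
  desc <- descriptions %||% attr(signatures, "descriptions") %||%
    setNames(rep("na", length(signatures)), names(signatures))
  lines <- purrr::imap_chr(signatures, function(genes, nm) {
    paste(c(nm, desc[[nm]] %||% "na", genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a signature collection to a gene universe
#'
#' Keeps only signatures whose member genes are all present in `universe`
#' (the whole-transcriptome scoring rule: a partially covered signature is
#' excluded rather than scored on its covered fraction). The excluded sets
#' and their missing genes are reported in the `excluded` attribute.
#'
#' @param signatures Named list of gene sets.
#' @param universe Character vector of available genes (non-empty).
#' @return Filtered named list with attribute `excluded` (tibble `signature`,
#'   `missing`).
#' @export
restrict_signatures <- function(signatures, universe) {
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  missing <- purrr::map(signatures, setdiff, y = universe)
  keep <- lengths(missing) == 0
  excluded <- tibble(
    signature = names(signatures)[!keep],
    missing = unname(purrr::map_chr(missing[!keep], paste, collapse = ","))
  )
  out <- signatures[keep]
  attr(out, "descriptions") <- attr(signatures, "descriptions")[names(out)]
  attr(out, "excluded") <- excluded
  out
}

#' Reconcile whole-transcriptome gene names against a panel
#'
#' Applies an alias map to the whole-transcriptome matrix so its row names
#' match the panel probe names, then reports the overlap. Actions:
#' `"merge"` combines several source rows into one target row by summing
#' counts (sum conserves reads; flagged in the report); `"rename"` relabels a
#' single row; `"drop"` marks a panel probe as having no transcriptome match.
#' Matching is case-sensitive exact string equality after alias application.
#'
#' @param wts Genes-x-samples whole-transcriptome count matrix.
#' @param panel_genes Character vector of panel probe names to match.
#' @param alias_map Data frame with columns `source`, `target`, `action`
#'   (`rename`/`merge`/`drop`); may be empty.
#' @return List: `counts` (reconciled matrix), `overlap` (matched panel
#'   probes), `dropped_panel` (panel probes with no match), `report`
#'   (tibble of actions applied).
#' @export
reconcile_genes <- function(wts, panel_genes, alias_map = NULL) {
  wts <- as_count_matrix(wts, "wts")
  if (is.null(alias_map)) {
    alias_map <- tibble(source = character(), target = character(), action = character())
  }
  alias_map <- as_tibble(alias_map)
  stopifnot(all(c("source", "target", "action") %in% names(alias_map)))
  bad <- setdiff(alias_map$action, c("rename", "merge", "drop"))
  if (length(bad)) abort(sprintf("Unknown alias actions: %s", paste(bad, collapse = ", ")))
  merge_rows <- alias_map[alias_map$action == "merge", , drop = FALSE]
  if (anyDuplicated(unique(merge_rows[c("source", "target")])$source)) {
    abort("A source gene appears in more than one merge group.")
  }
  report <- list()
  # merges: sum the source rows into one target row
  for (tg in unique(merge_rows$target)) {
    src <- merge_rows$source[merge_rows$target == tg]
    absent <- setdiff(src, rownames(wts))
    if (length(absent)) {
      abort(sprintf("Merge group for '%s' references absent genes: %s",
                    tg, paste(absent, collapse = ", ")))
    }
    merged <- colSums(wts[src, , drop = FALSE])
    wts <- wts[setdiff(rownames(wts), src), , drop = FALSE]
    wts <- rbind(wts, matrix(merged, nrow = 1, dimnames = list(tg, colnames(wts))))
    report[[length(report) + 1]] <- tibble(action = "merge", source = paste(src, collapse = "+"),
                                           target = tg, rule = "sum")
  }
  # renames
  ren <- alias_map[alias_map$action == "rename", , drop = FALSE]
  for (i in seq_len(nrow(ren))) {
    src <- ren$source[i]; tg <- ren$target[i]
    if (!src %in% rownames(wts)) {
      abort(sprintf("Rename source '%s' absent from the matrix.", src))
    }
    rownames(wts)[rownames(wts) == src] <- tg
    report[[length(report) + 1]] <- tibble(action = "rename", source = src,
                                           target = tg, rule = "relabel")
  }
  dropped <- alias_map$target[alias_map$action == "drop"]
  overlap <- setdiff(intersect(panel_genes, rownames(wts)), dropped)
  no_match <- setdiff(setdiff(panel_genes, rownames(wts)), dropped)
  for (g in c(dropped, no_match)) {
    report[[length(report) + 1]] <- tibble(action = "drop", source = g,
                                           target = NA_character_, rule = "no WTS match")
  }
  list(counts = wts, overlap = overlap,
       dropped_panel = union(dropped, no_match),
       report = dplyr::bind_rows(report) %||% tibble())
}

#' Read / write a genes-x-samples count matrix as TSV
#'
#' First column is the gene identifier, header row carries the sample IDs.
#'
#' @param path File path.
#' @return For the reader, a numeric matrix with gene row names.
#' @export
read_count_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_count_matrix(as.data.frame(df), basename(path))
}

#' @rdname read_count_matrix
#' @param x Genes-x-samples matrix.
#' @export
write_count_matrix <- function(x, path) {
  x <- as_count_matrix(x)
  df <- tibble::as_tibble(x, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Requires columns `sample_id`, `patient_id`, `response`, `treatment`,
#' `biopsy_site`, `batch`; an `is_repeat` column is added (FALSE) when
#' absent.
#'
#' @param path TSV path.
#' @return Tibble of per-sample metadata.
#' @export
read_metadata <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "patient_id", "response", "treatment", "biopsy_site", "batch")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort(sprintf("Metadata is missing required column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!"is_repeat" %in% names(df)) df$is_repeat <- FALSE
  df
}
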