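#' Read a part-1 clinical table
#'
#' Reads and validates the per-patient clinical CSV: one row per patient with
#' best overall response, NLR, overall survival (months + event flag) and raw
#' qPCR Ct values in columns suffixed `_ct` (e.g. `HLA-E_ct`, `GAPDH_ct`).
#'
#' @param path CSV file with a header row.
#' @param config [analysis_config()]; used to check that the reference gene's
#'   Ct column is present.
#' @return A validated tibble (class `pex_clinical`): columns `patient_id`,
#'   `bor`, `nlr`, `os_months`, `os_event` and one `<gene>_ct` column per
#'   assayed gene. Missing Ct values for non-reference markers are kept as
#'   `NA`; downstream stages decide how to treat them.
#' @export
read_clinical_table <- function(path, config = analysis_config()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_clinical_table(raw, config)
}

#' Validate an in-memory clinical table
#'
#' @param table data frame shaped like the clinical CSV (see
#'   [read_clinical_table()]).
#' @inheritParams read_clinical_table
#' @return The validated tibble with class `pex_clinical` prepended.
#' @export
validate_clinical_table <- function(table, config = analysis_config()) {
  table <- as_tibble(table)
  required <- c("patient_id", "bor", "nlr", "os_months", "os_event")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("clinical table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ct_cols <- grep("_ct$", names(table), value = TRUE)
  if (length(ct_cols) == 0) {
    abort("clinical table has no Ct columns (expected >=1 column suffixed '_ct')")
  }
  ref_col <- paste0(config$reference_gene, "_ct")
  if (!ref_col %in% names(table)) {
    abort(paste0("clinical table is missing the reference-gene column '",
                 ref_col, "'"))
  }
  if (anyDuplicated(table$patient_id)) {
    dup <- unique(table$patient_id[duplicated(table$patient_id)])
    abort(paste0("duplicate patient_id: ", paste(dup, collapse = ", ")))
  }
  bad_bor <- setdiff(unique(table$bor), bor_levels())
  if (length(bad_bor) > 0) {
    abort(paste0("unknown BOR categories: ", paste(bad_bor, collapse = ", ")))
  }
  for (col in c("nlr", "os_months", ct_cols)) {
    v <- table[[col]]
    if (!is.numeric(v)) {
      bad_rows <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      abort(paste0("non-numeric values in column '", col, "' at row(s): ",
                   paste(head(bad_rows, 5), collapse = ", ")))
    }
  }
  if (any(table$os_months < 0, na.rm = TRUE)) abort("os_months must be >= 0")
  if (!all(table$os_event %in% c(0, 1))) abort("os_event must be 0/1")
  class(table) <- c("pex_clinical", class(table))
  table
}

#' Gene symbols assayed in a clinical table
#'
#' @param table clinical tibble.
#' @return Character vector of gene symbols (suffix `_ct` stripped).
#' @export
clinical_genes <- function(table) {
  sub("_ct$", "", grep("_ct$", names(table), value = TRUE))
}

#' Write a clinical table to CSV
#'
#' @param table clinical tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' Write ranked combination results to CSV
#'
#' Serializes the output of [rank_combinations()] in the layout of the
#' published candidate-combination table: one row per combination with rank,
#' space-joined markers (genes alphabetical, NLR last), AUC with its 95% CI,
#' the selected score threshold and confusion metrics at it. Displayed values
#' are rounded to 3 decimals; ppv/npv also carry full-precision columns.
#'
#' @param results tibble from [rank_combinations()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_combination_table <- function(results, path) {
  if (nrow(results) == 0) abort("no combination results to write")
  out <- tibble(
    rank = results$rank,
    markers = results$markers,
    auc = round(results$auc, 3),
    auc_ci_low = round(results$auc_ci_low, 3),
    auc_ci_high = round(results$auc_ci_high, 3),
    threshold = round(results$threshold, 3),
    sensitivity = round(results$sensitivity, 3),
    specificity = round(results$specificity, 3),
    ppv = round(results$ppv, 3),
    npv = round(results$npv, 3),
    ppv_full = results$ppv,
    npv_full = results$npv
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a combination table written by [write_combination_table()]
#'
#' @param path CSV file.
#' @return A tibble ordered by rank.
#' @export
read_combination_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  arrange(out, rank)
}

#' Read a gene-by-sample matrix from TSV
#'
#' Used for both raw discovery counts and TPM tables: first column gene
#' symbol, remaining columns one per sample.
#'
#' @param path TSV file.
#' @return A numeric matrix with gene rownames.
#' @export
read_gene_matrix <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- tb[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a gene-by-sample matrix to TSV
#'
#' @param m numeric matrix with gene rownames.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_gene_matrix <- function(m, path) {
  tb <- as_tibble(m, rownames = "gene")
  readr::write_tsv(tb, path)
  invisible(path)
}
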