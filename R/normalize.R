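# qPCR delta-Ct normalization and the log-CPM statistics used by the
# discovery filter.

#' Delta-Ct normalization of a qPCR panel
#'
#' Normalizes each marker gene's threshold cycle to the reference gene:
#' `neg_delta_ct = Ct_ref - Ct_gene`, which increases with transcript
#' abundance. The reference gene itself is excluded from the output. ROC and
#' vote thresholds downstream all operate on this scale; AUC and the
#' threshold-vote classification are invariant under any monotone rescaling
#' (e.g. `2^-dCt`), so the choice of scale affects units only.
#'
#' @param table clinical tibble with `<gene>_ct` columns.
#' @param reference_gene reference gene symbol (its `_ct` column must be
#'   complete).
#' @return Long tibble: `patient_id`, `gene`, `neg_delta_ct`. Marker Cts that
#'   are missing stay absent (rows dropped), never imputed.
#' @export
delta_ct <- function(table, reference_gene = "GAPDH") {
  ref_col <- paste0(reference_gene, "_ct")
  if (!ref_col %in% names(table)) {
    abort(paste0("reference-gene column '", ref_col, "' not found"))
  }
  ref <- table[[ref_col]]
  if (anyNA(ref)) {
    abort(paste0("missing reference Ct for patient(s): ",
                 paste(table$patient_id[is.na(ref)], collapse = ", ")))
  }
  ct_cols <- setdiff(grep("_ct$", names(table), value = TRUE), ref_col)
  long <- tidyr::pivot_longer(
    table[, c("patient_id", ct_cols)],
    cols = dplyr::all_of(ct_cols),
    names_to = "gene", values_to = "ct"
  )
  long$gene <- sub("_ct$", "", long$gene)
  long$neg_delta_ct <- rep(ref, each = length(ct_cols)) - long$ct
  long <- long[!is.na(long$ct), c("patient_id", "gene", "neg_delta_ct")]
  as_tibble(long)
}

#' Compare raw Ct between responders and non-responders
#'
#' Welch two-sample t test on the raw (un-normalized) threshold cycle of one
#' gene between responders (CR/PR) and non-responders (SD/PD/NE). Used to
#' check reference-gene behavior: systematically lower Ct (more template) in
#' non-responders suggests elevated total exosome output.
#'
#' @param table clinical tibble.
#' @param gene gene symbol (must have a `<gene>_ct` column).
#' @return One-row tibble: `gene`, `grouping`, `mean_responder`,
#'   `mean_nonresponder`, `statistic`, `p_value`, `test`.
#' @export
compare_raw_ct <- function(table, gene) {
  col <- paste0(gene, "_ct")
  if (!col %in% names(table)) abort(paste0("no Ct column for gene '", gene, "'"))
  resp <- is_responder(table$bor)
  x <- table[[col]][resp]
  y <- table[[col]][!resp]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("need >=2 measured patients per response group")
  }
  ht <- welch_p(x, y)
  tibble(
    gene = gene, grouping = "responder vs non-responder",
    mean_responder = mean(x), mean_nonresponder = mean(y),
    statistic = ht$statistic, p_value = ht$p, test = "welch"
  )
}

# Welch two-sample test that survives zero pooled variance: two constant
# groups give statistic 0 / p 1 when equal, +-Inf / p 0 when separated.
welch_p <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(statistic = 0, p = 1))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Log2 counts-per-million
#'
#' `log2(1e6 * count / library_size + 1)` per column. A plain library-size
#' normalization for the discovery filter; no TMM or dispersion modelling.
#'
#' @param counts non-negative gene-by-sample count matrix.
#' @return Matrix of the same shape.
#' @export
log2_cpm <- function(counts) {
  counts <- as.matrix(counts)
  libs <- colSums(counts)
  if (any(libs <= 0)) {
    abort(paste0("zero/negative library size in sample(s): ",
                 paste(colnames(counts)[libs <= 0], collapse = ", ")))
  }
  log2(sweep(counts, 2, libs, "/") * 1e6 + 1)
}

# The three BOR groupings used in discovery. PR/SD vs PD puts SD with PR.
bor_groupings <- function() {
  list(
    "PR vs PD" = list(g1 = "PR", g2 = "PD"),
    "PR vs SD/PD" = list(g1 = "PR", g2 = c("SD", "PD")),
    "PR/SD vs PD" = list(g1 = c("PR", "SD"), g2 = "PD")
  )
}

#' Per-gene group contrast on a log2 expression matrix
#'
#' For one BOR grouping, computes per gene the log2 fold change
#' (mean(group1) - mean(group2) on the log2 scale) and a two-sided Welch p.
#'
#' @param expr log2-scale gene-by-sample matrix (e.g. from [log2_cpm()]).
#' @param labels BOR category per sample (column).
#' @param grouping one of `"PR vs PD"`, `"PR vs SD/PD"`, `"PR/SD vs PD"`.
#' @return Tibble: `gene`, `grouping`, `log2_fc`, `p_value`, `test`.
#' @export
group_logfc <- function(expr, labels, grouping = "PR vs PD") {
  grouping <- arg_match(grouping, names(bor_groupings()))
  g <- bor_groupings()[[grouping]]
  i1 <- labels %in% g$g1
  i2 <- labels %in% g$g2
  if (sum(i1) < 2 || sum(i2) < 2) {
    abort(paste0("grouping '", grouping, "' has a side with <2 samples"))
  }
  stats <- apply(expr, 1, function(v) {
    ht <- welch_p(v[i1], v[i2])
    c(lfc = mean(v[i1]) - mean(v[i2]), p = ht$p)
  })
  tibble(
    gene = rownames(expr), grouping = grouping,
    log2_fc = unname(stats["lfc", ]), p_value = unname(stats["p", ]),
    test = "welch"
  )
}
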