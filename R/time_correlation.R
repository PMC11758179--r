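# Part-2 statistics: linking frozen plasma marker levels to the tumor
# immune microenvironment of a paired treatment-naive cohort.

#' Pearson correlation test
#'
#' Sample correlation with the two-sided p from
#' `t = r sqrt((n-2)/(1-r^2))` on `n-2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (pairs with any NA dropped).
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("Pearson test needs n >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  ht <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p: the sum of hypergeometric probabilities of all tables (with
#' the observed margins) no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table))) {
    abort("table must contain non-negative integers")
  }
  if (sum(table) == 0) abort("all-zero table")
  fisher.test(table)$p.value
}

#' Median split into high/low groups
#'
#' Values at or above the sample median go to `high`; below to `low`. With
#' odd n and distinct values this yields `ceiling(n/2)` high.
#'
#' @param values numeric vector.
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
median_split <- function(values) {
  if (length(values) < 2) abort("median split needs n >= 2")
  ifelse(values >= median(values), "high", "low")
}

#' Mann-Whitney U test
#'
#' Exact-enumeration p when both samples together have at most 12
#' observations and no ties; otherwise the tie-corrected normal
#' approximation. Two-sided. The U statistic equals
#' `n_a * n_b * AUC(a vs b)` (pair counting with half-credit for ties).
#'
#' @param a,b numeric vectors.
#' @return One-row tibble: `U`, `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  if (length(a) == 1 && length(b) == 1 && a == b) {
    return(tibble(U = 0.5, p = 1))
  }
  no_ties <- !any(duplicated(c(a, b)))
  exact <- (length(a) + length(b) <= 12) && no_ties
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  tibble(U = unname(ht$statistic), p = ht$p.value)
}

#' Interferon-gamma signature scores
#'
#' Per patient, the mean over the signature genes of the across-patient
#' z-score of `log2(TPM + 1)`. Signature genes absent from the TPM table are
#' dropped with a warning; genes constant across patients contribute 0.
#'
#' @param tpm gene-by-patient TPM matrix.
#' @param gene_list character vector of signature genes.
#' @param signature_name label carried into the output.
#' @return Tibble: `patient_id`, `signature_name`, `score`.
#' @export
ifng_signature_score <- function(tpm, gene_list, signature_name = "ifng") {
  present <- intersect(gene_list, rownames(tpm))
  if (length(present) == 0) abort("no signature genes present in the TPM table")
  dropped <- setdiff(gene_list, present)
  if (length(dropped) > 0) {
    warn(paste0("signature genes absent from TPM table, dropped: ",
                paste(dropped, collapse = ", ")))
  }
  lg <- log2(tpm[present, , drop = FALSE] + 1)
  z <- t(apply(lg, 1, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  tibble(
    patient_id = colnames(tpm),
    signature_name = signature_name,
    score = colMeans(z)
  )
}

#' Concordance of a plasma marker with IHC protein status
#'
#' Median-splits the plasma marker values into high/low, cross-tabulates
#' against the IHC high/low status (an upstream slide-review call, consumed
#' as data) and tests association by Fisher's exact test. Patients with
#' missing IHC status are excluded and reported.
#'
#' @param plasma numeric plasma marker values (one per patient).
#' @param ihc character vector of `"high"`/`"low"` IHC calls (NA allowed).
#' @return List: `table` (2x2, plasma x IHC), `p` (Fisher), `n_excluded`.
#' @export
ihc_concordance <- function(plasma, ihc) {
  stopifnot(length(plasma) == length(ihc))
  ok <- !is.na(ihc) & !is.na(plasma)
  n_excluded <- sum(!ok)
  plasma <- plasma[ok]; ihc <- ihc[ok]
  if (length(plasma) < 2) abort("need >=2 patients with IHC status and plasma value")
  split <- factor(median_split(plasma), levels = c("high", "low"))
  ihc <- factor(ihc, levels = c("high", "low"))
  tab <- table(plasma = split, ihc = ihc)
  list(table = tab, p = fisher_exact_2x2(tab), n_excluded = n_excluded)
}
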