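# Candidate-marker discovery: the four-criterion union filter applied to the
# pilot sequencing cohort, followed by a deterministic ranking to a top-k
# candidate list.

#' Score genes against the four discovery criteria
#'
#' For each gene of a log2-CPM matrix, computes the three BOR-grouping
#' contrasts (PR vs PD, PR vs SD/PD, PR/SD vs PD) and two ROC AUCs --
#' AUC1 = max over the non-responder-detecting contrasts (PR vs PD and
#' PR/SD vs PD), AUC2 = PR vs SD/PD -- then records which criteria hold:
#'
#' * C1: any grouping's Welch p below `de_alpha`;
#' * C2: any grouping's |log2 fold change| above `lfc_cutoff`;
#' * C3: AUC1 or AUC2 above `auc_cutoff` (orientation auto-fitted, so AUC is
#'   measured on whichever direction separates);
#' * C4: gene on the literature allowlist.
#'
#' A gene qualifies as a candidate when it meets at least one criterion (a
#' deliberately broad union filter; no multiple-testing correction at this
#' stage).
#'
#' @param expr log2-CPM gene-by-sample matrix.
#' @param bor_labels BOR category per sample.
#' @param config [analysis_config()] with the cutoffs and allowlist.
#' @return A `pex_discovery` tibble: per gene the three p-values and fold
#'   changes, `auc1`, `auc2`, logical criterion columns `c1`-`c4`,
#'   `n_criteria` and `qualifies`.
#' @export
score_discovery_genes <- function(expr, bor_labels, config = analysis_config()) {
  for (grp in c("PR", "SD", "PD")) {
    if (sum(bor_labels == grp) < 2) {
      abort(paste0("BOR group ", grp, " has <2 samples"))
    }
  }
  contrasts <- purrr::map(names(bor_groupings()),
                          ~ group_logfc(expr, bor_labels, .x))
  names(contrasts) <- names(bor_groupings())

  # per-gene AUCs with auto orientation (report max of the two directions)
  auc_for <- function(g1, g2) {
    i1 <- bor_labels %in% g1 # responder-leaning side
    i2 <- bor_labels %in% g2 # non-responder-leaning side = positive class
    apply(expr, 1, function(v) {
      a <- auc_mann_whitney(c(v[i1], v[i2]),
                            c(rep(0L, sum(i1)), rep(1L, sum(i2))))
      max(a, 1 - a)
    })
  }
  auc_pr_pd <- auc_for("PR", "PD")
  auc_prsd_pd <- auc_for(c("PR", "SD"), "PD")
  auc2 <- auc_for("PR", c("SD", "PD"))
  auc1 <- pmax(auc_pr_pd, auc_prsd_pd)

  p_mat <- sapply(contrasts, function(x) x$p_value)
  lfc_mat <- sapply(contrasts, function(x) x$log2_fc)
  genes <- rownames(expr)
  out <- tibble(
    gene = genes,
    p_pr_pd = p_mat[, "PR vs PD"],
    p_pr_sdpd = p_mat[, "PR vs SD/PD"],
    p_prsd_pd = p_mat[, "PR/SD vs PD"],
    lfc_pr_pd = lfc_mat[, "PR vs PD"],
    lfc_pr_sdpd = lfc_mat[, "PR vs SD/PD"],
    lfc_prsd_pd = lfc_mat[, "PR/SD vs PD"],
    auc1 = unname(auc1),
    auc2 = unname(auc2)
  )
  out$c1 <- out$p_pr_pd < config$de_alpha |
    out$p_pr_sdpd < config$de_alpha | out$p_prsd_pd < config$de_alpha
  out$c2 <- pmax(abs(out$lfc_pr_pd), abs(out$lfc_pr_sdpd),
                 abs(out$lfc_prsd_pd)) > config$lfc_cutoff
  out$c3 <- out$auc1 > config$auc_cutoff | out$auc2 > config$auc_cutoff
  out$c4 <- out$gene %in% config$literature_allowlist
  out$n_criteria <- out$c1 + out$c2 + out$c3 + out$c4
  out$qualifies <- out$n_criteria >= 1
  class(out) <- c("pex_discovery", class(out))
  out
}

#' Select the top candidate genes from discovery statistics
#'
#' Qualifying genes (>=1 criterion met) are ranked by: number of criteria met
#' (descending), best AUC `max(auc1, auc2)` (descending), smallest p-value
#' over the three groupings (ascending), then gene symbol (alphabetical) as
#' the final deterministic tie-break. The first `k` are returned; if fewer
#' than `k` qualify, all qualifiers are.
#'
#' @param stats `pex_discovery` tibble from [score_discovery_genes()].
#' @param k number of candidates to keep (default 20).
#' @return Character vector of gene symbols, best first.
#' @export
select_candidates <- function(stats, k = 20L) {
  q <- stats[stats$qualifies, ]
  if (nrow(q) == 0) return(character())
  q$max_auc <- pmax(q$auc1, q$auc2)
  q$min_p <- pmin(q$p_pr_pd, q$p_pr_sdpd, q$p_prsd_pd)
  q <- arrange(q, desc(n_criteria), desc(max_auc), min_p, gene)
  head(q$gene, k)
}
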