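#' Marker panel used by the validated prognostic combination
#'
#' The six exosomal mRNA markers carried through response-prediction and
#' survival analysis, with their directions: "unfavorable" markers are
#' elevated in non-responders (a vote fires when the value exceeds the
#' threshold), "favorable" markers are elevated in responders (a vote fires
#' when the value falls below the threshold). The neutrophil-to-lymphocyte
#' ratio (NLR) is handled as an additional unfavorable marker.
#'
#' @return Named character vector mapping marker to direction.
#' @export
default_marker_directions <- function() {
  c(
    "HLA-E"     = "unfavorable",
    "ACTB"      = "unfavorable",
    "MPIG6B"    = "unfavorable",
    "TNFRSF13C" = "unfavorable",
    "RABL2B"    = "favorable",
    "ZNF480"    = "favorable"
  )
}

#' Default IFN-gamma signature gene lists
#'
#' The 6-gene "preliminary" and 18-gene "expanded" interferon-gamma-related
#' signatures widely used as tissue biomarkers of PD-1 blockade response.
#' These defaults are editable: pass your own lists through
#' [analysis_config()] if your annotation differs.
#'
#' @return Named list with elements `ifng_6` and `ifng_18`.
#' @export
default_signature_gene_lists <- function() {
  list(
    ifng_6 = c("IFNG", "STAT1", "IDO1", "CXCL10", "CXCL9", "HLA-DRA"),
    ifng_18 = c(
      "CCL5", "CD27", "CD274", "CD276", "CD8A", "CMKLR1", "CXCL9", "CXCR6",
      "HLA-DQA1", "HLA-DRB1", "HLA-E", "IDO1", "LAG3", "NKG7", "PDCD1LG2",
      "PSMB10", "STAT1", "TIGIT"
    )
  )
}

#' Analysis configuration
#'
#' Collects every tunable the pipeline uses: the qPCR reference gene, marker
#' directions, discovery filter cutoffs, combination-search bounds and the
#' random seed. Invariants are checked on construction.
#'
#' @param reference_gene qPCR reference gene symbol; its Ct normalizes all
#'   marker Cts (delta-Ct method).
#' @param marker_directions named character vector mapping each marker gene to
#'   `"unfavorable"` or `"favorable"`.
#' @param nlr_included should the neutrophil-to-lymphocyte ratio enter the
#'   combination search as an extra (unfavorable) marker?
#' @param combination_size_min,combination_size_max subset sizes enumerated by
#'   [rank_combinations()]. The default starts at 2: singleton "combinations"
#'   are the per-marker ROC analyses and are assessed separately.
#' @param top_k_combinations how many ranked combinations to keep.
#' @param de_alpha significance cutoff for the discovery filter's
#'   differential-expression criterion.
#' @param lfc_cutoff absolute log2 fold-change cutoff for the discovery filter.
#' @param auc_cutoff AUC cutoff (in (0.5, 1)) for the discovery filter.
#' @param literature_allowlist genes admitted to discovery regardless of
#'   statistics (prior-evidence criterion).
#' @param signature_gene_lists named list of gene vectors for signature
#'   scoring; see [default_signature_gene_lists()].
#' @param rng_seed integer seed governing all stochastic stages.
#' @param censor_horizon_months administrative censoring horizon (months).
#'
#' @return An object of class `pex_config` (a named list).
#' @export
analysis_config <- function(reference_gene = "GAPDH",
                            marker_directions = default_marker_directions(),
                            nlr_included = TRUE,
                            combination_size_min = 2L,
                            combination_size_max = NULL,
                            top_k_combinations = 10L,
                            de_alpha = 0.05,
                            lfc_cutoff = 1.5,
                            auc_cutoff = 0.7,
                            literature_allowlist = character(),
                            signature_gene_lists = default_signature_gene_lists(),
                            rng_seed = 1L,
                            censor_horizon_months = 36) {
  stopifnot(
    is.character(reference_gene), length(reference_gene) == 1L,
    is.character(marker_directions), !is.null(names(marker_directions))
  )
  bad <- setdiff(unique(marker_directions), c("unfavorable", "favorable"))
  if (length(bad) > 0) {
    abort(paste0("unknown marker direction(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(names(marker_directions))) {
    abort("each marker must map to exactly one direction")
  }
  n_markers <- length(marker_directions) + as.integer(isTRUE(nlr_included))
  if (is.null(combination_size_max)) combination_size_max <- n_markers
  if (!(combination_size_min >= 1 &&
        combination_size_min <= combination_size_max &&
        combination_size_max <= n_markers)) {
    abort("need 1 <= combination_size_min <= combination_size_max <= number of markers")
  }
  if (!(de_alpha > 0 && de_alpha < 1)) abort("de_alpha must be in (0,1)")
  if (lfc_cutoff < 0) abort("lfc_cutoff must be non-negative")
  if (!(auc_cutoff > 0.5 && auc_cutoff < 1)) abort("auc_cutoff must be in (0.5,1)")
  if (censor_horizon_months < 0) abort("censor_horizon_months must be >= 0")

  structure(
    list(
      reference_gene = reference_gene,
      marker_directions = marker_directions,
      nlr_included = isTRUE(nlr_included),
      combination_size_min = as.integer(combination_size_min),
      combination_size_max = as.integer(combination_size_max),
      top_k_combinations = as.integer(top_k_combinations),
      de_alpha = de_alpha,
      lfc_cutoff = lfc_cutoff,
      auc_cutoff = auc_cutoff,
      literature_allowlist = literature_allowlist,
      signature_gene_lists = signature_gene_lists,
      rng_seed = as.integer(rng_seed),
      censor_horizon_months = censor_horizon_months
    ),
    class = "pex_config"
  )
}

#' @export
print.pex_config <- function(x, ...) {
  cat("<pex_config>\n")
  cat("  reference gene:      ", x$reference_gene, "\n")
  cat("  markers:             ",
      paste0(names(x$marker_directions), " (",
             substr(x$marker_directions, 1, 5), ")", collapse = ", "), "\n")
  cat("  NLR included:        ", x$nlr_included, "\n")
  cat("  combination sizes:   ", x$combination_size_min, "-",
      x$combination_size_max, "\n")
  cat("  discovery cutoffs:    p <", x$de_alpha, ", |log2FC| >", x$lfc_cutoff,
      ", AUC >", x$auc_cutoff, "\n")
  invisible(x)
}

# BOR vocabulary, ordered from best to worst response.
bor_levels <- function() c("CR", "PR", "SD", "PD", "NE")

#' Responder dichotomy from best overall response
#'
#' Responders are CR + PR; non-responders SD + PD + NE. This is the dichotomy
#' behind every response ROC analysis in the pipeline, with the non-responder
#' as the positive class.
#'
#' @param bor character vector of BOR categories.
#' @return Logical vector, `TRUE` for responders.
#' @export
is_responder <- function(bor) {
  bad <- setdiff(unique(bor), bor_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown BOR categories: ", paste(bad, collapse = ", ")))
  }
  bor %in% c("CR", "PR")
}

#' Cohort response-rate summary
#'
#' Tabulates best-overall-response counts and percentages and the
#' responder/non-responder split.
#'
#' @param bor character vector of BOR categories (one per patient), or a
#'   clinical table with a `bor` column.
#' @return A tibble with one row per BOR category (count, percent) plus
#'   attributes `n_responders` / `n_nonresponders`.
#' @export
summarize_bor <- function(bor) {
  if (is.data.frame(bor)) bor <- bor$bor
  bad <- setdiff(unique(bor), bor_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown BOR categories: ", paste(bad, collapse = ", ")))
  }
  n_total <- length(bor)
  counts <- table(factor(bor, levels = bor_levels()))
  out <- tibble(
    bor = names(counts),
    n = as.integer(counts),
    percent = round(100 * as.integer(counts) / n_total, 1)
  )
  attr(out, "n_responders") <- sum(is_responder(bor))
  attr(out, "n_nonresponders") <- sum(!is_responder(bor))
  out
}
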