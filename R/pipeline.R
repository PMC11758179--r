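# End-to-end orchestration of the two study stages, with a machine-readable
# run manifest (row counts and explicit exclusions at every step).

#' Run the part-1 validation pipeline
#'
#' Delta-Ct normalization, per-marker ROC threshold fitting, exhaustive
#' threshold-vote combination ranking, and score-stratified survival
#' analysis (Kaplan-Meier, log-rank, Cox) for each top combination. The
#' combination with the highest converged hazard ratio (ties: lowest Wald p)
#' is selected as the frozen prognostic score. Deterministic given its
#' inputs and the config seed.
#'
#' @param clinical a clinical tibble or a CSV path (see
#'   [read_clinical_table()]).
#' @param config [analysis_config()].
#' @param outdir optional directory; when given, writes `combinations.csv`,
#'   `km.csv`, `tests.json` and `manifest.json`.
#' @return A `pex_part1` list: `config`, `rules`, `combinations`,
#'   `survival` (per-combination HR / log-rank / 2-year OS tibble),
#'   `selected` (frozen rules + score threshold), `km` (step functions for
#'   the selected stratification) and `manifest`.
#' @export
run_part1 <- function(clinical, config = analysis_config(), outdir = NULL) {
  table <- if (is.character(clinical)) {
    read_clinical_table(clinical, config)
  } else {
    validate_clinical_table(clinical, config)
  }
  set.seed(config$rng_seed)
  markers <- c(names(config$marker_directions),
               if (config$nlr_included) "NLR")

  rules <- fit_marker_rules(table, markers, config)
  combos <- rank_combinations(table, rules, config)

  surv_rows <- purrr::map(seq_len(nrow(combos)), function(i) {
    members <- combos$members[[i]]
    applied <- apply_frozen_combination(members, combos$threshold[i], table,
                                        config$reference_gene)
    keep <- !is.na(applied$score)
    grp <- as.integer(applied$label[keep] == "score_high")
    t_ <- table$os_months[keep]
    e_ <- table$os_event[keep]
    lr <- logrank_test(t_, e_, grp)
    cx <- cox_binary(t_, e_, grp)
    km_hi <- km_estimator(t_[grp == 1], e_[grp == 1])
    km_lo <- km_estimator(t_[grp == 0], e_[grp == 0])
    tibble(
      rank = combos$rank[i], markers = combos$markers[i],
      n_high = sum(grp == 1), n_low = sum(grp == 0),
      hr = cx$hr, hr_ci_low = cx$ci95[["low"]], hr_ci_high = cx$ci95[["high"]],
      cox_p = cx$wald_p, cox_converged = cx$converged,
      logrank_chi2 = lr$chi2, logrank_p = lr$p,
      os24_high = survival_at(km_hi, 24), os24_low = survival_at(km_lo, 24)
    )
  })
  surv <- bind_rows(surv_rows)

  ok <- surv$cox_converged
  sel_i <- which(ok)[order(-surv$hr[ok], surv$cox_p[ok])][1]
  selected <- list(
    rank = surv$rank[sel_i],
    markers = surv$markers[sel_i],
    rules = combos$members[[sel_i]],
    threshold_score = combos$threshold[sel_i]
  )

  applied <- apply_frozen_combination(selected$rules, selected$threshold_score,
                                      table, config$reference_gene)
  keep <- !is.na(applied$score)
  km <- km_strata(table$os_months[keep], table$os_event[keep],
                  applied$label[keep])

  manifest <- list(
    stage = "part1",
    seed = config$rng_seed,
    n_input = nrow(table),
    n_analyzed = sum(keep),
    exclusions = applied[!keep, c("patient_id", "exclusion_reason")],
    n_combinations_tested = choose_total(length(markers),
                                         config$combination_size_min,
                                         config$combination_size_max),
    selected_combination = selected$markers,
    package_version = as.character(utils::packageVersion("pexvote"))
  )

  out <- structure(
    list(config = config, rules = rules, combinations = combos,
         survival = surv, selected = selected, km = km, manifest = manifest),
    class = "pex_part1"
  )
  if (!is.null(outdir)) write_part1_outputs(out, outdir)
  out
}

choose_total <- function(n, k_min, k_max) {
  sum(vapply(seq(k_min, k_max), function(k) choose(n, k), 0))
}

write_part1_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_combination_table(res$combinations, file.path(outdir, "combinations.csv"))
  readr::write_csv(res$km, file.path(outdir, "km.csv"))
  jsonlite::write_json(
    list(survival = res$survival,
         selected = list(
           rank = res$selected$rank,
           markers = res$selected$markers,
           threshold_score = res$selected$threshold_score,
           rules = as.data.frame(res$selected$rules)
         )),
    file.path(outdir, "tests.json"), auto_unbox = TRUE, digits = NA
  )
  m <- res$manifest
  m$exclusions <- as.data.frame(m$exclusions)
  jsonlite::write_json(m, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.pex_part1 <- function(x, ...) {
  cat("<pex_part1> ", x$manifest$n_analyzed, "/", x$manifest$n_input,
      " patients analyzed; top combination by AUC: ",
      x$combinations$markers[1],
      sprintf(" (AUC %.3f)", x$combinations$auc[1]), "\n", sep = "")
  cat("  frozen prognostic combination: ", x$selected$markers,
      sprintf(" (score threshold %.3f, HR %.2f)", x$selected$threshold_score,
              x$survival$hr[x$survival$rank == x$selected$rank]), "\n", sep = "")
  invisible(x)
}

#' Run the part-2 tumor-correlation pipeline
#'
#' Applies a frozen part-1 combination to the treatment-naive plasma cohort,
#' then computes: per-marker Pearson correlation of plasma -dCt with tumor
#' TPM (tumor-profiled patients only), plasma-vs-IHC concordance for the key
#' marker (median split + Fisher's exact test), and median-split
#' Mann-Whitney comparisons of CPS, IFN-gamma signature scores and immune
#' fractions between plasma-high and plasma-low patients.
#'
#' @param part2 list with `plasma`, `tumor_tpm`, `ihc`, `fractions` as
#'   produced by [simulate_part2_cohort()] (or read from the equivalent
#'   files).
#' @param frozen list with `rules` (a `pex_rules` tibble) and
#'   `threshold_score`, e.g. `run_part1(...)$selected`.
#' @param config [analysis_config()].
#' @param key_gene plasma marker used for the IHC concordance and the
#'   median-split comparisons (default `"HLA-E"`).
#' @return A `pex_part2` list: `labels`, `pearson`, `ihc`, `split_tests`,
#'   `signatures`, `manifest`.
#' @export
run_part2 <- function(part2, frozen, config = analysis_config(),
                      key_gene = "HLA-E") {
  if (is.null(frozen$rules) || is.null(frozen$threshold_score)) {
    abort("frozen combination (rules + threshold_score) from a part-1 run is required")
  }
  plasma <- part2$plasma
  genes <- names(config$marker_directions)
  labels <- apply_frozen_combination(frozen$rules, frozen$threshold_score,
                                     plasma, config$reference_gene)

  expr <- delta_ct(plasma, config$reference_gene)
  plasma_wide <- tidyr::pivot_wider(expr, id_cols = "patient_id",
                                    names_from = "gene",
                                    values_from = "neg_delta_ct")

  tumor_ids <- colnames(part2$tumor_tpm)
  pearson <- purrr::map_dfr(intersect(genes, rownames(part2$tumor_tpm)),
                            function(g) {
    i <- match(tumor_ids, plasma_wide$patient_id)
    pt <- pearson_test(plasma_wide[[g]][i], part2$tumor_tpm[g, ])
    mutate(pt, gene = g, .before = 1)
  })

  # plasma key-marker vs IHC protein call, all patients with IHC status
  i_all <- match(part2$ihc$patient_id, plasma_wide$patient_id)
  conc <- ihc_concordance(plasma_wide[[key_gene]][i_all],
                          part2$ihc$ihc_hla_e)

  # median-split comparisons: CPS on the full cohort, signature scores and
  # fractions on the tumor-profiled subset (split recomputed within it)
  split_all <- median_split(plasma_wide[[key_gene]][i_all])
  cps_test <- mann_whitney_u(part2$ihc$cps[split_all == "high"],
                             part2$ihc$cps[split_all == "low"])

  i_tum <- match(tumor_ids, plasma_wide$patient_id)
  split_tum <- median_split(plasma_wide[[key_gene]][i_tum])
  split_tbl <- tibble(patient_id = tumor_ids, split = split_tum)

  sigs <- purrr::imap_dfr(config$signature_gene_lists, function(gl, nm) {
    sc <- ifng_signature_score(part2$tumor_tpm, gl, nm)
    sc <- left_join(sc, split_tbl, by = "patient_id")
    mw <- mann_whitney_u(sc$score[sc$split == "high"],
                         sc$score[sc$split == "low"])
    tibble(signature_name = nm, U = mw$U, p = mw$p)
  })

  frac_tests <- if (is.null(part2$fractions) || nrow(part2$fractions) == 0) {
    warn("empty immune-fraction table: fraction comparisons skipped")
    tibble(cell_type = character(), U = numeric(), p = numeric())
  } else {
    fr <- left_join(part2$fractions, split_tbl, by = "patient_id")
    fr %>%
      group_by(cell_type) %>%
      dplyr::group_modify(~ mann_whitney_u(.x$fraction[.x$split == "high"],
                                           .x$fraction[.x$split == "low"])) %>%
      ungroup()
  }

  manifest <- list(
    stage = "part2",
    n_plasma = nrow(plasma),
    n_tumor_profiled = length(tumor_ids),
    n_missing_tumor = nrow(plasma) - length(tumor_ids),
    n_score_high = sum(labels$label == "score_high", na.rm = TRUE),
    n_score_low = sum(labels$label == "score_low", na.rm = TRUE),
    exclusions = labels[is.na(labels$score),
                        c("patient_id", "exclusion_reason")],
    frozen_combination = paste(frozen$rules$marker, collapse = " "),
    frozen_threshold = frozen$threshold_score
  )

  structure(
    list(labels = labels, pearson = pearson,
         ihc = conc,
         split_tests = bind_rows(
           tibble(cell_type = "CPS", U = cps_test$U, p = cps_test$p),
           frac_tests
         ),
         signatures = sigs,
         manifest = manifest),
    class = "pex_part2"
  )
}

#' @export
print.pex_part2 <- function(x, ...) {
  cat("<pex_part2> ", x$manifest$n_plasma, " plasma patients (",
      x$manifest$n_tumor_profiled, " tumor-profiled); ",
      x$manifest$n_score_low, " survivor-signature / ",
      x$manifest$n_score_high, " non-survivor-signature\n", sep = "")
  cat("  IHC concordance Fisher p: ", format(x$ihc$p, digits = 3), "\n")
  invisible(x)
}
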