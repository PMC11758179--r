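# Directional threshold-vote combinations: each marker rule casts a 0/1
# "non-responder" vote, a combination's score is the mean vote, and all
# marker subsets are ranked by the AUC of that score.

#' Build a table of marker rules
#'
#' @param marker character vector of marker names (gene symbols, or `"NLR"`).
#' @param direction `"unfavorable"` (elevated in non-responders; vote fires
#'   above the threshold) or `"favorable"` (elevated in responders; vote
#'   fires below).
#' @param threshold decision threshold per marker, on the -dCt scale for
#'   genes and the raw ratio scale for NLR.
#' @return A tibble with columns `marker`, `direction`, `threshold` (class
#'   `pex_rules`).
#' @export
marker_rules <- function(marker, direction, threshold) {
  stopifnot(length(marker) == length(direction),
            length(marker) == length(threshold))
  if (anyDuplicated(marker)) abort("duplicate marker in rule set")
  bad <- setdiff(unique(direction), c("unfavorable", "favorable"))
  if (length(bad) > 0) abort(paste0("unknown direction: ", paste(bad, collapse = ", ")))
  if (!all(is.finite(threshold))) abort("rule thresholds must be finite")
  out <- tibble(marker = marker, direction = direction, threshold = threshold)
  class(out) <- c("pex_rules", class(out))
  out
}

#' Cast a single marker vote
#'
#' An unfavorable rule votes 1 when the value strictly exceeds its threshold;
#' a favorable rule votes 1 when the value falls strictly below. Equality
#' never fires a vote.
#'
#' @param direction `"unfavorable"` or `"favorable"`.
#' @param threshold finite threshold.
#' @param value measured marker value(s).
#' @return Integer 0/1 vector of votes.
#' @export
vote <- function(direction, threshold, value) {
  if (anyNA(value)) abort("vote() requires measured values; exclude the patient upstream")
  direction <- arg_match(direction, c("unfavorable", "favorable"))
  if (direction == "unfavorable") as.integer(value > threshold)
  else as.integer(value < threshold)
}

#' Threshold-vote combination score
#'
#' Mean of the member votes: 0 means no marker in the combination predicted a
#' non-responder, 1 that all did; the image is `{0, 1/m, ..., 1}`.
#'
#' @param rules a `pex_rules` tibble (the combination's members).
#' @param values data frame or matrix of marker values, one row per patient,
#'   columns named by marker. Patients with any member marker missing get
#'   `NA` (to be excluded, never scored 0).
#' @return Numeric vector of scores, one per row of `values`.
#' @export
combination_score <- function(rules, values) {
  values <- as.data.frame(values)
  missing_cols <- setdiff(rules$marker, names(values))
  if (length(missing_cols) > 0) {
    abort(paste0("no measurements for marker(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  votes <- vapply(seq_len(nrow(rules)), function(i) {
    v <- values[[rules$marker[i]]]
    out <- rep(NA_integer_, length(v))
    ok <- !is.na(v)
    if (any(ok)) {
      out[ok] <- vote(rules$direction[i], rules$threshold[i], v[ok])
    }
    out
  }, integer(nrow(values)))
  votes <- matrix(votes, nrow = nrow(values))
  rowMeans(votes) # NA wherever any member vote is NA
}

#' Enumerate marker subsets
#'
#' Every subset of the given markers with size in `[size_min, size_max]`,
#' exactly once, in deterministic order: by size, then lexicographically on
#' marker names.
#'
#' @param markers character vector of marker names.
#' @param size_min,size_max inclusive subset-size bounds.
#' @return List of character vectors (each sorted, NLR last).
#' @export
enumerate_combinations <- function(markers, size_min = 2L,
                                   size_max = length(markers)) {
  if (size_min < 1 || size_min > size_max || size_max > length(markers)) {
    abort("need 1 <= size_min <= size_max <= length(markers)")
  }
  ordered <- order_markers(markers)
  out <- list()
  for (m in seq(size_min, size_max)) {
    subsets <- combn(ordered, m, simplify = FALSE)
    out <- c(out, subsets)
  }
  out
}

# genes alphabetical, NLR always last
order_markers <- function(markers) {
  genes <- sort(setdiff(markers, "NLR"))
  c(genes, intersect("NLR", markers))
}

#' Per-patient marker value matrix on the scales the rules use
#'
#' Genes on the -dCt scale (via [delta_ct()]), NLR raw. One row per patient.
#'
#' @param table clinical tibble.
#' @param markers marker names to extract.
#' @param reference_gene qPCR reference gene.
#' @return Tibble: `patient_id`, `bor`, one column per marker.
#' @export
marker_values <- function(table, markers, reference_gene = "GAPDH") {
  genes <- setdiff(markers, "NLR")
  out <- tibble(
    patient_id = table$patient_id,
    bor = if ("bor" %in% names(table)) table$bor else NA_character_
  )
  if (length(genes) > 0) {
    expr <- delta_ct(table, reference_gene)
    wide <- tidyr::pivot_wider(expr, id_cols = "patient_id",
                               names_from = "gene",
                               values_from = "neg_delta_ct")
    missing_genes <- setdiff(genes, names(wide))
    if (length(missing_genes) > 0) {
      abort(paste0("gene(s) not assayed in the clinical table: ",
                   paste(missing_genes, collapse = ", ")))
    }
    out <- left_join(out, wide[, c("patient_id", genes)], by = "patient_id")
  }
  if ("NLR" %in% markers) out$NLR <- table$nlr
  out
}

#' Fit directional rules for each marker on a training cohort
#'
#' For every marker, computes its ROC against the responder/non-responder
#' dichotomy (positive class = non-responder), auto-fits the orientation so
#' AUC >= 0.5 (unfavorable = elevated in non-responders), and selects the
#' nearest-top-left threshold. Thresholds fit here are frozen and reused
#' inside every combination; there is no per-combination refitting.
#'
#' @param table clinical tibble.
#' @param markers marker names (genes and/or `"NLR"`). Default: the six panel
#'   genes plus NLR.
#' @param config [analysis_config()].
#' @param directions `"auto"` (orient each marker by its empirical AUC) or a
#'   named vector of fixed directions.
#' @return A `pex_rules` tibble with an extra `auc` column (the solo AUC of
#'   each marker under its fitted orientation).
#' @export
fit_marker_rules <- function(table,
                             markers = c(names(config$marker_directions),
                                         if (config$nlr_included) "NLR"),
                             config = analysis_config(),
                             directions = "auto") {
  vals <- marker_values(table, markers, config$reference_gene)
  positive <- !is_responder(vals$bor) # non-responder = positive class
  rows <- purrr::map(markers, function(mk) {
    v <- vals[[mk]]
    ok <- !is.na(v)
    if (identical(directions, "auto")) {
      a_hi <- auc_mann_whitney(v[ok], positive[ok], "higher_is_positive")
      dir <- if (a_hi >= 0.5) "unfavorable" else "favorable"
    } else {
      dir <- unname(directions[[mk]])
    }
    orient <- if (dir == "unfavorable") "higher_is_positive" else "lower_is_positive"
    roc <- roc_curve(v[ok], positive[ok], orientation = orient)
    cut <- select_threshold_topleft(roc)
    tibble(marker = mk, direction = dir,
           threshold = cut$threshold, auc = roc$auc)
  })
  out <- bind_rows(rows)
  class(out) <- c("pex_rules", class(out))
  out
}

#' Exhaustively rank threshold-vote combinations by AUC
#'
#' Enumerates every marker subset in the configured size range, scores every
#' eligible patient (patients missing any member marker are excluded from
#' that combination), computes the score's AUC for non-responder detection
#' with its DeLong CI, selects the nearest-top-left score threshold and the
#' confusion metrics at it, and returns the top combinations sorted by AUC
#' (ties: fewer markers first, then lexicographic).
#'
#' @param table clinical tibble.
#' @param rules `pex_rules` tibble with frozen per-marker thresholds, e.g.
#'   from [fit_marker_rules()].
#' @param config [analysis_config()]; supplies size bounds and `top_k`.
#' @param top_k number of combinations to keep (default from config).
#' @return A tibble (class `pex_combinations`) with columns `rank`,
#'   `markers` (space-joined, genes alphabetical then NLR), `m`, `auc`,
#'   `auc_ci_low`, `auc_ci_high`, `threshold`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `n_used`, `n_excluded`, and a list-column `members`.
#' @export
rank_combinations <- function(table, rules, config = analysis_config(),
                              top_k = config$top_k_combinations) {
  vals <- marker_values(table, rules$marker, config$reference_gene)
  positive <- !is_responder(vals$bor)
  if (sum(positive) < 2 || sum(!positive) < 2) {
    abort("need >=2 patients in each response class")
  }
  subsets <- enumerate_combinations(rules$marker,
                                    config$combination_size_min,
                                    config$combination_size_max)
  rows <- purrr::map(subsets, function(members) {
    sub_rules <- rules[match(members, rules$marker), ]
    sc <- combination_score(sub_rules, vals)
    ok <- !is.na(sc)
    roc <- roc_curve(sc[ok], positive[ok])
    cut <- select_threshold_topleft(roc)
    tibble(
      markers = paste(members, collapse = " "),
      m = length(members),
      auc = roc$auc,
      auc_ci_low = roc$auc_ci[["low"]],
      auc_ci_high = roc$auc_ci[["high"]],
      threshold = cut$threshold,
      sensitivity = cut$sensitivity,
      specificity = cut$specificity,
      ppv = cut$ppv,
      npv = cut$npv,
      n_used = sum(ok),
      n_excluded = sum(!ok),
      members = list(sub_rules)
    )
  })
  out <- bind_rows(rows) %>%
    arrange(desc(auc), m, markers) %>%
    mutate(rank = row_number()) %>%
    select(rank, dplyr::everything())
  out <- head(out, top_k)
  class(out) <- c("pex_combinations", class(out))
  out
}

#' Apply a frozen combination to a new cohort
#'
#' Scores each patient with frozen per-marker thresholds and labels them
#' `score_high` (predicted non-responder / non-survivor signature) when the
#' score strictly exceeds the frozen score threshold, `score_low` otherwise.
#' Nothing is refit. Patients missing a member marker are excluded, with the
#' reason recorded.
#'
#' @param rules `pex_rules` tibble with frozen thresholds (the combination's
#'   members).
#' @param threshold_score frozen score cut from the training cohort.
#' @param table clinical tibble (or any table [marker_values()] accepts).
#' @param reference_gene qPCR reference gene.
#' @return Tibble: `patient_id`, `score`, `label` in
#'   `{score_high, score_low}` (`NA` label + `exclusion_reason` for excluded
#'   patients).
#' @export
apply_frozen_combination <- function(rules, threshold_score, table,
                                     reference_gene = "GAPDH") {
  vals <- marker_values(table, rules$marker, reference_gene)
  sc <- combination_score(rules, vals)
  tibble(
    patient_id = vals$patient_id,
    score = sc,
    label = dplyr::if_else(sc > threshold_score, "score_high", "score_low"),
    exclusion_reason = dplyr::if_else(is.na(sc), "missing member marker",
                                      NA_character_)
  )
}

#' @export
print.pex_combinations <- function(x, ...) {
  cat("<pex_combinations> top", nrow(x), "threshold-vote combinations\n")
  NextMethod()
}

#' @exportS3Method generics::tidy
tidy.pex_combinations <- function(x, ...) {
  as_tibble(x[, setdiff(names(x), "members")])
}

#' @rdname plot_combinations
#' @export
autoplot.pex_combinations <- function(object, ...) {
  df <- tidy(object)
  df$markers <- factor(df$markers, levels = rev(df$markers))
  ggplot2::ggplot(df, ggplot2::aes(x = auc, y = markers)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$auc_ci_low,
                                          xmax = .data$auc_ci_high)) +
    ggplot2::labs(x = "AUC (95% CI)", y = NULL,
                  title = "Ranked threshold-vote combinations") +
    ggplot2::theme_minimal()
}

#' Plot ranked combinations as an AUC forest plot
#'
#' @param object a `pex_combinations` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
plot_combinations <- function(object, ...) autoplot.pex_combinations(object, ...)
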