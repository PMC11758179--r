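# Empirical ROC machinery: Mann-Whitney AUC, DeLong variance, candidate
# thresholds as midpoints between consecutive distinct observed scores, and
# nearest-top-left threshold selection.

check_binary_labels <- function(labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) abort("labels must be binary (0/1 or logical)")
  if (length(unique(labels)) < 2) {
    abort("both classes must be present (single-class input)")
  }
  as.integer(labels)
}

orient_scores <- function(scores, orientation) {
  orientation <- arg_match(orientation, c("higher_is_positive", "lower_is_positive"))
  if (orientation == "lower_is_positive") -scores else scores
}

#' Mann-Whitney (rank) estimate of the ROC AUC
#'
#' Tie-corrected probability that a positive scores above a negative:
#' `(#\{pos > neg\} + 0.5 * #\{pos = neg\}) / (n_pos * n_neg)`, computed via
#' ranks in O(n log n).
#'
#' @param scores numeric vector.
#' @param labels binary vector, 1 = positive class.
#' @param orientation `"higher_is_positive"` (default) or
#'   `"lower_is_positive"` (scores are negated internally).
#' @return The AUC, a number in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels,
                             orientation = "higher_is_positive") {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores)) abort("scores must not contain NA")
  s <- orient_scores(scores, orientation)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  r <- rank(s, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong placement values via midranks (O(n log n)): for each positive, the
# fraction of negatives it beats (ties half); symmetrically for negatives.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  n_pos <- length(pos)
  n_neg <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(n_pos)] - r_pos) / n_neg
  v01 <- 1 - (r_all[n_pos + seq_len(n_neg)] - r_neg) / n_pos
  list(v10 = v10, v01 = v01)
}

#' DeLong confidence interval for an AUC
#'
#' Nonparametric variance from per-observation placement values, normal
#' approximation, interval clipped to \[0, 1\]. Perfectly separated data have
#' zero placement variance and yield a degenerate interval at the AUC.
#'
#' @inheritParams auc_mann_whitney
#' @param alpha two-sided error rate (default 0.05 for a 95% interval).
#' @return Named numeric vector `c(low, high)`.
#' @export
delong_ci <- function(scores, labels, alpha = 0.05,
                      orientation = "higher_is_positive") {
  labels <- check_binary_labels(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos < 2 || n_neg < 2) {
    abort("DeLong CI needs >=2 observations in each class")
  }
  s <- orient_scores(scores, orientation)
  auc <- auc_mann_whitney(s, labels)
  pl <- delong_placements(s, labels)
  v <- var(pl$v10) / n_pos + var(pl$v01) / n_neg
  z <- qnorm(1 - alpha / 2)
  half <- z * sqrt(v)
  c(low = max(0, auc - half), high = min(1, auc + half))
}

#' Empirical ROC curve
#'
#' Computes sensitivity and specificity over every candidate threshold --
#' the midpoints between consecutive distinct observed scores, padded with
#' infinite sentinels -- together with the Mann-Whitney AUC and its DeLong
#' 95% CI. Under `higher_is_positive`, observations strictly above a
#' threshold are called positive.
#'
#' @inheritParams auc_mann_whitney
#' @param alpha error rate for the DeLong interval.
#' @return A `pex_roc` object: list with `thresholds`, `sensitivity`,
#'   `specificity` (aligned vectors, thresholds increasing on the working
#'   scale), `auc`, `auc_ci`, `orientation`, class sizes, and the input
#'   scores/labels (needed to derive confusion counts at a chosen cut).
#' @export
roc_curve <- function(scores, labels, orientation = "higher_is_positive",
                      alpha = 0.05) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores)) abort("scores must not contain NA")
  s <- orient_scores(scores, orientation)
  u <- sort(unique(s))
  thr_work <- c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  # cumulative class counts at each distinct value give the whole curve
  iu <- match(s, u)
  cum_pos <- cumsum(tabulate(iu[labels == 1L], nbins = length(u)))
  cum_neg <- cumsum(tabulate(iu[labels == 0L], nbins = length(u)))
  sens <- (n_pos - c(0, cum_pos)) / n_pos
  spec <- c(0, cum_neg) / n_neg
  # report thresholds on the original score scale
  thr <- if (identical(orientation, "lower_is_positive")) -thr_work else thr_work
  structure(
    list(
      thresholds = thr,
      sensitivity = sens,
      specificity = spec,
      auc = auc_mann_whitney(s, labels),
      auc_ci = if (n_pos >= 2 && n_neg >= 2) {
        delong_ci(s, labels, alpha = alpha)
      } else {
        c(low = NA_real_, high = NA_real_)
      },
      orientation = arg_match(orientation,
                              c("higher_is_positive", "lower_is_positive")),
      positive_class_size = n_pos,
      negative_class_size = n_neg,
      scores = scores,
      labels = labels
    ),
    class = "pex_roc"
  )
}

#' @export
print.pex_roc <- function(x, ...) {
  cat("<pex_roc> AUC ", format(round(x$auc, 3)),
      " (95% CI ", format(round(x$auc_ci[["low"]], 3)), "-",
      format(round(x$auc_ci[["high"]], 3)), "), ",
      x$positive_class_size, " positives / ",
      x$negative_class_size, " negatives, ", x$orientation, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pex_roc <- function(x, ...) {
  tibble(
    threshold = x$thresholds,
    sensitivity = x$sensitivity,
    specificity = x$specificity
  )
}

#' @exportS3Method generics::glance
glance.pex_roc <- function(x, ...) {
  tibble(
    auc = x$auc,
    auc_ci_low = x$auc_ci[["low"]],
    auc_ci_high = x$auc_ci[["high"]],
    n_positive = x$positive_class_size,
    n_negative = x$negative_class_size,
    orientation = x$orientation
  )
}

#' @rdname plot_roc
#' @export
autoplot.pex_roc <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(intercept = 0, slope = 1,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (AUC %.3f, 95%% CI %.3f-%.3f)",
                      object$auc, object$auc_ci[["low"]],
                      object$auc_ci[["high"]])
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object a `pex_roc` object from [roc_curve()].
#' @param ... unused.
#' @return A ggplot.
#' @export
plot_roc <- function(object, ...) autoplot.pex_roc(object, ...)

#' Confusion metrics at a fixed threshold
#'
#' Under `higher_is_positive`, scores strictly above the threshold are called
#' positive (equality classifies low, matching the strict voting rule used
#' throughout). ppv/npv are computed from the observed counts, or -- when a
#' prevalence is supplied -- by Bayes' rule from sensitivity, specificity and
#' that prevalence:
#' `ppv = sens*pi / (sens*pi + (1-spec)*(1-pi))`,
#' `npv = spec*(1-pi) / (spec*(1-pi) + (1-sens)*pi)`.
#'
#' @inheritParams auc_mann_whitney
#' @param threshold finite decision threshold.
#' @param prevalence_override optional prior probability of the positive
#'   class used for ppv/npv in place of the empirical prevalence.
#' @return A one-row tibble (class `pex_confusion` prepended): threshold,
#'   sensitivity, specificity, ppv, npv, tp, fp, tn, fn.
#' @export
confusion_at <- function(scores, labels, threshold,
                         orientation = "higher_is_positive",
                         prevalence_override = NULL) {
  labels <- check_binary_labels(labels)
  if (length(scores) == 0) abort("empty input")
  if (!is.finite(threshold)) abort("threshold must be finite")
  s <- orient_scores(scores, orientation)
  t <- if (identical(orientation, "lower_is_positive")) -threshold else threshold
  call_pos <- s > t
  tp <- sum(call_pos & labels == 1L)
  fp <- sum(call_pos & labels == 0L)
  fn <- sum(!call_pos & labels == 1L)
  tn <- sum(!call_pos & labels == 0L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  if (is.null(prevalence_override)) {
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  } else {
    pv <- predictive_values(sens, spec, prevalence_override)
    ppv <- pv$ppv
    npv <- pv$npv
  }
  out <- tibble(
    threshold = threshold, sensitivity = sens, specificity = spec,
    ppv = ppv, npv = npv,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
  class(out) <- c("pex_confusion", class(out))
  out
}

#' Nearest-top-left threshold selection
#'
#' Chooses the candidate threshold minimizing the squared distance of the ROC
#' point to the top-left corner, `(1-sens)^2 + (1-spec)^2`. Ties are broken
#' toward higher specificity, then toward the more conservative (higher on
#' the working scale) threshold. The reported threshold is the midpoint of
#' the two adjacent distinct observed scores bracketing the cut.
#'
#' @param roc a `pex_roc` object.
#' @param prevalence_override optional prevalence for ppv/npv; see
#'   [confusion_at()].
#' @return A one-row `pex_confusion` tibble at the selected threshold.
#' @export
select_threshold_topleft <- function(roc, prevalence_override = NULL) {
  stopifnot(inherits(roc, "pex_roc"))
  # only real cuts between observed scores are admissible thresholds
  finite <- which(is.finite(roc$thresholds))
  if (length(finite) == 0) abort("degenerate ROC: a single distinct score")
  d2 <- (1 - roc$sensitivity[finite])^2 + (1 - roc$specificity[finite])^2
  # lexicographic: min distance, then max specificity, then latest index
  # (thresholds increase with index on the working scale, so the last tied
  # index is the most conservative cut)
  best <- which(d2 == min(d2))
  best <- best[roc$specificity[finite][best] ==
                 max(roc$specificity[finite][best])]
  i <- finite[best[length(best)]]
  thr <- roc$thresholds[i]
  confusion_at(roc$scores, roc$labels, thr,
               orientation = roc$orientation,
               prevalence_override = prevalence_override)
}

#' Predictive values from sensitivity, specificity and prevalence
#'
#' Bayes' rule for the post-test probabilities:
#' `ppv = sens*pi / (sens*pi + (1-spec)*(1-pi))` and
#' `npv = spec*(1-pi) / (spec*(1-pi) + (1-sens)*pi)`. Lets ppv/npv be
#' recomputed for any prevalence from a classifier's operating point, e.g.
#' to check a reported table's internal consistency.
#'
#' @param sensitivity,specificity operating-point probabilities.
#' @param prevalence prior probability of the positive class, in (0, 1).
#' @return A one-row tibble: `ppv`, `npv`.
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  if (!(prevalence > 0 && prevalence < 1)) {
    abort("prevalence must be in (0,1)")
  }
  pi <- prevalence
  tibble(
    ppv = sensitivity * pi / (sensitivity * pi + (1 - specificity) * (1 - pi)),
    npv = specificity * (1 - pi) /
      (specificity * (1 - pi) + (1 - sensitivity) * pi)
  )
}

#' Midpoint between two adjacent achievable vote-score levels
#'
#' For an m-marker vote score the achievable levels are `0, 1/m, ..., 1`; a
#' decision cut between levels `k/m` and `(k+1)/m` is reported as their
#' midpoint, `(2k+1) / (2m)`. This is the convention behind every published
#' combination threshold.
#'
#' @param m number of markers in the combination.
#' @param k lower vote count at the cut (0 <= k < m).
#' @return The midpoint threshold.
#' @export
vote_level_midpoint <- function(m, k) {
  stopifnot(m >= 1, k >= 0, k < m)
  (k / m + (k + 1) / m) / 2
}
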