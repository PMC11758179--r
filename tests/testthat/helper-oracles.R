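# Independent oracles used to cross-check the package's implementations.
# These deliberately use the slowest, most literal formulation of each
# quantity so they share no code with the functions under test.

# AUC by exhaustive pair counting
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Two-sided Fisher p by full enumeration of the hypergeometric support
oracle_fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }, 0)
  p_obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact permutation p for the two-sample log-rank test: enumerate every
# assignment of group labels with the observed group sizes.
oracle_logrank_exact_perm <- function(times, events, groups) {
  n <- length(times)
  n1 <- sum(groups == 1)
  obs <- survival::survdiff(survival::Surv(times, events) ~ groups)$chisq
  assignments <- utils::combn(n, n1, simplify = FALSE)
  stats <- vapply(assignments, function(idx) {
    g <- integer(n)
    g[idx] <- 1L
    survival::survdiff(survival::Surv(times, events) ~ g)$chisq
  }, 0)
  mean(stats >= obs - 1e-12)
}

# Brute-force nearest-top-left scan over every candidate midpoint threshold
oracle_topleft_scan <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- (u[-length(u)] + u[-1]) / 2
  best <- NULL
  best_key <- c(Inf, -Inf, -Inf)
  for (t in cand) {
    sens <- mean(scores[labels == 1] > t)
    spec <- mean(scores[labels == 0] <= t)
    key <- c((1 - sens)^2 + (1 - spec)^2, spec, t)
    if (key[1] < best_key[1] - 1e-12 ||
        (abs(key[1] - best_key[1]) < 1e-12 &&
         (key[2] > best_key[2] + 1e-12 ||
          (abs(key[2] - best_key[2]) < 1e-12 && key[3] > best_key[3])))) {
      best_key <- key
      best <- list(threshold = t, sensitivity = sens, specificity = spec)
    }
  }
  best
}

# Vectors x, y with an exact prescribed sample Pearson correlation
make_exact_corr <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))
  x_ <- scale(x)[, 1]
  e_ <- scale(e)[, 1]
  list(x = x_, y = r * x_ + sqrt(1 - r^2) * e_)
}

# Small deterministic clinical fixture: m markers, explicit values
make_clinical_fixture <- function(neg_dct, bor, nlr = NULL,
                                  os_months = NULL, os_event = NULL,
                                  ref_ct = 25) {
  n <- nrow(neg_dct)
  out <- tibble::tibble(
    patient_id = sprintf("F%02d", seq_len(n)),
    bor = bor,
    nlr = if (is.null(nlr)) rep(2, n) else nlr,
    os_months = if (is.null(os_months)) rep(12, n) else os_months,
    os_event = if (is.null(os_event)) rep(1L, n) else os_event
  )
  for (g in colnames(neg_dct)) out[[paste0(g, "_ct")]] <- ref_ct - neg_dct[, g]
  out$GAPDH_ct <- rep(ref_ct, n)
  out
}
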