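test_that("votes are strict and direction-symmetric", {
  expect_equal(vote("unfavorable", 1, 1), 0L)  # equality never fires
  expect_equal(vote("unfavorable", 1, 1.01), 1L)
  expect_equal(vote("favorable", 1, 0.99), 1L)
  expect_equal(vote("favorable", 1, 1), 0L)
  expect_error(vote("unfavorable", 1, NA), "measured")

  set.seed(19)
  for (i in 1:50) {
    v <- rnorm(1); t <- rnorm(1)
    expect_equal(vote("unfavorable", t, v), vote("favorable", -t, -v))
  }
})

test_that("combination score is the mean vote with missing -> NA", {
  rules <- marker_rules(
    marker = c("A", "B", "C", "D", "E", "F", "G"),
    direction = rep("unfavorable", 7),
    threshold = rep(0, 7)
  )
  vals <- as.data.frame(setNames(as.list(c(1, 1, 1, 1, 1, -1, -1)),
                                 rules$marker))
  expect_equal(combination_score(rules, vals), 5 / 7)
  all_pos <- as.data.frame(setNames(as.list(rep(1, 7)), rules$marker))
  expect_equal(combination_score(rules, all_pos), 1)
  vals$D <- NA
  expect_true(is.na(combination_score(rules, vals))) # excluded, not zero
  expect_error(combination_score(rules, vals[, 1:5]), "no measurements")
})

test_that("flipping one member's vote moves the score by exactly 1/m", {
  set.seed(23)
  for (m in c(2, 4, 7)) {
    rules <- marker_rules(sprintf("M%d", 1:m), rep("unfavorable", m),
                          rnorm(m))
    v <- rules$threshold - abs(rnorm(m)) # all votes 0
    df <- as.data.frame(setNames(as.list(v), rules$marker))
    s0 <- combination_score(rules, df)
    for (j in 1:m) {
      df2 <- df
      df2[[j]] <- rules$threshold[j] + 1 # flip vote j
      expect_equal(combination_score(rules, df2), s0 + 1 / m)
    }
  }
})

test_that("subset enumeration is complete, duplicate-free and ordered", {
  mk <- c("HLA-E", "ACTB", "MPIG6B", "RABL2B", "TNFRSF13C", "ZNF480", "NLR")
  subs <- enumerate_combinations(mk, 2, 7)
  expect_length(subs, 120) # 2^7 - 1 - 7
  subs1 <- enumerate_combinations(mk, 1, 7)
  expect_length(subs1, 127)
  keys <- vapply(subs, function(s) paste(sort(s), collapse = "|"), "")
  expect_equal(anyDuplicated(keys), 0L)
  sizes <- lengths(subs)
  expect_true(all(diff(sizes) >= 0)) # ordered by size
  expect_true(all(vapply(subs, function(s) {
    identical(s, c(sort(setdiff(s, "NLR")), intersect("NLR", s)))
  }, TRUE))) # genes alphabetical, NLR last
  expect_error(enumerate_combinations(mk, 5, 3), "size_min")
})

test_that("rank_combinations matches an independent brute-force reference", {
  spec <- simulation_spec(n_patients = 50, seed = 18)
  coh <- simulate_part1_cohort(spec)
  cfg <- analysis_config(top_k_combinations = 200)
  rules <- fit_marker_rules(coh, config = cfg)
  got <- rank_combinations(coh, rules, cfg, top_k = 200)
  expect_equal(got$rank, seq_len(nrow(got)))

  # brute force: recompute every subset's AUC from first principles
  vals <- marker_values(coh, rules$marker)
  pos <- as.integer(!is_responder(vals$bor))
  for (i in sample(nrow(got), 12)) {
    members <- strsplit(got$markers[i], " ")[[1]]
    scores <- vapply(seq_len(nrow(vals)), function(p) {
      votes <- vapply(members, function(mk) {
        r <- rules[rules$marker == mk, ]
        v <- vals[[mk]][p]
        if (r$direction == "unfavorable") as.integer(v > r$threshold)
        else as.integer(v < r$threshold)
      }, 0L)
      mean(votes)
    }, 0)
    expect_equal(got$auc[i], oracle_auc_pairs(scores, pos))
  }

  # ranking is by AUC desc with deterministic tie handling
  expect_true(all(diff(got$auc) <= 1e-12))
})

test_that("combination AUC is invariant to rule order and k rows are returned", {
  spec <- simulation_spec(n_patients = 40, seed = 27)
  coh <- simulate_part1_cohort(spec)
  cfg <- analysis_config()
  rules <- fit_marker_rules(coh, config = cfg)
  vals <- marker_values(coh, rules$marker)
  pos <- !is_responder(vals$bor)
  sub <- rules[c(1, 3, 5), ]
  rev_sub <- sub[3:1, ]
  s1 <- combination_score(sub, vals)
  s2 <- combination_score(rev_sub, vals)
  expect_equal(s1, s2)
  expect_equal(auc_mann_whitney(s1, pos), auc_mann_whitney(s2, pos))

  rc <- rank_combinations(coh, rules, cfg, top_k = 10)
  expect_equal(nrow(rc), 10)
  expect_equal(rc$rank, 1:10)
})

test_that("a frozen combination is applied strictly, with training idempotence", {
  spec <- simulation_spec(seed = 31)
  coh <- simulate_part1_cohort(spec)
  cfg <- analysis_config()
  rules <- fit_marker_rules(coh, config = cfg)
  rc <- rank_combinations(coh, rules, cfg)
  frozen <- rc$members[[1]]
  thr <- rc$threshold[1]

  applied <- apply_frozen_combination(frozen, thr, coh)
  pos <- !is_responder(coh$bor)
  # reapplying to the training cohort reproduces the training confusion counts
  expect_equal(sum(applied$label == "score_high" & pos), rc$sensitivity[1] * sum(pos))
  expect_equal(sum(applied$label == "score_low" & !pos), rc$specificity[1] * sum(!pos))

  # a score exactly at the cut is score_low
  one <- marker_rules("X", "unfavorable", 0)
  tab <- tibble::tibble(patient_id = c("a", "b"), nlr = c(1, 1),
                        X_ct = c(25 - 0.5, 25 + 0.5), GAPDH_ct = 25)
  lab <- apply_frozen_combination(one, 1, tab) # score 1 not > 1
  expect_equal(lab$label, c("score_low", "score_low"))
  lab2 <- apply_frozen_combination(one, 0.99, tab)
  expect_equal(lab2$label, c("score_high", "score_low"))
})

test_that("recovering a single informative marker adds nothing from noise", {
  # with one informative marker and pure-noise companions, the best
  # combination cannot beat the informative marker's solo AUC by much
  spec <- simulation_spec(
    n_patients = 2000,
    marker_effects = c("HLA-E" = 1.2, "ACTB" = 0, "MPIG6B" = 0,
                       "TNFRSF13C" = 0, "RABL2B" = 0, "ZNF480" = 0),
    score_frailty = 0,
    seed = 55
  )
  coh <- simulate_part1_cohort(spec)
  cfg <- analysis_config(combination_size_min = 1, nlr_included = FALSE)
  rules <- fit_marker_rules(coh, names(spec$marker_effects), cfg)
  rc <- rank_combinations(coh, rules, cfg, top_k = 5)
  solo <- rules$auc[rules$marker == "HLA-E"]
  expect_lte(rc$auc[1], solo + 0.03)
  expect_true(grepl("HLA-E", rc$markers[1]))
})
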