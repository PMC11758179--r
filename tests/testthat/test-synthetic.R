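test_that("identical seeds give bit-identical cohorts; spec is validated", {
  a <- simulate_part1_cohort(simulation_spec(seed = 5))
  b <- simulate_part1_cohort(simulation_spec(seed = 5))
  expect_identical(a, b)
  c <- simulate_part1_cohort(simulation_spec(seed = 6))
  expect_false(identical(a, c))

  expect_error(simulation_spec(bor_probs = c(CR = 0.5, PR = 0.2, SD = 0.2,
                                             PD = 0.2, NE = 0.1)), "sum to 1")
  expect_error(simulation_spec(marker_sd = 0), "marker_sd")
  expect_error(simulation_spec(hazard = c(CR = 0, PR = 1, SD = 1, PD = 1,
                                          NE = 1)), "hazard")
})

test_that("BOR mix lands inside exact binomial 99% bands", {
  coh <- simulate_part1_cohort(simulation_spec(seed = 12))
  counts <- table(factor(coh$bor, levels = c("CR", "PR", "SD", "PD", "NE")))
  probs <- c(7, 12, 25, 55, 5) / 104
  for (i in seq_along(probs)) {
    lo <- qbinom(0.005, 104, probs[i])
    hi <- qbinom(0.995, 104, probs[i])
    expect_gte(counts[i], lo)
    expect_lte(counts[i], hi)
  }
})

test_that("zero censoring horizon degenerates to all-censored at time zero", {
  coh <- simulate_part1_cohort(simulation_spec(censor_horizon_months = 0,
                                               seed = 2))
  expect_true(all(coh$os_event == 0))
  expect_true(all(coh$os_months == 0))
})

test_that("null marker effects give null per-marker AUCs at n=2000", {
  spec <- simulation_spec(
    n_patients = 2000,
    marker_effects = c("HLA-E" = 0, "ACTB" = 0, "MPIG6B" = 0,
                       "TNFRSF13C" = 0, "RABL2B" = 0, "ZNF480" = 0),
    seed = 33
  )
  coh <- simulate_part1_cohort(spec)
  vals <- marker_values(coh, names(spec$marker_effects))
  pos <- !is_responder(vals$bor)
  for (g in names(spec$marker_effects)) {
    a <- auc_mann_whitney(vals[[g]], pos)
    expect_gte(a, 0.4)
    expect_lte(a, 0.6)
  }
})

test_that("generator directions are recovered by per-marker AUC orientation", {
  spec <- simulation_spec(n_patients = 2000, seed = 44)
  coh <- simulate_part1_cohort(spec)
  rules <- fit_marker_rules(coh, names(spec$marker_effects))
  for (g in names(spec$marker_effects)) {
    eff <- spec$marker_effects[[g]]
    if (abs(eff) < 0.5 * spec$marker_sd) next
    want <- if (eff > 0) "unfavorable" else "favorable"
    expect_equal(rules$direction[rules$marker == g], want)
  }
})

test_that("discovery counts: shape, planted effects, library spread, errors", {
  spec <- simulation_spec(seed = 9)
  sim <- simulate_discovery_counts(spec, n_genes = 100,
                                   planted = c(G0001 = 2, G0002 = -2))
  expect_equal(dim(sim$counts), c(100, 17))
  expect_equal(sum(sim$labels == "PR"), 6)
  expect_equal(sum(sim$labels == "SD"), 5)
  expect_equal(sum(sim$labels == "PD"), 6)
  expect_true(all(sim$counts == round(sim$counts)) && all(sim$counts >= 0))
  libs <- colSums(sim$counts)
  expect_gte(max(libs) / min(libs), 2)

  lfc <- group_logfc(log2_cpm(sim$counts), sim$labels, "PR vs SD/PD")
  expect_equal(lfc$log2_fc[lfc$gene == "G0001"], 2, tolerance = 0.8)
  expect_equal(lfc$log2_fc[lfc$gene == "G0002"], -2, tolerance = 0.8)

  expect_error(simulate_discovery_counts(spec, n_genes = 10,
                                         planted = c(ZZZZ = 2)), "universe")
  expect_error(simulate_discovery_counts(spec, group_sizes = c(PR = 1, SD = 5,
                                                               PD = 6)),
               ">= 2")
})

test_that("planted fold changes pass the |log2FC| criterion in most seeds", {
  hits <- 0
  reps <- 40
  for (s in seq_len(reps)) {
    sim <- simulate_discovery_counts(simulation_spec(seed = 1000 + s),
                                     n_genes = 30,
                                     planted = c(G0001 = 2))
    lfc <- group_logfc(log2_cpm(sim$counts), sim$labels, "PR vs SD/PD")
    if (abs(lfc$log2_fc[lfc$gene == "G0001"]) > 1.5) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("part-2 generator: correlation target, pairing and degenerate args", {
  spec <- simulation_spec(seed = 3)
  # rho = 0 at n = 1000: sample r within sampling error of zero
  big <- simulate_part2_cohort(spec, n = 1000, rho_hla_e = 0,
                               n_missing_tumor = 0)
  expr <- delta_ct(big$plasma)
  hla <- expr[expr$gene == "HLA-E", ]
  r <- cor(hla$neg_delta_ct[match(colnames(big$tumor_tpm), hla$patient_id)],
           big$tumor_tpm["HLA-E", ])
  expect_lt(abs(r), 0.08)

  # rho = 0.9 at n = 17 is detected in most seeds
  sig <- 0
  for (s in 1:20) {
    p2 <- simulate_part2_cohort(simulation_spec(seed = 600 + s), n = 20,
                                rho_hla_e = 0.9)
    expr <- delta_ct(p2$plasma)
    hla <- expr[expr$gene == "HLA-E", ]
    i <- match(colnames(p2$tumor_tpm), hla$patient_id)
    pt <- pearson_test(hla$neg_delta_ct[i], p2$tumor_tpm["HLA-E", ])
    if (pt$p < 0.05) sig <- sig + 1
  }
  expect_gte(sig / 20, 0.8)

  p2 <- simulate_part2_cohort(spec, n = 20)
  expect_equal(nrow(p2$plasma), 20)
  expect_equal(ncol(p2$tumor_tpm), 17) # 3 of 20 lack tumor expression
  expect_true(all(p2$fractions$fraction >= 0 & p2$fractions$fraction <= 1))
  expect_true(all(p2$ihc$ihc_hla_e %in% c("high", "low")))

  expect_error(simulate_part2_cohort(spec, n = 3), "n >= 4")
  expect_error(simulate_part2_cohort(spec, rho_hla_e = 1.2), "rho")
})
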