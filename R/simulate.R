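# Synthetic-cohort generators. They emulate the statistical structure the
# pipeline assumes -- a 104-patient validation cohort with a CR/PR/SD/PD/NE
# mix of about 7/12/25/55/5, class-shifted marker distributions,
# response-linked exponential survival with administrative censoring, a
# pilot sequencing cohort of 6 PR / 5 SD / 6 PD samples, and a 20-patient
# paired treatment-naive cohort (17 with tumor expression) -- so every
# downstream stage is testable without patient-level data.

#' Simulation specification
#'
#' Holds every distributional choice of the generators. Marker effects are
#' shifts in -dCt units between non-responders and responders (positive =
#' unfavorable marker, elevated in non-responders); their defaults are sized
#' so the per-marker empirical AUCs land in the realistic 0.59-0.73 band.
#' Survival is exponential per BOR class with rates (per month) ordered
#' CR < PR < SD < PD << NE, and a frailty term couples each patient's
#' standardized marker burden to the hazard so that score-high patients are
#' enriched for early death.
#'
#' @param n_patients cohort size (default 104).
#' @param bor_probs named probability vector over CR, PR, SD, PD, NE
#'   (defaults 7/104, 12/104, 25/104, 55/104, 5/104).
#' @param marker_effects named vector of -dCt shifts (non-responder minus
#'   responder); negative values mark favorable markers.
#' @param marker_baseline responder mean -dCt shared by all markers.
#' @param marker_sd within-class -dCt standard deviation.
#' @param nlr_meanlog,nlr_sdlog length-2 named vectors (`responder`,
#'   `nonresponder`) of log-normal NLR parameters.
#' @param hazard named per-BOR exponential rates, month^-1.
#' @param score_frailty multiplier linking standardized marker burden to the
#'   log hazard.
#' @param censor_horizon_months administrative censoring horizon.
#' @param ref_ct_mean,ref_ct_sd distribution of the reference gene's raw Ct.
#' @param seed integer RNG seed.
#' @return A `pex_sim_spec` list.
#' @export
simulation_spec <- function(n_patients = 104L,
                            bor_probs = c(CR = 7, PR = 12, SD = 25,
                                          PD = 55, NE = 5) / 104,
                            marker_effects = c(
                              "HLA-E" = 0.85, "ACTB" = 0.75,
                              "MPIG6B" = 0.55, "TNFRSF13C" = 0.45,
                              "RABL2B" = -0.50, "ZNF480" = -0.40
                            ),
                            marker_baseline = -4,
                            marker_sd = 1,
                            nlr_meanlog = c(responder = log(2.5),
                                            nonresponder = log(3.2)),
                            nlr_sdlog = c(responder = 0.45,
                                          nonresponder = 0.50),
                            hazard = c(CR = 0.003, PR = 0.004, SD = 0.036,
                                       PD = 0.066, NE = 0.5),
                            score_frailty = 0.4,
                            censor_horizon_months = 36,
                            ref_ct_mean = 25, ref_ct_sd = 1,
                            seed = 1L) {
  if (abs(sum(bor_probs) - 1) > 1e-12) abort("bor_probs must sum to 1")
  if (!setequal(names(bor_probs), bor_levels())) {
    abort("bor_probs must be named CR, PR, SD, PD, NE")
  }
  if (any(hazard <= 0)) abort("all hazard rates must be > 0")
  if (marker_sd <= 0) abort("marker_sd must be > 0")
  if (censor_horizon_months < 0) abort("censor_horizon_months must be >= 0")
  if (n_patients < 1) abort("n_patients must be >= 1")
  structure(
    list(
      n_patients = as.integer(n_patients),
      bor_probs = bor_probs[bor_levels()],
      marker_effects = marker_effects,
      marker_baseline = marker_baseline,
      marker_sd = marker_sd,
      nlr_meanlog = nlr_meanlog, nlr_sdlog = nlr_sdlog,
      hazard = hazard[bor_levels()],
      score_frailty = score_frailty,
      censor_horizon_months = censor_horizon_months,
      ref_ct_mean = ref_ct_mean, ref_ct_sd = ref_ct_sd,
      seed = as.integer(seed)
    ),
    class = "pex_sim_spec"
  )
}

#' Simulate the part-1 clinical cohort
#'
#' Samples BOR from the configured mix, draws each marker's -dCt normal with
#' a class-dependent mean, reconstructs raw Ct as
#' `Ct_gene = Ct_ref - (-dCt)` with a per-patient reference Ct, draws NLR
#' log-normal per response class, and draws exponential survival with the
#' BOR-specific rate scaled by `exp(score_frailty * standardized marker
#' burden)`; times beyond the horizon are administratively censored at it.
#' Bit-identical tables for identical seeds.
#'
#' @param spec a [simulation_spec()].
#' @return A validated clinical tibble (class `pex_clinical`).
#' @export
simulate_part1_cohort <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "pex_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  bor <- sample(bor_levels(), n, replace = TRUE, prob = spec$bor_probs)
  nonresp <- !is_responder(bor)
  genes <- names(spec$marker_effects)

  neg_dct <- sapply(genes, function(g) {
    spec$marker_baseline + spec$marker_effects[[g]] * nonresp +
      rnorm(n, 0, spec$marker_sd)
  })
  neg_dct <- matrix(neg_dct, nrow = n, dimnames = list(NULL, genes))
  cls <- ifelse(nonresp, "nonresponder", "responder")
  nlr <- rlnorm(n, spec$nlr_meanlog[cls], spec$nlr_sdlog[cls])
  ref_ct <- rnorm(n, spec$ref_ct_mean, spec$ref_ct_sd)

  # standardized marker burden, direction-aligned (higher = worse)
  align <- sign(spec$marker_effects)
  z <- sweep(sweep(neg_dct, 2, spec$marker_baseline +
                     spec$marker_effects * mean(nonresp)), 2,
             spec$marker_sd, "/")
  burden_mat <- sweep(z, 2, align, "*")
  burden <- rowMeans(cbind(burden_mat,
                           (log(nlr) - mean(spec$nlr_meanlog)) /
                             mean(spec$nlr_sdlog)))

  rate <- spec$hazard[bor] * exp(spec$score_frailty * burden)
  t_raw <- rexp(n, rate)
  os_event <- as.integer(t_raw <= spec$censor_horizon_months)
  os_months <- pmin(t_raw, spec$censor_horizon_months)

  out <- tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    bor = bor,
    nlr = nlr,
    os_months = os_months,
    os_event = os_event
  )
  for (g in genes) out[[paste0(g, "_ct")]] <- ref_ct - neg_dct[, g]
  out$GAPDH_ct <- ref_ct
  validate_clinical_table(out, analysis_config())
}

#' Simulate the pilot discovery count matrix
#'
#' Log-normal-Poisson counts for `n_genes` genes over PR/SD/PD samples, with
#' fold changes planted on designated genes between PR and the SD/PD side,
#' and library sizes varied at least two-fold. Only the discovery filter's
#' behavior, not a negative-binomial count law, is emulated.
#'
#' @param spec a [simulation_spec()] (supplies the seed).
#' @param n_genes gene-universe size.
#' @param group_sizes named integer vector of PR/SD/PD sample counts
#'   (default 6/5/6, each must be >= 2).
#' @param planted named numeric vector: gene -> log2 fold change (PR minus
#'   SD/PD) to plant. Names must be in the gene universe
#'   (`G0001 ... G<n_genes>` unless they already match).
#' @param dispersion_sd sd of the log-normal overdispersion term.
#' @return List: `counts` (gene-by-sample integer matrix), `labels` (BOR per
#'   sample).
#' @export
simulate_discovery_counts <- function(spec = simulation_spec(),
                                      n_genes = 500L,
                                      group_sizes = c(PR = 6, SD = 5, PD = 6),
                                      planted = numeric(),
                                      dispersion_sd = 0.25) {
  stopifnot(inherits(spec, "pex_sim_spec"))
  if (!all(c("PR", "SD", "PD") %in% names(group_sizes))) {
    abort("group_sizes must name PR, SD and PD")
  }
  if (any(group_sizes < 2)) abort("each BOR group needs >= 2 samples")
  set.seed(spec$seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (length(planted) > 0) {
    outside <- setdiff(names(planted), genes)
    if (length(outside) > 0) {
      abort(paste0("planted gene(s) not in universe: ",
                   paste(outside, collapse = ", ")))
    }
  }
  labels <- rep(c("PR", "SD", "PD"), times = group_sizes[c("PR", "SD", "PD")])
  n_samples <- length(labels)
  base_log2 <- runif(n_genes, 2, 9)
  eff <- setNames(rep(0, n_genes), genes)
  eff[names(planted)] <- planted
  lib <- round(10^runif(n_samples, 5.7, 6.3)) # up to ~4-fold spread
  mu_log2 <- outer(base_log2, rep(1, n_samples)) +
    outer(eff, as.numeric(labels == "PR")) +
    matrix(rnorm(n_genes * n_samples, 0, dispersion_sd), n_genes)
  rel <- 2^mu_log2
  rel <- sweep(rel, 2, colSums(rel), "/")
  counts <- matrix(rpois(n_genes * n_samples, sweep(rel, 2, lib, "*")),
                   n_genes, dimnames = list(genes, sprintf("S%02d", 1:n_samples)))
  list(counts = counts, labels = labels)
}

#' Simulate the part-2 paired treatment-naive cohort
#'
#' Generates paired plasma qPCR, tumor TPM, IHC/CPS and immune-fraction
#' tables for `n` patients. A shared latent tumor HLA-E level drives: the
#' plasma HLA-E -dCt (population correlation `rho_hla_e` with the tumor TPM),
#' the IHC high/low protein call (thresholded latent with reader noise), and
#' an elevated activated-NK fraction. A configurable subset of patients
#' lacks tumor expression (insufficient frozen tissue). Plasma markers are
#' shifted toward the favorable (treatment-naive) pattern -- unfavorable
#' genes down, favorable genes up, NLR responder-like -- except TNFRSF13C,
#' which keeps a non-responder-like spread; a frozen part-1 combination
#' therefore scores essentially everyone below threshold.
#'
#' @param spec a [simulation_spec()].
#' @param n number of patients (>= 4).
#' @param rho_hla_e population correlation between plasma HLA-E -dCt and
#'   tumor HLA-E TPM, in \[-1, 1\].
#' @param n_missing_tumor patients without tumor expression (default 3).
#' @param naive_shift favorable shift applied to plasma markers, in -dCt
#'   units.
#' @return List of tibbles/matrices: `plasma` (patient_id, nlr, `_ct`
#'   columns), `tumor_tpm` (gene x patient matrix, tumor-profiled patients
#'   only), `ihc` (patient_id, ihc_hla_e, cps), `fractions` (long tibble:
#'   patient_id, cell_type, fraction).
#' @export
simulate_part2_cohort <- function(spec = simulation_spec(), n = 20L,
                                  rho_hla_e = 0.6, n_missing_tumor = 3L,
                                  naive_shift = 2) {
  stopifnot(inherits(spec, "pex_sim_spec"))
  if (n < 4) abort("part-2 cohort needs n >= 4")
  if (abs(rho_hla_e) > 1) abort("|rho_hla_e| must be <= 1")
  if (n_missing_tumor < 0 || n_missing_tumor > n - 3) {
    abort("n_missing_tumor must leave >= 3 tumor-profiled patients")
  }
  set.seed(spec$seed + 1L)
  ids <- sprintf("T%03d", seq_len(n))
  genes <- names(spec$marker_effects)

  z_tumor <- rnorm(n) # latent tumor HLA-E
  z_plasma <- rho_hla_e * z_tumor + sqrt(1 - rho_hla_e^2) * rnorm(n)

  # plasma panel: favorable, treatment-naive pattern
  fav_mean <- function(g) {
    e <- spec$marker_effects[[g]]
    if (g == "TNFRSF13C") {
      spec$marker_baseline + e / 2 # stays non-responder-leaning
    } else if (e > 0) {
      spec$marker_baseline - naive_shift # unfavorable gene pushed down
    } else {
      spec$marker_baseline + naive_shift # favorable gene pushed up
    }
  }
  ref_ct <- rnorm(n, spec$ref_ct_mean, spec$ref_ct_sd)
  plasma <- tibble(
    patient_id = ids,
    nlr = rlnorm(n, spec$nlr_meanlog[["responder"]] - 0.2,
                 spec$nlr_sdlog[["responder"]])
  )
  for (g in genes) {
    ndct <- if (g == "HLA-E") {
      fav_mean(g) + spec$marker_sd * z_plasma
    } else {
      fav_mean(g) + rnorm(n, 0, spec$marker_sd)
    }
    plasma[[paste0(g, "_ct")]] <- ref_ct - ndct
  }
  plasma$GAPDH_ct <- ref_ct

  # tumor TPM: HLA-E linear in the latent (keeps the Pearson target);
  # remaining panel + signature genes log-normal background
  tumor_ids <- ids[seq_len(n - n_missing_tumor)]
  nt <- length(tumor_ids)
  keep <- match(tumor_ids, ids)
  bg_genes <- setdiff(unique(c(genes,
                               unlist(default_signature_gene_lists(),
                                      use.names = FALSE))), "HLA-E")
  tpm <- matrix(rlnorm(length(bg_genes) * nt, meanlog = 3, sdlog = 1),
                nrow = length(bg_genes),
                dimnames = list(bg_genes, tumor_ids))
  tpm <- rbind(tpm, "HLA-E" = pmax(100 + 20 * z_tumor[keep], 1))

  # IHC protein call from the noisy latent; CPS independent background
  latent_protein <- z_tumor + rnorm(n, 0, 0.8)
  ihc <- tibble(
    patient_id = ids,
    ihc_hla_e = ifelse(latent_protein > 0, "high", "low"),
    cps = round(pmin(rlnorm(n, log(10), 1), 100), 1)
  )

  # immune fractions: activated NK tracks the tumor latent
  cell_types <- c("NK_activated", "NK_resting", "T_CD8", "T_CD4_memory",
                  "Macrophage_M1", "Macrophage_M2", "B_naive")
  fr <- purrr::map_dfr(seq_len(nt), function(i) {
    raw <- rexp(length(cell_types))
    names(raw) <- cell_types
    raw["NK_activated"] <- raw["NK_activated"] *
      exp(0.9 * z_tumor[keep[i]])
    raw <- raw / sum(raw)
    tibble(patient_id = tumor_ids[i], cell_type = cell_types,
           fraction = unname(raw))
  })

  list(plasma = plasma, tumor_tpm = tpm, ihc = ihc, fractions = fr)
}
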