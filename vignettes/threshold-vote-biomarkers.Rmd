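---
title: "Threshold-vote marker combinations: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-vote marker combinations: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pexvote)
```

## The model

`pexvote` builds a non-responder-predicting score from a small panel of
directional marker rules. A rule is a triple (marker, direction, threshold).
Unfavorable markers — elevated in non-responders — vote 1 when the measured
value strictly exceeds the threshold; favorable markers vote 1 when the
value falls strictly below it. For a combination of $m$ rules the score is
the mean vote, taking values in $\{0, 1/m, \dots, 1\}$: 0 means no marker
called the patient a non-responder, 1 means all did.

Marker expression is measured by RT-qPCR and normalized by the delta-Ct
method: the working scale is $-\Delta Ct = Ct_{ref} - Ct_{gene}$, which
increases with transcript abundance. Everything downstream — ROC curves,
AUC, votes — is invariant under strictly monotone transforms, so working on
$-\Delta Ct$ rather than the linearized $2^{-\Delta Ct}$ changes no
classification output; it keeps thresholds in interpretable cycle units.
The neutrophil-to-lymphocyte ratio enters as one extra unfavorable marker
on its raw ratio scale.

The response dichotomy throughout is responders (CR + PR) versus
non-responders (SD + PD + NE), with the **non-responder as the positive
class**. AUC is computed as the tie-corrected Mann–Whitney probability that
a positive scores above a negative, and its 95% interval by the DeLong
placement-value variance with a normal approximation, clipped to $[0,1]$.
Perfectly separated data have zero placement variance and a degenerate
interval — reported as such rather than patched.

## Threshold conventions

Candidate decision thresholds are the midpoints between consecutive
distinct observed scores, padded with infinite sentinels for the two
trivial classifiers. The operating point is chosen as the candidate
minimizing the squared distance to the ROC top-left corner,
$(1-\mathrm{sens})^2 + (1-\mathrm{spec})^2$. Two numerical choices matter
and are fixed once, everywhere:

* **Midpoints, not observed values.** For an $m$-marker vote score the
  achievable levels are $k/m$, so a cut between $k/m$ and $(k+1)/m$ is
  reported as $(2k+1)/2m$ — e.g. $9/14 = 0.643$ for a 7-marker score cut
  between 4/7 and 5/7, and $7/12 = 0.583$ for a 6-marker score cut between
  3/6 and 4/6. This is also what mainstream ROC software reports.
* **Strict inequalities, ties vote 0.** A value exactly at a threshold
  never fires a vote, and a score exactly at the frozen score cut
  classifies low. Distance ties during threshold selection resolve toward
  higher specificity, then toward the more conservative cut, making
  selection fully deterministic.

Per-marker thresholds are fit once on the full training cohort and then
frozen inside every combination; there is no per-subset refitting. Marker
orientation is auto-fitted so each marker's solo AUC is at least 0.5, and
the fitted direction is recorded in the rule.

## The combination search

All marker subsets with sizes from `combination_size_min` (default 2) to
the panel size are enumerated exactly once, in deterministic order (by
size, then lexicographically; NLR sorts last). Singletons are excluded by
default because single markers are assessed separately by their own ROC
analyses; setting the minimum to 1 is supported. Subsets are ranked by
score AUC, ties broken toward fewer markers then lexicographically.
Patients missing any member marker are excluded from that combination only,
with the exclusion and its reason recorded in the run manifest — a missing
measurement is never scored as a 0 vote.

For prognosis each top combination's frozen score splits the cohort at its
vote threshold; overall survival is compared by Kaplan–Meier curves,
log-rank test, and a one-covariate Cox model (Efron tie handling by
default, Breslow available for cross-checks; Wald 95% CI — the interval
convention is a declared choice). The frozen prognostic signature is the
combination with the highest converged hazard ratio, ties broken by the
smaller Wald p. 2-year overall survival is read off the product-limit curve
at 24 months as a right-continuous step function.

## The discovery filter

Discovery operates on log2 counts-per-million, `log2(1e6 * count/libsize +
1)`, with per-gene Welch tests across three best-overall-response
groupings: PR vs PD, PR vs SD/PD, and PR/SD vs PD (SD sides with PR in the
last). A gene qualifies if it meets **any** of: (C1) some grouping's
p below 0.05; (C2) some |log2 fold change| above 1.5; (C3) AUC1 (the larger
of the PR-vs-PD and PR/SD-vs-PD AUCs) or AUC2 (PR vs SD/PD) above 0.7;
(C4) presence on a literature allowlist. No multiple-testing correction is
applied at this stage — the filter is deliberately permissive, and its
type-I behavior is checked by simulation instead.

The reduction of qualifiers to a top-$k$ list has no published rule, so the
package fixes one: rank by number of criteria met, then best AUC, then
smallest p, then gene symbol. It is monotone in evidence and fully
deterministic; it is a declared convention, not a reconstruction.

Differential expression is tested by Welch's t statistic rather than a
negative-binomial count model: the selection thresholds, not the count law,
are the object under study here, and Welch/ANOVA is the package's
significance machinery throughout. Degenerate inputs are defined exactly:
two constant groups give statistic 0 and p 1 when equal, $\pm\infty$ and
p 0 when separated; one constant group falls through to the ordinary
Welch–Satterthwaite computation.

## The paired (part-2) stage

A frozen combination applied to a new cohort refits nothing: frozen
per-marker thresholds cast votes, and the frozen score cut labels patients
`score_high` (non-survivor signature) or `score_low`. The paired analyses
are: Pearson correlation (two-sided t on $n-2$ df) of each plasma marker
with its tumor TPM, restricted to tumor-profiled patients; concordance of
the key plasma marker with the IHC protein call via a median split and
Fisher's exact test; and Mann–Whitney comparisons of CPS, IFN-γ signature
scores and immune-cell fractions between plasma-high and plasma-low
patients. The median split sends values **at or above** the median to
`high` — with 17 distinct values this yields the 9/8 split that matches the
convention of the motivating analyses. Signature scores are means of
across-patient z-scores of `log2(TPM + 1)` over the signature genes; the
6- and 18-gene IFN-γ lists ship as editable defaults taken from the
signature literature, not asserted as any particular study's exact lists.
CPS, IHC calls and immune fractions are consumed as data: slide scoring and
deconvolution are out of scope.

## The synthetic cohort generator

The generator exists so that every stage is exercisable and testable
without patient-level data, which the motivating study does not deposit.
`simulation_spec()` fixes the study conditions:

* **Cohort**: 104 patients, best-overall-response probabilities
  7/104 (CR), 12/104 (PR), 25/104 (SD), 55/104 (PD), 5/104 (NE).
* **Markers**: $-\Delta Ct$ normal within response class, sd 1 cycle,
  responder baseline −4, non-responder shifts (in cycles)
  HLA-E +0.85, ACTB +0.75, MPIG6B +0.55, TNFRSF13C +0.45, RABL2B −0.50,
  ZNF480 −0.40. These place the per-marker AUCs in the 0.59–0.73 band
  realistic for single liquid-biopsy markers. NLR is log-normal with a
  small class shift (solo AUC ≈ 0.59).
* **Survival**: exponential per BOR class, rates (month⁻¹) 0.003 (CR),
  0.004 (PR), 0.036 (SD), 0.066 (PD), 0.5 (NE) — the simplest model giving
  the expected survival ordering and plausible 2-year rates — multiplied by
  `exp(0.4 × standardized marker burden)` so that marker-high patients die
  earlier and hazard-ratio recovery is testable end-to-end. Administrative
  censoring at 36 months.
* **Pilot counts**: log-normal–Poisson with 6 PR / 5 SD / 6 PD samples and
  ≥2-fold library-size spread. Only the filter's behavior is under test,
  so no negative-binomial dispersion estimation is emulated.
* **Paired cohort**: 20 patients, 17 with tumor expression. One latent
  tumor HLA-E level drives the plasma HLA-E value (population correlation
  `rho_hla_e`), the IHC call (noisy threshold) and an elevated
  activated-NK fraction. Plasma markers are shifted toward the favorable
  treatment-naive pattern (TNFRSF13C excepted, mirroring the observed
  exception), so a frozen part-1 combination scores essentially everyone
  below threshold.

What the generator does **not** emulate: between-marker correlation in the
panel (real exosomal transcripts co-vary with total exosome output),
non-exponential hazards, informative censoring, batch effects and assay
drift, and negative-binomial count dispersion. Passing tests therefore
demonstrate correctness of the algorithms and calibration under the assumed
structure — not clinical performance on real cohorts.

## Test and simulation sizes

The suite checks each statistic against an independent oracle (exhaustive
pair counting for AUC, full hypergeometric enumeration for Fisher's test,
exact label-assignment enumeration for the log-rank permutation comparison,
the score-test/log-rank identity for Cox, the $U = n_a n_b \cdot$AUC
identity for Mann–Whitney) and runs recovery simulations at the sizes the
checks need: combination-search recovery of a planted 3-marker panel over
100 seeds at n = 2000; DeLong coverage over 1000 cohorts of 100 + 100 at
true AUC 0.8; Cox recovery of a planted hazard ratio of 2.878 as the median
of 5 fits at n = 2000 (a single fit has sd(log HR) ≈ 0.05, so a ±10% band
is only ~1.9 standard errors); discovery type-I over 20 replicates of 200
null genes.

One caveat surfaced by the enumeration oracle: at n = 8 the log-rank
permutation distribution has ~70 atoms, so the asymptotic chi-square p can
sit up to ~0.1 from the exact permutation p mid-range; close agreement
(±0.02) holds in the separated, small-p regime where the test is actually
used. The tests assert exactly that.

## Known limitations

* Thresholds, combination ranking and the frozen signature are all fit on
  one cohort; reported AUCs and HRs are training-set quantities with the
  usual selection optimism. The package freezes and transfers the score but
  implements no internal cross-validation.
* DeLong intervals for the *top-ranked* combination do not account for the
  exhaustive search that chose it.
* The discovery stage deliberately applies no multiple-testing correction.
* Cox fitting flags monotone-likelihood non-convergence, and such
  combinations are passed over when selecting the frozen signature.
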