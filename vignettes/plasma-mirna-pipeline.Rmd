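---
title: "Two-phase plasma miRNA biomarker analysis: models and design choices"
author: "plasmaMiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase plasma miRNA biomarker analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaMiR)
```

# The measurement model

Quantitative PCR reports, per (assay, sample) well, a cycle threshold Ct:
the amplification cycle at which fluorescence crosses a fixed threshold.
Ct is inversely log-linear in template abundance — one cycle fewer is
roughly a two-fold higher input — so all modelling in `plasmaMiR` happens
on the Ct (log2-like) scale. A well in which no amplification is observed
within the instrument's run is *undetected*; `CtSet` stores such wells
(empty cells, "Undetermined" tokens, or numeric readings above the
ceiling) **at** the detection ceiling with a parallel logical flag. The
ceiling defaults to 40 cycles, the conventional run length of TaqMan
arrays; it is a constructor/reader argument (`ceiling =`) because
instruments and export settings differ, and the convention itself — not
any imputation — is the package's treatment of non-detection: a value at
the ceiling is informative about absence but is never trusted as a
quantitative measurement where precision matters (reference candidacy).

Two containers built on `SummarizedExperiment` carry the data: `CtSet`
(raw Ct + undetected flags, per-assay card and internal-control metadata)
and `RelativeExpressionSet` (−ΔΔCt levels with normalization provenance).
`SampleTable` (an `S4Vectors` `DFrame`) validates the clinical annotation:
group tokens are normalized, controls can never carry survival fields, and
an `os_event` without an `os_time` is rejected. `alignSamples()` takes the
Ct file's column order as canonical and reorders the annotation — one
source of truth for sample order.

# Normalization

## Reference selection

Circulating miRNAs have no accepted endogenous control, so the discovery
phase selects one per card from the data by three criteria, applied in
this order:

1. **Stability** — smallest standard deviation of raw Ct across the whole
   cohort, after removing assays with zero variance (flat at the ceiling:
   never detected anywhere, hence uninformative).
2. **Yield** — mean raw Ct at most `maxMeanCt` (default 35 cycles). Late-Ct
   assays sit near the detection limit where replicate noise explodes; 35
   is the usual reliable-quantification bound quoted for TaqMan chemistry.
   Assays with *any* undetected well are excluded from candidacy outright
   (they stay in the screen, at the ceiling).
3. **Neutrality** — a usable normalizer must not itself differ between the
   clinical categories. Two rank-based tests are applied to the candidate's
   Ct: Mann–Whitney for controls vs all patients, and Kruskal–Wallis
   across the five groups. Both p-values must *exceed* `alpha` (default
   0.05). Rank tests were chosen because group sizes in the discovery
   design are 10 and normality of plasma Ct is not defensible.

`shortlistReferences()` keeps the `k = 6` most stable eligible assays per
card (the shortlist size a stability screen of this design produces), ties
broken lexicographically by assay name so reruns are deterministic;
`selectReference()` then picks the most stable shortlisted assay passing
neutrality, per card, and returns the full report including every
shortlist p-value — failure is an informative error listing them.

## Relative quantification

With reference r and baseline group B (default `control`):

* ΔCt(a, s) = Ct(a, s) − Ct(r, s) — within-sample normalization; with a
  per-card reference each assay uses its own card's control, with a
  spike-in a single global reference.
* ΔΔCt(a, s) = ΔCt(a, s) − mean over B of ΔCt(a, ·)
* stored relative level = **−ΔΔCt**, so positive means *up* versus the
  baseline average and one unit is about two-fold. The linear view
  2^(−ΔΔCt) is available as `foldChanges()`; the pipeline and all tests
  pin the −ΔΔCt scale, which is symmetric and variance-stable — whether a
  study's "relative level" meant −ΔΔCt or its power-of-two is a recurring
  ambiguity, and fixing the log scale is the choice least sensitive to
  outliers in downstream rank tests and regressions.

Technical replicate wells are averaged **on the Ct scale before**
subtraction (`collapseDuplicates = TRUE`), matching the "mean cycle
threshold of the replicated measurement" convention; averaging after ΔCt
would give the same value only when the reference is replicate-free, and
before/after differ once wells are missing, so the order is fixed and
documented. A collapsed well counts as undetected only when all its
replicates were. An undetected *reference* well is an error naming the
sample — there is no defensible fill-in for a normalizer.

Two identities are enforced by construction and by test: levels are
invariant to adding any per-sample constant to all Ct (global efficiency
shifts cancel), and one extra cycle on a target changes its level by
exactly −1.

# The marker screen

`defaultScheme()` fixes the seven staged comparisons — control vs CRC,
control vs I–II, control vs III–IV, I–II vs III–IV, control vs IV, I–III
vs IV, II vs III — tagged with the marker category each screens for
(detection, early stage, late stage, metastasis, and the stage II/III
distinction relevant to adjuvant-chemotherapy decisions). Per assay and
comparison the default test is the two-sided Mann–Whitney (exact null
enumeration when the pooled n is ≤ 20 with no ties, tie-corrected normal
approximation otherwise); Welch's t is available by argument, and the test
used is recorded in every output row. The effect measure is the difference
of relative-level medians (side B − side A) and fixes the reported
direction.

Thresholding: candidates are rows with p < `alpha` (0.05, two-sided). No
multiple-testing correction is applied by default — the screen is a
hypothesis-generating step whose hits proceed to independent validation,
which is the error control this design actually relies on; Benjamini–
Hochberg within comparison is available (`adjust = "BH"`), and the
BH-selected set is provably a subset of the uncorrected one at equal
alpha. A *trend band* `alpha ≤ p < alphaTrend` (0.06) flags borderline
assays without selecting them: promotion of a trend candidate is an
explicit analyst decision, never automatic.

`zscoreForHeatmap()` produces the display matrix: each assay row scaled to
mean 0, SD 1 across samples, population-SD convention (denominator n, so
`[1, 2, 3]` maps to ±1.2247), constant rows refused.

# Marker evaluation

Logistic models are fit by maximum likelihood (`stats::glm`); complete
separation is detected from the fitted class probabilities and raised as
an error rather than returned as a silently divergent fit.
`bestSingleMarker()` fits each candidate alone and ranks a leaderboard by
rank AUC of the fitted score (or AIC); since a single-predictor logistic
score is monotone in the marker, its AUC equals the raw marker's and the
orientation (which direction is disease-like) is inferred from data,
never assumed.

The AUC is the rank statistic — the probability a random positive
outscores a random negative, ties one half — identical to the trapezoidal
area under the empirical ROC (both identities are tested to 1e-10 against
exhaustive pair counting). Its standard error uses the Hanley–McNeil
plug-in with Q1 = A/(2−A), Q2 = 2A²/(1+A), and the 95% CI is the Wald
interval clipped to [0, 1]. Hanley–McNeil needs only (A, n⁺, n⁻), which is
what a published AUC ± SE allows a reader to check; the nonparametric
DeLong SE computed from the score placements is available
(`aucSeDeLong()`, `rocSummary(seMethod = "delong")`). A limitation worth
stating: the Q1/Q2 terms are exact under a bi-exponential score model; for
Gaussian scores at high AUC (≈0.9) Hanley–McNeil is conservative by on
the order of 20%, which is the direction of error one wants in a CI but
matters when comparing SEs across estimators.

The operating cutoff maximizes Youden's J = sensitivity + specificity − 1
over midpoints between adjacent distinct scores, rule "score ≥ cutoff ⇒
positive", ties broken toward higher sensitivity then lower cutoff. The
common alternative phrasing of "the cutoff that maximizes the AUC" is not
well defined — a cutoff does not change the area — and is read here as the
standard Youden optimum; the closest-to-(0,1) criterion is available via
`criterion = "closest_topleft"`.

# Survival

For each marker, patients are dichotomized at the **mean** relative level:
high means strictly above, a value exactly at the mean is low (the
boundary must land somewhere; putting it in "low" keeps "high" a strict
exceedance and is fixed and documented). Kaplan–Meier curves
(product-limit, censored observations after tied events) and the two-group
log-rank test (hypergeometric terms summed over event times, χ² on 1 df;
an optional permutation p for small samples) describe each marker;
`buildDesign()` then encodes the multivariable contrasts — stage III–IV vs
I–II, CEA > 5 vs ≤ 5 µg/L (a value of exactly 5 is the reference arm),
age ≥ 55 vs < 55 years, female vs male, chemotherapy yes vs no, marker
high vs low, each coded 1 for the first-listed level — and `coxFit()`
estimates the proportional-hazards model by partial likelihood with
**Breslow** tie handling (the simplest standard default; Efron available),
reporting RR = exp(β) with Wald CI and p. Markers enter the multivariable
model when their univariate log-rank p < 0.05, mirroring the usual
univariate-then-multivariable reporting. Patients lacking survival
information are excluded from the survival arm only, never from marker
evaluation; survival time is taken as given in months and never
recomputed from dates. No proportionality diagnostics are run — with
months-scale follow-up and binary covariates the model is used as a
reporting convention, and this is a stated limitation.

# The synthetic study

The generator exists so that every stage can be scored against known
truth. `simulationConfig()` defaults define the emulated design:

* **Cohorts** — discovery: 10 controls + 10 patients per stage I–IV, 754
  assays split 377/377 across cards A/B; validation: 47 controls + 187
  patients (38/50/50/49 by stage) with two technical replicate wells per
  sample for an 11-marker panel, a cel-miR-39-like spike-in and a
  miR-451-like endogenous control.
* **Ct model** — Ct(a, s) = μ_a + shift_a(group(s)) + biological noise
  (SD σ_a) (+ technical noise, SD 0.15 cycles, per validation well),
  clipped at the 40-cycle ceiling with the undetected flag. Filler assays
  draw μ_a ~ U(22, 38) and σ_a ~ U(0.3, 1.5) cycles — order-of-magnitude
  choices for plasma TaqMan profiles, surfaced entirely in the config; 30
  "absent" assays sit flat at the ceiling to exercise the zero-variance
  filter. Effects are planted **in cycles** so they propagate through
  normalization exactly as real signal would.
* **Planted structure** — six low-variation assays per card: three truly
  group-neutral (the designated reference analogues, smallest SDs:
  0.12–0.19 cycles) and three low-SD but modestly shifted (a
  miR-16-like hemolysis-sensitive pattern), so the neutrality criterion
  has genuine rejections to make. Eleven markers carry per-stage shifts of
  0.7–2.5 cycles in the directions of their categories (e.g. the
  metastasis marker −2.5 cycles in stage IV only; the early-stage marker
  dips between stage II and III to make the II-vs-III comparison
  non-trivial).
* **Clinical composition** — sex, surgery, chemotherapy and
  no-survival-information counts are *fixed count vectors permuted across
  patients*, not independent draws, so the generated cohort reproduces the
  designed composition exactly on every seed (including exactly one
  patient with unknown chemotherapy and 13 without follow-up).
* **Survival** — exponential baseline hazard (0.006/month) with log-linear
  effects: 1.1 for stage III–IV and per-SD coefficients for the prognostic
  markers (0.9, 0.6, 0.4) applied to the marker's standardized latent
  level; administrative censoring uniform on 6–50 months (median 28). CEA
  is log-normal with a stage-shifted location and is used only as a Cox
  covariate.
* **Determinism** — one seed governs everything through per-cohort derived
  streams, so outputs are bitwise reproducible and adding markers does not
  perturb unrelated draws.

What passing these tests does **not** show about real data: the generator
draws independent Gaussian noise per assay — no hemolysis or batch
artifacts, no correlated miRNA families, no heavy-tailed contamination,
no plate or card effects beyond the per-card reference. Recovery rates on
synthetic cohorts are therefore upper bounds on what identical settings
would achieve on real plasma profiles.

# Problem sizes and runtime choices

The test suite and the acceptance script run the design sizes of the
emulated study (754 × 50 discovery, 234-sample validation). Monte-Carlo
checks use sizes chosen to make their tolerances meaningful at interactive
runtimes: 1,000 random matrices for the −ΔΔCt and AUC oracles, 10,000
replicates for the screening power oracle with the planted effect measured
over ten independent cohorts of 200 assays (a single cohort's shared
reference draw would otherwise dominate the comparison), 100 seeds for
reference-selection recovery, 200 replicates of n = 400 for Cox recovery
and coverage, and a 40-seed sweep of the full two-phase pipeline for
contrast-winner recovery. The end-to-end run itself takes seconds on one
CPU.
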