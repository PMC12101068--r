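---
title: "Immunophenotypic WM/MZL scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunophenotypic WM/MZL scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmscore)
```

## The diagnostic problem

Waldenström Macroglobulinaemia (WM) and marginal zone lymphoma (MZL) are
both mature B-cell neoplasms that can present with an IgM paraprotein,
bone-marrow involvement and overlapping morphology; MYD88 L265P, although
typical of WM, occurs in some MZL as well. No single flow-cytometry marker
separates the two. What does separate them is a *pattern*: WM clones tend
to show weak CD19 and CD22, negative or weak FMC7 and CD27, strong CD79b,
and aberrant CD13 on a small subset of cells, while MZL clones keep
normal-to-strong FMC7/CD22/CD27 and rarely express CD13.

`wmscore` operationalises that pattern as two additive scores, one point
per criterion:

| criterion | 1 point when | compartment |
|---|---|---|
| CD19 | weak (or negative) | BM + PB |
| FMC7 | negative or weak | BM + PB |
| CD22 | weak (or negative) | BM + PB |
| CD79b | strong, **provided CD22 is negative/weak** | BM + PB |
| CD27 | negative or weak | BM + PB |
| CD13 | expressed on ≥ 2 % of clonal B cells | BM + PB |
| clonal fraction | clonal B cells < 10 % of lymphocytes | PB only |

A bone-marrow total of **3/6 or more**, or a peripheral-blood total of
**4/7 or more**, calls WM; otherwise MZL. The blood criterion reflects
that circulating WM clones are typically small (median around 7 % of
lymphocytes) whereas circulating MZL clones are large (median around
52 %); 10 % is the practical boundary.

Two readings in the criterion table deserve comment, because the
published table is silent on them:

* **"Weak" rows and negative markers.** The CD19 and CD22 rows award the
  point for *weak* expression. A fully negative marker is weaker than
  weak, so the package awards the point for negative as well (and the
  CD79b condition is explicitly "CD22−/weak"). This monotone reading
  cannot lower any total.
* **FMC7 "negative or weak".** Negativity is judged on percent positive
  and weakness on the MFI ratio; either earns the point.

When a criterion's marker is missing from the input, the score is
reported over the available criteria with a reduced maximum, and no
WM/MZL call is made if the missing points could change it (the call is
`NA` with the missing criteria listed). Safety first: a partial score
never silently pretends to be a full one. A WM call accompanied by
*strong* FMC7 carries an advisory note, since strong FMC7 is an MZL
feature.

## From events to grades

The event-level pipeline mirrors routine practice:

1. **Lymphocyte gate** (`gate_lymphocytes()`): a deterministic
   two-cluster partition on (log CD45, log side scatter), keeping the
   CD45-bright/SSC-low cluster. If the two clusters explain less than
   45 % of the variance the input is treated as a single lymphocyte
   population — a pure-lymphocyte file must not be cut in half. A
   rectangular manual gate can override the automatic one.
2. **B cells** (`partition_b_cells()`): the CD19-bright cluster, accepted
   only when the two CD19 clusters are separated by more than four-fold
   in intensity; otherwise all lymphocytes are treated as B cells (useful
   for pre-gated B-cell files).
3. **Clonality**: surface light-chain restriction. Each B cell is called
   kappa/lambda-positive against a negativity cutoff placed at the
   99th-percentile boundary of an internal negative population (T cells
   for B-lineage markers, residual B cells for CD5/CD43/CD13). The
   boundary is estimated robustly as `median × exp(z₀.₉₉ · MAD)` of the
   log intensities, so a small admixture of bright pathological events in
   the reference cluster cannot inflate it. Among single-positive cells,
   a two-component equal-variance Gaussian mixture on the expressed-chain
   log intensity (via *mclust*) separates a bright clonal mode from
   residual polytypic B cells; the clone is the brightest-n set sized by
   the mixture weight, which avoids the clone-tail bias of hard
   classification. A population is clonal when the kappa:lambda event
   ratio within the candidate exceeds 4:1 (or is below 1:4), the
   conventional clinical bound. Fewer than 50 B cells, or no restricted
   cluster, yields `light_chain = "none"` and a low-confidence flag.
4. **Percent positive and MFI** (`percent_positive()`, `mfi()`): percent
   above the cutoff and the arithmetic mean intensity, both on the raw
   instrument scale and over the *entire* pathological population. No
   display transform ever enters the scoring arithmetic.

## Grading against a reference

Grades discretise expression relative to normal mature B cells
(`grade_marker()`):

* **negative** — percent positive below the positivity threshold: 30 %
  for every marker except CD13, whose validated threshold is 2 %;
* otherwise by the **MFI ratio** (clonal population MFI / reference
  population MFI): **weak** < 0.5, **normal** 0.5–2.0, **strong** > 2.0.

The half/double boundaries are the conventional clinical reading of
"dim"/"bright" — no published numeric boundary exists for these
categories, so they are configurable (`reference_ranges()`); this is the
single largest judgment call in the package and is deliberately surfaced
in the configuration.

The preferred reference is the *paired residual normal B-cell population
of the same sample* (when it holds ≥ 50 events); stored healthy-control
ranges are the fallback for heavily infiltrated samples. CD13, CD5, CD23
and CD43 are graded on percent alone: normal B cells do not express them
(or, for CD23/CD38, express them partially and dimly), so a
population-mean MFI ratio against normal B is not meaningful. CD38 is
likewise treated on percent, which is also the variable used for its
association with CXCR4 mutation status (`cd38_cxcr4_association()`;
a Fisher-exact variant on dichotomised positivity is available). CD25 is
excluded entirely: its reactivity varies too much across antibody clones
and fluorochromes to grade reproducibly.

## The synthetic cohort generator

`simulate_profile()` / `simulate_events()` / `simulate_cohort()` generate
labelled WM, MZL and healthy-control data so the entire pipeline is
testable without patient material. The defaults encode the cohort
structure the scores were derived under:

* kappa restriction in 79 % of WM (5:1 kappa:lambda in MZL);
* CD5/CD23/CD43 positive in 9 % / 18 % / 22 % of WM; CD13 in two-thirds;
* bone-marrow clonal infiltration: scaled Beta on [2, 92] % of
  lymphocytes with mean 45 % (shape 2 for mild right-of-centre mass);
* blood clonal fraction: lognormal with median 7 % (WM) and 52 % (MZL),
  σ(log) = 0.8;
* WM grade tendencies (CD19/CD22 weak, CD79b strong, FMC7/CD27
  heterogeneous and often low) and the MZL contrast (normal-to-strong
  FMC7/CD22/CD27, less CD38);
* a CXCR4-mutated WM subgroup (prevalence 0.35, the typical range in WM
  cohorts) with low/absent CD38 and shifted-down CD19, CD79b, FMC7 and
  CD27.

Only the prevalences with published numbers are pinned; everything
described qualitatively ("heterogeneous", "mostly negative") is spread
over grade categories by an explicit probability table in `sim_config()`,
the MZL bone-marrow infiltration (median 30 %, σ(log) = 0.8) and all MFI
dispersion parameters are modelling choices fixed once here, and the
per-grade MFI ratios are drawn log-uniformly *inside* the grading bands
with a margin (weak 0.18–0.45, normal 0.6–1.8, strong 2.3–7), so
round-trip mis-grades can only occur near category boundaries.

The event model is a per-channel lognormal mixture: each population
(clonal B, residual B, T cells, non-lymphocytes) draws each channel from
an autofluorescence baseline (median 25, σ(log) = 0.6) or a positive
component (σ(log) = 0.35) whose level is solved so that the *population
mean* realises the planted MFI ratio — the ratio is defined on population
means, and keeping the generator and the grader on the same definition is
what makes the round trip exact in expectation. Pan-B markers are drawn
at 98–99.8 % positivity on the clone (a clone is CD19-positive by
definition of the gate). Ground-truth population labels ride along in the
table metadata. A virtual single-tube acquisition carrying all 14 markers
is the default; `tubes = TRUE` yields three per-tube aliquots matching
the shipped panel, in which case tubes without light chains approximate
clonal statistics on all B cells of that tube (flagged, and adequate when
the clone dominates the B compartment).

What the simulator does **not** emulate: spectral spillover and
compensation residues, doublets and viability artefacts, plasma-cell
CD38/CD138 continua, acquisition batch effects, and — importantly —
*correlation between markers within a patient*: grades are drawn
independently per marker, which makes simulated WM score distributions
broader (more low-scoring WM) than real cohorts, where the phenotype is
coherent. Passing tests therefore demonstrate the pipeline's internal
correctness, not the clinical operating characteristics, which come from
the published cohorts.

## Evaluation

`confusion()` (WM is always the positive class), `roc_curve()` (one
operating point per integer threshold `score ≥ t`, trapezoidal AUC equal
to the tie-half concordance probability) and `youden_optimal()`
(maximises J = Se + Sp − 1, ties broken toward the higher threshold,
i.e. higher specificity) follow the usual nonparametric conventions.
Undefined proportions (zero denominators) are returned as `NA` with a
flag rather than silently as 0 or 1. Exact binomial confidence intervals
are deliberately not attached to Se/Sp by default.

## Numerical and testing choices

* All partitions are deterministic (fixed quantile-initialised 2-means;
  hierarchical-initialised EM): gating consumes no random numbers, so a
  fixed seed fixes the entire pipeline output.
* Degenerate inputs error loudly: empty populations for percent/MFI,
  empty CD45 channels, non-positive MFIs in ratios, single-class inputs
  to ROC.
* The test-suite problem sizes — 20,000 events for event-level round
  trips, 2,000 profiles for prevalence recovery, 200 random cohorts for
  the AUC/concordance identity — were chosen as the smallest sizes at
  which the statistical tolerances (±3 percentage points on the clone
  fraction, exact binomial 95 % intervals, 1e-12 on the AUC identity)
  are comfortably stable.
* The acceptance script (`scripts/acceptance.R`) recomputes the
  derivation-cohort metrics from their published misclassification
  counts, rescores the packaged worked examples, re-derives the Youden
  thresholds on derivation-shaped score distributions, and reports
  simulated-cohort AUCs and simulator prevalence recoveries, all from a
  single `--seed`.

## Known limitations

FCS support is a minimal list-mode codec (FCS 3.0/3.1, float/double/
integer data, single dataset); spillover matrices are read but never
applied. The automated gates are honest defaults, not a replacement for
expert review — overrides exist at every stage (rectangular lymphocyte
gate, per-marker cutoffs, reference ranges, grade boundaries). The
mixture-based clonality detector assumes the clone's light-chain
intensity is at least comparable to residual B cells; a clone *dimmer*
than residual polytypic cells with a sub-4:1 overall ratio would be
missed, a configuration we have not seen described for WM or MZL.
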