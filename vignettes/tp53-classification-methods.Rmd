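---
title: "Classifying TP53 mutations and stratifying NSCLC prognosis: methods"
author: "tp53ea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying TP53 mutations and stratifying NSCLC prognosis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tp53ea)
```

## The problem

TP53 is the most frequently mutated gene in non-small cell lung cancer
(NSCLC), altered in roughly half of patients, but its mutations are not
functionally equivalent and their prognostic meaning depends on how they
are classified.  `tp53ea` implements, as one tested pipeline, the four
classification systems in common use and the downstream comparisons that
decide which of them carries independent prognostic information:

1. **missense vs truncating** — truncating means nonsense, frameshift or
   splice-site (protein-shortening) mutations;
2. **exon 8 vs non-exon 8** — location of the variant in the coding exon
   structure;
3. **disruptive vs nondisruptive** — a structural rule: truncating
   variants, plus missense substitutions inside the L2 or L3 loop of the
   DNA-binding domain (DBD) that swap the residue's polarity/charge
   group, are disruptive; everything else is nondisruptive;
4. **EAp53 high vs low risk** — missense variants carrying an
   evolutionary-action score above 75 are high-risk, at or below 75
   low-risk.  The scores themselves are an external input (a lookup
   table); the package never computes them.

Patient-level status feeds a survival comparison (Kaplan–Meier, log-rank,
Cox proportional hazards) and a genomic-landscape contrast between EAp53
high-risk carriers (HR) and everyone else (OT): per-gene frequencies,
pathway-level alteration rates (RTK, cell cycle, DNA damage repair) and
tumor mutation burden (TMB).

## Reference data and their defaults

All rule constants are data, not code, bundled as editable tab-delimited
files under `inst/extdata/`:

* **Exon map.** The canonical 393-codon transcript, coding exons 2–11.
  Codons spanning an exon junction are assigned to the earlier exon so
  the map is a strict partition of 1..393 (validated at load).  Known
  hotspots land in the conventional exons (R110L exon 4, R158L exon 5,
  Y220C exon 6, Y236C/R249S exon 7, R273C/R282W/E298X exon 8).
* **Domains.** DBD at residues 102–292.  The L2/L3 loop boundaries are
  not universally tabulated; the default uses L2 = 163–195 and
  L3 = 236–251, the convention of the disruptive-classification
  literature (it makes Y236C an L3 residue).  Both are configurable in
  the domain file, and load-time validation keeps the loops inside the
  DBD.
* **Polarity/charge groups.** The standard biochemistry grouping:
  nonpolar {G,A,V,L,I,P,F,M,W}, polar-uncharged {S,T,C,Y,N,Q}, positive
  {K,R,H}, negative {D,E}.  Because the grouping is an unstated choice in
  much of the literature, it is isolated in a config file rather than
  hard-coded.
* **EAp53 scores.** A lookup keyed by (ref, position, alt), scores in
  [0, 100]; absence is a value (`NA`), never silently zero.  The bundled
  table is *synthetic* (it spans the 75 threshold for testing); real
  scores should be supplied by the user, either as this file or as an
  `ea_score` column in the variant table (the column wins).
* **Protein sequence.** Used only by the simulator to pick consistent
  reference residues; it is synthetic, with the well-known hotspot
  residues pinned to their true amino acids and all other positions
  pseudorandom.  It is deliberately not the real p53 sequence and is
  labelled accordingly.

## Classification semantics

`parse_hgvs_p()` normalizes the MAF dialects (optional `p.`, stop as
`X`/`*`/`Ter`, `fs` suffixes, `..._splice` tokens) into one internal
form; unparseable strings raise errors carrying the raw text, and the
table-level wrapper `annotate_variant_file()` collects them into a skip
table with row numbers instead of dropping them.

Decisions the source literature leaves open, resolved here and
documented once:

* **In-frame indels** are non-truncating, nondisruptive,
  EAp53-not-applicable, and excluded from the missense-vs-truncating
  dichotomies (they fall into the "other" bucket of the four-group
  scheme).  The dichotomies in the literature only ever name missense
  and truncating classes.
* **Splice variants** carry no protein position: their exon field is
  missing and they can never satisfy the L2/L3 clause; they are
  truncating (hence disruptive) by definition.  They are excluded from
  the per-exon and per-domain location contrasts but remain in the
  alteration denominator.
* **Synonymous variants** never count toward patient-level mutant
  status (standard MAF convention).
* **Missense without a score** is EAp53 `not_applicable` and grouped
  with "others"; the skip/annotation tables keep the count auditable.
* **Multi-mutation patients** are labelled by precedence EAp53
  high-risk > low-risk > truncating > other (configurable).  The
  high-risk exposure is the risk-defining one in the four-group design,
  so it dominates; all dichotomous flags are ORs over the patient's
  variants and therefore order-independent.

## Statistical conventions

* 2×2 association tests pick **Fisher's exact test whenever any expected
  cell count is below 5**, otherwise the chi-square test with continuity
  correction; the choice is recorded per table.  Tables with an empty
  margin are reported not-testable rather than raising.  In the per-gene
  landscape screen a table whose mutated/wild-type margin is empty (a
  gene altered in everyone or no one) is reported with p = 1, since both
  groups have identical frequency by construction.
* All tests are two-sided at α = 0.05; raw p-values are reported, with
  an optional Benjamini–Hochberg column for the per-gene screen only.
* Survival: product-limit estimate; k-group log-rank with k−1 degrees of
  freedom; Cox partial likelihood with **Efron tie handling** by default
  (months-resolution data produce many ties; Breslow is available); Wald
  CIs and p-values on the log-hazard scale.  The reference level of
  every scheme is the "others"/wild-type-containing group.  Survival
  times are used as provided in `os_months`; the package takes no
  position on the time origin.
* The analysis design mirrors the combine-then-compare logic: each
  dichotomous scheme first runs a *pre-combination check* (e.g.
  truncating vs wild-type) among the complement subgroups, then the
  combined two-group comparison, a univariate Cox fit, and a
  multivariate fit adjusting for age > 65, sex, smoking and EGFR status.
* Mann–Whitney for TMB: exact enumeration when both groups have ≤ 20
  observations and no ties, otherwise the tie-corrected normal
  approximation with continuity correction.
* Percentages in cohort summaries are rounded half-up to one decimal on
  the applicable denominator (multi-organ metastasis among stage IV
  only), matching clinical-table formatting conventions.
* TMB is only computed when a panel size (Mb) is supplied, with the
  eligibility rule (exclude silent/non-coding classes) explicit; a small
  driver panel cannot support TMB, so no default panel size is assumed.

## The synthetic cohort generator

`simulate_cohort()` exists so the whole pipeline is testable without any
external download.  Its defaults *are* the design conditions of the
study population the package targets: 210 patients, TP53 prevalence
0.514 with a 15.7% second-mutation rate among carriers, 60% male, 50%
smokers, 45% EGFR-mutant, stage distribution 4.3/3.8/14.8/75.2/1.9%,
32.3% multi-organ metastasis among stage IV, overall survival available
for 41% of patients, and no ICI exposure.  The mutation spectrum gives
each of the eight canonical hotspots (R282W, R158L, Y236C, E298X, R110L,
R273C, R280K, Y220C) more than 2% of the alteration mass, places random
missense mass in the DBD (exons 5–8), and puts 31% of the mass on
truncating templates enriched in exons 4/10 and outside the DBD.  EAp53
scores for simulated missense variants come from a two-component normal
mixture (modes ≈ 50 and ≈ 85, equal weight) so both risk classes are
populated at any realistic n.

Survival is Weibull proportional hazards (shape 1.2, scale 30 months)
with censoring as the minimum of a 40-month administrative horizon and
an exponential dropout (rate 0.01/month).  Generative log hazard ratios
default to the multivariate pattern the analysis is designed to detect:
EAp53 high-risk 3.63, male 2.06, smoker 0.65, EGFR-mutant 0.30,
age > 65 0.82, and no residual effect of the other TP53 schemes —
so in a simulated cohort only the EAp53 scheme should survive
multivariate adjustment, which is exactly what the test suite checks.

A single root seed derives one substream per component (covariates,
TP53 spectrum, EA scores, survival, landscape), so changing one
component's parameters does not perturb the draws of the others, and
seeded runs are byte-identical.

**What the generator does not emulate:** panel-specific coverage and
calling noise, allele fractions, copy-number and fusion events,
covariate correlations (sex and smoking are drawn independently, unlike
real NSCLC cohorts), non-proportional hazards, and informative
censoring.  Passing tests therefore demonstrate correctness of the
pipeline's logic and statistics under a clean generative model, not
robustness to real-data artifacts.

## Verification strategy and problem sizes

Every statistic has an independent oracle in the test suite: the
disruptive rule is re-derived by brute force over all 393 × 20
substitutions from literal interval/group definitions; Kaplan–Meier is
checked against the empirical survival function (no censoring) and a
hand product-limit; the log-rank statistic against the
observed-minus-expected hypergeometric sums; Cox coefficients against a
one-dimensional Efron partial-likelihood optimizer; Fisher and
Mann–Whitney p-values against exhaustive enumeration.  Parameter
recovery uses 50 replicates of n = 500 (mean log-HR error within ±0.1,
~95% CI coverage) and the log-rank type-I error 1000 null replicates of
n = 100 (acceptance band 3.5–6.5%); these sizes give stable Monte-Carlo
estimates while keeping the default suite fast.

## Limitations

* The four-group placement of patients carrying both an EAp53 high-risk
  and a truncating mutation is a design choice (precedence), not an
  empirical fact; reports flag the affected patients via the annotation
  table.
* Real EAp53 scores and the true p53 sequence are not redistributed;
  the bundled synthetic stand-ins are for testing and simulation only.
* The exon numbering follows one canonical transcript; analyses of
  cohorts annotated against another isoform must supply their own exon
  map (the transcript label is echoed in every report's provenance
  block).
* DNA-level (c./g.) HGVS, copy-number events, competing risks and
  time-varying covariates are out of scope.
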