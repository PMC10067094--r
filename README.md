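# tp53ea

Functional classification of TP53 mutations and prognostic
stratification of non-small cell lung cancer (NSCLC) cohorts, in R.

About half of NSCLC patients carry a TP53 mutation, but the mutations
are not functionally equivalent, and the field uses several competing
classification systems to decide which patients they mark for poor
prognosis.  `tp53ea` implements the four common systems as one tested,
reusable pipeline, for cancer genomicists and biostatisticians working
with panel-sequencing (MAF-style) cohorts:

* **missense vs truncating** (nonsense / frameshift / splice-site),
* **exon 8 vs non-exon 8**,
* **disruptive vs nondisruptive** — disruptive = truncating, or a
  missense substitution inside the L2 (163–195) or L3 (236–251) loop of
  the DNA-binding domain (residues 102–292) that changes the residue's
  polarity/charge group,
* **EAp53** — missense variants with an evolutionary-action score
  *s* ∈ [0, 100]: high-risk if *s* > 75, low-risk if *s* ≤ 75.  Scores
  are consumed as a lookup table or per-variant column, never computed.

Downstream, the package aggregates variants to patient level
(four-group split: EAp53 high-risk / low-risk / truncating / wild-type),
runs Kaplan–Meier, log-rank and Cox proportional-hazards comparisons per
scheme (univariate and multivariate adjusting for age > 65, sex,
smoking, EGFR status), and contrasts the genomic landscape of EAp53
high-risk carriers (HR) against all others (OT): per-gene frequencies,
RTK / cell-cycle / DNA-damage-repair pathway alteration rates, and
tumor mutation burden (mutations per megabase, Mann–Whitney).  A seeded
synthetic-cohort generator with the same statistical structure makes the
whole pipeline runnable and testable without any external data.

See `vignettes/tp53-classification-methods.Rmd` for the methods account:
rule semantics, statistical conventions, generator design and
limitations.

## Worked example

```r
library(tp53ea)

# classify a few protein changes against the bundled reference data
# (EAp53 scores here come from the bundled synthetic lookup table)
refs <- load_reference_set()
ann <- annotate_variants(c("R282W", "R249S", "Y236C", "E298X"),
                         refs$model, refs$domains, refs$properties,
                         ea = refs$ea)
ann[, c("raw_hgvs", "effect", "exon", "in_l2_l3", "is_disruptive",
        "eap53_class")]
#>   raw_hgvs   effect exon in_l2_l3 is_disruptive    eap53_class
#> 1    R282W missense    8    FALSE         FALSE      high_risk
#> 2    R249S missense    7     TRUE          TRUE      high_risk
#> 3    Y236C missense    7     TRUE         FALSE      high_risk
#> 4    E298X nonsense    8    FALSE          TRUE not_applicable
```

R282W sits in exon 8 of the DNA-binding domain but outside the L2/L3
loops, so it is *nondisruptive*; R249S swaps a positive residue for a
polar-uncharged one inside L3, so it is *disruptive*; Y236C is in L3 but
keeps its polarity group (nondisruptive); the nonsense variant E298X is
truncating, hence disruptive, and EAp53 does not apply to it.

Full pipeline on a simulated cohort:

```r
sim <- simulate_cohort(simulation_config(seed = 1))
paths <- write_cohort(sim, "example")
report <- run_tp53_analysis(paths[["clinical"]], paths[["variants"]],
                            panel_mb = 1.2)
report
#> Four-group sizes:
#> EAp53 high-risk  EAp53 low-risk      truncating              WT
#>              42              43              30              95
#>
#> Survival analysis: n=70, events=42
#>   missense_vs_others       log-rank p=0.8274 | ... HR(multi)=1.42, p=0.302
#>   nondisruptive_vs_others  log-rank p=0.8335 | ... HR(multi)=1.17, p=0.648
#>   exon8_vs_others          log-rank p=0.6907 | ... HR(multi)=0.94, p=0.927
#>   eap53_vs_others          log-rank p=0.0007543 | HR(uni)=3.12 |
#>                            HR(multi)=5.42 (2.49-11.78), p=2.04e-05
#>   four-group log-rank: chi2=19.19 (df=3), p=0.00025
#>
#> TMB HR vs OT: median 2.50 vs 1.67 mut/Mb, p=8.359e-06
```

The survival analysis runs on the advanced-stage, ICI-naive patients
with overall-survival data (n = 70 of 210 here).  The generator's
design places the prognostic signal on the EAp53 exposure, and that is
what the fits recover: the EAp53 scheme is the only one significant
after multivariate adjustment, with a hazard ratio well above 1, and the
HR group carries a higher TMB.  `write_report(report, "outdir")` emits
the full bundle (annotation, stratification, association, survival and
landscape tables as TSV plus a JSON index with provenance).

A thin command-line front end with `simulate`, `annotate` and `run-all`
subcommands is installed at `inst/cli/tp53ea.R`.

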