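# chdrisk

Genetic and clinical coronary heart disease (CHD) risk modelling for type 2
diabetes (T2D) cohorts.

People with T2D are at elevated risk of CHD, and clinical risk engines built
for the general population do not capture diabetes duration or glycaemic
control. `chdrisk` implements, as one reusable pipeline, the computational
chain used when a multi-SNP CHD gene score is added to the UKPDS 10-year CHD
risk engine in a T2D cohort:

* a **19-SNP weighted gene score** with risk-allele dosage reduction and a
  recessive rule for *NOS3* rs1799983;
* the **UKPDS risk engine** (multiplicative annual hazard, geometric time
  evolution) with coefficients supplied as configuration;
* **combination of genetic and clinical risk** by converting the score's
  relative odds ratio to a relative risk at a fixed baseline incidence and
  folding it into the hazard;
* **genotyping concordance QC** between two call sources (per-SNP
  cross-tabulation over pairwise-complete calls);
* **cohort statistics**: baseline randomisation checks (ANOVA / chi-squared
  with log- and square-root-transformed traits), gene-score group
  comparisons, risk-allele distribution tests, and gene-score-tertile
  regressions;
* a **seeded synthetic-cohort generator** (Hardy–Weinberg genotypes at the
  panel allele frequencies, baseline clinical moments, configurable
  genotyping-error injection) so the whole chain is testable without any
  subject-level data.

## The model

For subject *i* with risk-allele dosage `g_ij ∈ {0,1,2}` at SNP *j* and
per-allele log odds ratio `w_j`, the gene score is

    GS_i = Σ_{j additive} w_j g_ij + Σ_{j recessive} w_j 1[g_ij = 2]

The UKPDS engine gives the subject's annual hazard as a product of one
positive multiplier per risk factor around a baseline intercept,

    q_i = q0 · Π_k β_k^{x_ik}

(continuous exposures centred at reference constants, binary exposures as
0/1, lipids entering as ln(total/HDL cholesterol)), and the 10-year risk as

    R_i = 1 − exp( −q_i d^{dur_i} (1 − d^10) / (1 − d) )

with `d` the per-year hazard ratio and `dur_i` years since T2D diagnosis.
Genetic risk enters by replacing `q_i` with `q_i · RR_i`, where

    OR_i = exp(GS_i − GS_ref),   RR_i = OR_i / (1 − p0 + p0 · OR_i)

with `GS_ref` the Hardy–Weinberg population expectation of the score (or a
supplied cohort mean) and `p0` the baseline ten-year CHD incidence
(default 0.3).

The bundled default panel carries the published rsIDs, gene loci,
chromosomes and risk allele frequencies, but **not** the published weights
(they are proprietary); `placeholderWeights()` provides a clearly synthetic,
plausibly scaled set for demonstration and testing. The bundled UKPDS
coefficients are transcribed from the published UKPDS Risk Engine reference
(Stevens et al. 2001, UKPDS 56).

## Worked example

```r
library(chdrisk)

panel     <- defaultPanel(weights = placeholderWeights())
coeffs    <- defaultUkpdsCoefficients()
cohort    <- simulateClinicalCohort(defaultCohortSpec(), seed = 42)
genotypes <- simulateGenotypes(panel, n = nrow(cohort), seed = 42)

scores <- computeGeneScore(genotypes, panel)
scores$subject_id <- cohort$subject_id
head(scores, 3)
#>      subject_id n_risk_alleles gene_score
#> S001       P001             15       3.30
#> S002       P002             16       2.77
#> S003       P003             20       3.73

comb <- combinedRisk(cohort, scores, coeffs, panel = panel)
head(comb[, c("subject_id", "gene_score", "or_rel", "rr",
              "ukpds_risk", "combined_risk_pct")], 3)
#>   subject_id gene_score    or_rel        rr ukpds_risk combined_risk_pct
#> 1       P001       3.30 1.1754934 1.1167013 0.05510942              6.13
#> 2       P002       2.77 0.6919013 0.7623665 0.09271386              7.15
#> 3       P003       3.73 1.8070361 1.4548107 0.12316027             17.40
```

Subject P001 carries 15 risk alleles for a gene score of 3.30, slightly
above the panel's population expectation, so their odds ratio relative to
the average genotype is 1.18, their relative risk at `p0 = 0.3` is 1.12,
and their clinical-only UKPDS risk of 5.5 % becomes a combined ten-year
risk of 6.1 %. Over this simulated three-arm cohort of 211 subjects the
combined risk spans 0.8–89 %.

Concordance QC against the bundled published array-validation counts:

```r
s <- summarizeConcordance(readConcordanceCounts())
c(s$overall_concordant, s$overall_compared, s$overall_pct)
#> [1] 3152.0 3158.0   99.8
s$inconsistent_rows   # a row whose printed genotype counts do not sum to n
#> [1] "rs708272"
```

A full run with stage outputs (gene scores, UKPDS and combined risk,
concordance report, baseline table) plus a reproducibility manifest:

```r
runPipeline(list(out_dir = "run1", seed = 7))
```

or from a shell, `Rscript inst/scripts/chdrisk-pipeline.R --seed 7 --out run1`.

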