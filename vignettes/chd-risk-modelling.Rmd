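---
title: "Combining a 19-SNP CHD gene score with the UKPDS risk engine: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining a 19-SNP CHD gene score with the UKPDS risk engine: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chdrisk)
```

# Scope and data model

`chdrisk` models ten-year coronary heart disease (CHD) risk in subjects with
type 2 diabetes (T2D) as the product of two components: a clinical hazard
from the UKPDS risk engine and a genetic multiplier derived from a weighted
19-SNP gene score. Around that core it provides genotype I/O, genotyping
concordance QC, the cohort-level statistics used to check trial
randomisation and score–trait associations, and a seeded synthetic-cohort
generator that reproduces the statistical structure these analyses assume.

Four S4 classes carry the data: `SnpPanel` (the score definition),
`GenotypeSet` (subject-by-SNP allele calls), `UkpdsCoefficients` (the risk
engine's parameterisation) and `ConcordanceTable` (per-SNP cross-tabulation
of two call sources). Analysis results are plain data.frames.

# The gene score

Each panel SNP *j* has a risk allele, risk allele frequency (RAF) and a
per-allele weight $w_j$ on the natural-log odds-ratio scale. With dosage
$g_{ij} \in \{0,1,2\}$,

$$GS_i = \sum_{j\,\mathrm{additive}} w_j\, g_{ij} \;+\;
  \sum_{j\,\mathrm{recessive}} w_j\, \mathbf{1}[g_{ij}=2].$$

*NOS3* rs1799983 is the panel's one recessive SNP: heterozygotes contribute
nothing. Whether a recessive homozygote should contribute the weight once or
twice is genuinely open; we score it once (`recessiveContribution =
"single"`) because the indicator, not the allele count, is the recessive
exposure, and expose `"double"` as a switch so the alternative convention
can be reproduced.

Allele matching is letter-exact against the panel — no strand flipping or
allele harmonisation. The genotyping arrays this package targets report
panel-defined alleles directly, so a foreign letter indicates a data error
that silent harmonisation would mask. Scoring requires complete panels by
default; `missing = "impute"` substitutes the Hardy–Weinberg (HWE)
expectation ($2\cdot RAF$ for additive dosages, $RAF^2$ for the recessive
indicator) for exploratory use only.

The bundled default panel ships the published rsIDs, gene loci, chromosomes
and RAFs, but the published per-allele weights are proprietary and are
therefore a required user input. `placeholderWeights()` is a synthetic set
with literature-plausible magnitudes (larger for the lipid loci, smaller
for the GWAS loci) used by the test-suite and demonstrations; nothing
scientific should be read into scores computed from it. The bundled allele
letters were compiled from public variant annotations and are likewise
illustrative — every computation depends only on internal letter
consistency and the RAF column.

# The UKPDS risk engine

The engine multiplies a baseline annual hazard $q_0$ by one positive
coefficient per risk factor,

$$q_i = q_0 \prod_k \beta_k^{x_{ik}},$$

where continuous exposures are centred at reference constants (age at T2D
diagnosis in years; HbA1c in %; systolic blood pressure per 10 mmHg;
$\ln(\mathrm{TC/HDL})$ for lipids) and binary exposures (female sex,
Afro-Caribbean ethnicity, smoking) enter as 0/1 exponents. Mixed ethnicity
is coded non-Afro-Caribbean, following the engine developers' guidance.
Current age is always derived as age at diagnosis + duration and never
stored, so the two can never disagree.

The hazard evolves geometrically with time since diagnosis at ratio $d$ per
year, giving the cumulative risk over a horizon of $T$ years for a subject
$dur$ years from diagnosis:

$$R = 1 - \exp\!\left(-q\, d^{dur}\, \frac{1-d^{T}}{1-d}\right).$$

This is the published UKPDS engine form; descriptions of it in the applied
literature sometimes garble the geometric term (conflating $d$ with the
diabetes duration, or dropping the minus sign inside the exponential), and
we deliberately implement the coherent published form — the one whose output
is a probability in $[0,1]$ and equals the year-by-year survival product
$1-\prod_{t=0}^{T-1}\exp(-q\,d^{dur+t})$. That identity is enforced in the
test-suite at tolerance $10^{-12}$ against an independently coded
brute-force oracle. At $d=1$ the geometric sum is replaced by its analytic
limit $T$ rather than evaluated as $0/0$.

Coefficient values live in a versioned JSON config, not in code: this
package's concern is the computation, and the engine's published
parameterisation (Stevens et al. 2001, UKPDS 56: $q_0 = 0.0112$,
$d = 1.078$, age 1.059 centred at 55, female 0.525, Afro-Caribbean 0.390,
smoking 1.350, HbA1c 1.183 centred at 6.72, SBP 1.088 per 10 mmHg centred
at 135.7, lipid ratio 3.845 centred at 1.59) ships as a clearly labelled
transcription in `inst/extdata/ukpds56_coefficients.json`. All engine tests
use synthetic coefficient sets, so correctness never rests on that
transcription.

# Combining genetic and clinical risk

Because gene scores are sums of log odds ratios, a subject's odds ratio
relative to a reference score is $OR = e^{GS - GS_\mathrm{ref}}$. The
combination proceeds in three steps:

1. **Reference point.** $GS_\mathrm{ref}$ defaults to the panel's HWE
   population expectation $\sum_\mathrm{add} 2\,w_j RAF_j +
   \sum_\mathrm{rec} w_j RAF_j^2$, so the average-genotype subject is risk
   neutral; a cohort mean can be supplied instead when the cohort itself is
   the reference population. Both conventions are defensible; the
   population expectation is the default because it does not change as
   subjects are added.
2. **OR → RR.** The odds ratio is converted to a relative risk at baseline
   incidence $p_0$ by the standard epidemiological formula
   $RR = OR / (1 - p_0 + p_0\,OR)$. The conversion keeps $RR$ between 1 and
   $OR$ and recovers $OR$ as $p_0 \to 0$. The default $p_0 = 0.3$ is the
   ten-year CHD incidence for this risk group reported from national heart
   statistics; we interpret it as the ten-year (not annual) incidence since
   it anchors a ten-year relative risk.
3. **Hazard scaling.** $q$ is multiplied by $RR$ before the cumulative-risk
   step, exactly as any other engine multiplier.

Two consequences are enforced as tests: a subject at the reference score
has combined risk identical to clinical-only risk, and combined risk is
continuous and strictly increasing in the gene score.

# Concordance QC

`compareCallSets()` cross-tabulates two call sources per SNP over their
shared subjects. A pair contributes only where **both** sources are
non-missing — the only policy consistent with published validation tables
whose per-SNP n varies SNP by SNP — and genotypes are compared as unordered
allele pairs. Genotype classes are labelled common/rare by allele counts in
the reference source (ties toward the panel risk allele). Percentages are
reported with round-half-even to 1 decimal, matching the convention of the
published table the bundled fixture transcribes.

The bundled fixture (`readConcordanceCounts()`) reproduces a published
validation of a 19-SNP cardiac risk array verbatim: 3158 comparisons, 6
discordant calls, overall concordance 99.8 %. One published row (rs708272)
prints genotype counts that do not sum to its number of comparisons; the
fixture reproduces the printed values and `summarizeConcordance()` flags
the inconsistency rather than correcting it, since which value is wrong is
unknowable from the publication.

# Cohort statistics

* Baseline comparisons: one-way ANOVA for numeric traits (on the log or
  square-root scale where specified) and Pearson chi-squared for
  categorical traits. No continuity correction is applied anywhere, so the
  tests are nominally calibrated and degenerate identical-group inputs give
  statistic exactly 0. A numeric trait with zero within-group variance is
  flagged rather than reported as an infinite F.
* Reporting conventions: log-transformed traits are summarised as geometric
  mean with an approximate SD (the delta-method back-transform, geometric
  mean × SD of logs); square-root-transformed traits as the back-transformed
  mean with the observed range.
* Gene-score group comparison: two-sample t-test, Welch by default (the
  safer default when variances are unknown; `var_equal = TRUE` gives the
  pooled test).
* Risk-allele distributions: chi-squared homogeneity on the two histograms
  after pooling adjacent cells until every expected count is at least 5
  (the standard validity rule; the smallest-expected cell is merged into
  its smaller neighbour, deterministically).
* Tertile associations: subjects are ranked into three groups of
  as-equal-as-possible size (ties broken by stable input order; cut-points
  reported as the 1/3 and 2/3 empirical quantiles), and each trait is
  regressed on the ordinal tertile index 1/2/3 — linear for numeric,
  logistic for binary traits — giving a single trend slope and two-sided
  p-value per trait. Logistic fits with an empty outcome cell in some
  tertile are flagged as possible separation and their p-value withheld.
* All p-values are two-sided and unadjusted for multiplicity, matching the
  reporting style of trial baseline tables where $p \le 0.05$ is read as
  significant.

# The synthetic-data generator

The generator exists so that every stage is exercisable end to end with no
subject-level data. It encodes the study conditions of a three-arm T2D
self-management trial baseline and a healthy-men reference cohort:

* **Genotypes** are drawn per SNP from HWE at the panel RAFs (dosage
  $\sim$ Binomial(2, RAF)), independently across SNPs and subjects.
  Independence (no linkage disequilibrium) is a deliberate simplification —
  the panel spans 13 chromosomes and the score treats alleles as
  independent contributors — but it means the generator cannot reproduce
  LD-induced correlation between nearby SNPs (e.g. the two *APOE* or *LPA*
  variants).
* **Clinical traits** are drawn per arm (sizes 67/74/70) from the published
  baseline moments: normal for age at diagnosis and SBP; log-normal for
  total cholesterol, HDL and HbA1c, parameterised by geometric mean and
  approximate SD; square-root-normal truncated at zero for T2D duration
  (back-transformed means 5.60/5.60/6.33 years — the published table gives
  no SD on the transformed scale, so the generator uses 1.0 sqrt-years, a
  round value consistent with the published 0–39 year range); Bernoulli
  for sex, smoking and ethnicity at the published percentages
  (Afro-Caribbean prevalence is not printed; 0.04/0.04/0.03 per arm were
  chosen once as small plausible values). Traits are drawn independently
  of one another, so real-world correlations (e.g. TC with HDL) are absent.
* **Arm assignment** uses a seeded permutation, so arm sizes are exact, as
  in blocked trial randomisation.
* **Genotyping errors** replace each call, independently with probability
  $\varepsilon$, by one of the two other legal genotypes at that SNP
  (uniformly), and record every perturbation in a ledger so concordance
  bookkeeping can be verified call for call.

All generator randomness is scoped: a `seed` argument produces bit-identical
output and restores the caller's RNG state.

Because the generator draws traits independently and without LD, passing
tests demonstrate that the *computational chain* is correct under the
stated statistical structure — they do not validate the score or the engine
against real patients, and quantities that require subject-level data
(published cohort medians, between-arm p-values, the published gene-score
means) are deliberately not asserted anywhere.

# Numerical and testing choices

* Engine-vs-oracle agreement is asserted at $10^{-12}$ (pure floating-point
  algebra); stochastic calibration checks use 3-standard-error bands.
* Problem sizes: Monte-Carlo checks of expectations use $10^5$–$10^6$
  subjects; generator-calibration replicates use 200 cohorts of the
  reference size 1360; null calibration of the four test families uses
  2000 replicates at trial-arm-sized groups. These sizes make 3-SE bands
  tight enough to detect real miscalibration while keeping the default
  suite fast.
* Degenerate inputs are first-class: RAF 0 or 1, zero gene-score variance,
  zero within-group variance, $d = 1$, zero horizon, identical histograms
  and self-comparisons all have defined, tested behaviour.

# Limitations

* The published score weights are not distributed; all shipped weights are
  synthetic placeholders and any substantive use requires real weights.
* No LD, no trait–trait and no genotype–trait correlation in the generator.
* The UKPDS engine is implemented for non-fatal CHD risk only; stroke and
  fatal-CHD equations, and general-population scores such as Framingham,
  are out of scope.
* Concordance QC reports discordance; it does not adjudicate which source
  is right.
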