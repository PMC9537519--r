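---
title: "Gene-centric CNV modifier analysis in BRCA1/BRCA2 carriers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric CNV modifier analysis in BRCA1/BRCA2 carriers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvmod)
```

## The problem

Women carrying pathogenic *BRCA1* or *BRCA2* variants have a high but
variable lifetime risk of breast cancer, and part of that variability is
heritable. `cnvmod` tests whether germline copy number variants (CNVs) —
deletions and duplications called from SNP-array intensity data — modify
that risk, gene region by gene region. Two features of such cohorts drive
the entire design:

* **Ascertainment.** Carriers are recruited through genetics clinics, which
  preferentially see affected women and their relatives. The sample is
  therefore enriched for cases in a way that depends on phenotype, and a
  naive case/control or cohort analysis of it is biased.
* **Relatedness.** Recruitment is family-based, so subjects cluster in
  families that share both genotype (a CNV segregates in a sibship) and
  unmodelled risk. Variance estimates must be robust to this clustering.

The package implements the whole desk pipeline around these two engines:
CNV-call post-processing and quality control, gene-centric genotype
construction, effective-test thresholds, concordance arithmetic against
orthogonal truth sets, and a synthetic cohort generator that reproduces the
statistical structure (family clustering, clinic ascertainment, noisy
calling) so everything can be validated end to end without restricted
consortium data.

## Risk model and baseline incidence

Disease onset follows a proportional-hazards modifier model on the age
scale,

$$\lambda_i(t) = \lambda_0(t)\, e^{\beta g_i},$$

where $g_i \in \{0,1\}$ indicates carrying a CNV of a given type
(deletion or duplication) overlapping the gene region under test, and
$\lambda_0(t)$ is the age-specific breast cancer incidence of carriers,
supplied as a piecewise-constant step function over age bands
(`incidence_table()`, YAML-configurable; `cumulative_hazard()` is its exact
integral). The package ships BRCA1-like and BRCA2-like default curves
(cumulative risk ≈ 72% and 69% by age 80) as *configuration*: analyses of
real data should substitute the published incidence estimates appropriate
to their cohort.

Follow-up runs from birth to the age at first breast cancer diagnosis, or
censoring at ovarian cancer diagnosis, bilateral prophylactic mastectomy or
last observation, whichever comes first. Only breast cancer counts as
affected; ovarian cancer is a censoring event.

## Engine 1: the retrospective-likelihood score test

`retro_score_test()` tests $\beta = 0$ using the *retrospective*
likelihood $P(g_i \mid \delta_i, t_i)$ — the probability of the genotype
conditional on the observed phenotype. Because the conditioning is on
phenotype, selecting subjects on phenotype (clinic ascertainment) does not
change the likelihood; that is the entire point of the construction. Under
the hazard model,

$$P(\delta, t \mid g) \propto \lambda_0(t)^{\delta} e^{\delta \beta g}
  \exp\{-\Lambda_0(t) e^{\beta g}\},$$

with the genotype frequency $p_s$ in each country × Ashkenazi-ancestry
stratum as a nuisance parameter, profiled at the stratum genotype mean
$\hat p_s$.

Writing $c_i = \delta_i - \Lambda_0(t_i)$ (the martingale-type residual)
and $\tilde c_i = c_i - \bar c_{s(i)}$ (centred within stratum), the
per-subject efficient score at $\beta = 0$ is

$$u_i = (g_i - \hat p_{s(i)})\,\tilde c_i, \qquad U = \sum_i u_i,$$

with family-cluster-robust variance $V = \sum_f \big(\sum_{i \in f}
u_i\big)^2$ and profile information $I = \sum_i \hat p_s (1 - \hat p_s)
\tilde c_i^2$. $U^2/V$ is referred to $\chi^2_1$; a one-step estimator
$\hat\beta = U/I$ with $se = \sqrt{V}/I$ yields the hazard ratio and its
95% CI.

**Why the residual is centred.** Since $\sum_{i \in s}(g_i - \hat p_s) = 0$
within each stratum, centring $c_i$ leaves $U$ unchanged; it matters only
for $V$. With an estimated $\hat p_s$, the raw family score sums retain a
component along $\sum_i c_i$, which is far from zero in an ascertained
sample (affected subjects are over-represented, so $\bar c > 0$), and the
uncentred robust variance overestimates $\mathrm{Var}(U)$ by a large factor
(about 1.8 in our calibration design). Centring is exactly the textbook
projection of the $\beta$-score orthogonal to the nuisance score for $p_s$,
and restores nominal size: in the packaged calibration (5,000 replicates of
~2,000-subject proband-ascertained sibship cohorts) the empirical type-I
error at $\alpha = 0.05$ sits within [0.04, 0.06] and the p-values pass a
Kolmogorov–Smirnov uniformity check.

Degenerate inputs: a monomorphic genotype gives $U = 0$, $p = 1$, HR
missing. Regions with fewer than `min_carriers` (default 2) carriers report
`NA` statistics. Strata with fewer than 2 carriers are pooled into one
residual stratum before centring, so a stratum cannot contribute a
degenerate $\hat p_s$ of 0 or 1 merely because it is small.

The one-step HR is an approximation around $\beta = 0$. It agrees with a
brute-force grid maximiser of the full retrospective log-likelihood to
within a few percent at cohort sizes in the thousands; on 20-subject
fixtures the agreement is only as good as the quadratic approximation
(checked at 0.15 tolerance for mild effects in the tests). It should be
read as an effect-size annotation on the score test, not as a maximum
likelihood estimate.

`retro_scan()` applies the test across a genotype matrix, counting for each
CNV type only regions with at least one overlapping CNV as *effective
tests* and flagging results against the Bonferroni threshold
$\alpha/n_{\mathrm{eff}}$ (`effective_test_threshold()`, displayed to one
significant figure, the convention used for such thresholds).

## Engine 2: the weighted-cohort hazard model

`weighted_cohort_fit()` estimates hazard ratios under ascertainment by
reweighting the sample so it mimics a true cohort
(`compute_weights()`). Subjects are grouped into bands by their age at
diagnosis/censoring (default 5-year bands 20–80, one opening band for ages
below 20, so the bands cover follow-up from birth; subjects aged 18–20 at
censoring fall in the opening band). Within band $a = [l_a, u_a)$ the
*expected* affected proportion is the probability of onset within the band
conditional on being disease-free at its start,

$$e_a = \frac{F(u_a) - F(l_a)}{S(l_a)} = 1 - \exp\{-(\Lambda_0(u_a) -
\Lambda_0(l_a))\},$$

and with $f_a$ the observed proportion, affected subjects receive weight
$e_a/f_a$ and unaffected subjects $(1-e_a)/(1-f_a)$, so the weighted
affected fraction equals $e_a$ in every band. Among the candidate readings
of "expected proportion" (cumulative risk at the subject's own age,
cumulative risk at the band end, band-conditional onset probability), only
the band-conditional form recovers a simulated true HR without material
bias under proband-affected ascertainment (mean $\hat\beta$ within 0.01 of
$\log 1.5$ on the packaged recovery design, versus ~0.14 attenuation for
the cumulative-risk readings); it is therefore the package's definition.
Bands where $f_a$ is 0 or 1 cannot be reweighted and keep weight 1, with a
warning.

The model itself is a weighted Cox partial likelihood on the age scale,
fitted by `survival::coxph` with a baseline stratified by country ×
Ashkenazi ancestry, fixed-effect adjustment for birth cohort and genotyping
array, Breslow tie handling (ages are continuous in simulation but heavily
tied in real data; Breslow keeps the weighted likelihood simple), and a
cluster-robust sandwich variance with families as clusters. Exposure can be
the three-level clinically diagnosed variant class (deletions and
duplications against "other" pathogenic variants; the
duplication-vs-other coding excludes deletion carriers), or any per-subject
vector such as a gene-region CNV genotype. Strata without events are
dropped with a warning; covariates that collapse to a single level are
dropped silently.

The weighting corrects the affected/unaffected imbalance that
ascertainment induces *marginally within age bands*. It does not undo
genotype-dependent sampling within families, which is why the score test —
whose conditioning handles ascertainment exactly — is the primary
genome-wide engine, with the weighted model used for effect estimation and
covariate-adjusted contrasts.

## CNV-call post-processing

The pipeline reproduces standard PennCNV post-processing with explicit,
testable rules:

* **Sample QC** (`filter_samples()`): exclusion on LRR s.d. > 0.28, BAF
  drift > 0.01, |waviness factor| > 0.05, LRR outlier rate > 0.1, BAF
  s.d. ≥ 0.2, LRR s.d. ≥ 0.4, or more than 100 CNV calls. The two LRR-s.d.
  cutoffs are both applied (the stricter dominates); strict versus
  non-strict comparisons follow the criteria as stated. Every breached
  criterion is reported per excluded sample.
* **Call filter** (`filter_calls()`): calls supported by five or more
  probes are retained.
* **Merging** (`merge_adjacent()`): neighbouring same-type calls merge when
  the gap between them is below 20% of the total length of the combined
  call. "Total length" is interpreted as the merged span
  ($\mathrm{end} - \mathrm{start} + 1$ of the union) and the gap excludes
  both endpoints, matching PennCNV `clean_cnv` semantics; merging is
  applied left-to-right to a fixed point, is idempotent, and sums probe
  counts. The summed-lengths denominator was the rejected alternative; the
  choice is stated here because the rule is often quoted without a
  definition.
* **Genotypes** (`overlap_genes()`): a subject carries a region-level
  deletion/duplication iff any call of that type overlaps the region by ≥1
  bp (GenomicRanges interval index; verified against quadratic brute force
  in the tests). Gene regions are (symbol, chromosome) pairs — duplicate
  BED rows collapse to their union span, and the same symbol on two
  chromosomes stays distinct. Hypervariable families (HLA, immunoglobulin
  superfamily, olfactory receptors) are excluded via a user-supplied symbol
  list, since they are named as families, not coordinates.
* **Conflicts** (`flag_conflicts()`): a subject with a deletion and a
  duplication in the same region whose calls do not mutually overlap is an
  inconsistent genotype; the (subject, region) pair is excluded from every
  test of that region. Mutually overlapping opposite-type calls are kept
  ("non-overlapping" qualifies the pair).
* **Map support** (`map_support()`): calls are collapsed to unique
  (chromosome, start, end, type) CNVs and marked as represented in a
  population CNV map on ≥1 bp same-type overlap — the screen used to flag
  regions whose CNVs look like calling artefacts (a region with ≥95%
  map-supported CNVs fails the "<95%" prioritisation criterion). The ≥1 bp
  same-type criterion is this package's choice; no published criterion
  exists for such comparisons.

Coordinates are 1-based closed throughout (the PennCNV convention);
BED I/O converts at the boundary and round-trips exactly. Chromosomes are
restricted to 1–22 and X; Y records and copy-neutral (cn = 2) records are
rejected as errors rather than dropped, to surface upstream problems.
X-chromosome regions are treated identically to autosomes (the cohorts are
female).

## Concordance arithmetic

`concordance_report()` evaluates calls against a truth set in both
directions: *sensitivity* (percentage of truth CNVs overlapped by a
same-type call) and *support rate* (percentage of calls overlapped by a
same-type truth interval). The support rate is a precision-type quantity
that call-evaluation studies sometimes label "specificity"; the package
keeps the honest name. Percentages are rounded half-up to one decimal.
Worked-example counts that appear in the tests occasionally disagree with
their published rounding at the 0.1 level (e.g. 700/851 = 82.256% prints as
82.3 here); the formula, not the printed rounding, is authoritative.

## The synthetic cohort generator

`simulate_cohort()` and `simulate_calls()` generate the study conditions
the engines assume:

* **Families** are sibships of size 1–4 (default mix 45/35/15/5%); the CNV
  is treated as an allele with frequency $q = 1 - \sqrt{1 - p}$ carried by
  unobserved parents and transmitted Mendelianly, so the marginal carrier
  frequency is $p$ and siblings are positively correlated — the robust
  variance is exercised non-trivially. Full multi-generation pedigrees are
  deliberately not modelled: clusters are what the variance estimator
  needs.
* **Onset** is drawn by exact piecewise-linear inversion of
  $\Lambda_0(t) e^{\beta g} = -\log u$ (`sample_onset_age()`); subjects
  whose required hazard exceeds the lifetime total never develop disease.
* **Censoring** combines a uniform age at last observation (default 25–80
  years) and an independent exponential competing-event clock (ovarian
  cancer/prophylactic mastectomy, default rate 0.005/year). Independence of
  the competing event is an assumption, noted as such. Subjects whose
  follow-up ends before the recruitment-eligibility age of 18 are excluded.
* **Ascertainment** follows the clinic: a family is retained iff its
  first-listed member (the proband) is affected. Real clinic ascertainment
  is more heterogeneous; proband-affected sampling induces the oversampling
  of affected carriers that the retrospective likelihood must tolerate,
  which is the property under test.
* **The clinically diagnosed variant class** (other/deletion/duplication,
  default 90/8/2%) is drawn per family — relatives share the family
  variant — and can carry its own log hazard ratio for Table-1-style
  contrasts.
* **Calling noise**: each true CNV is emitted with a type-specific
  detection probability (defaults 0.85 for deletions, 0.65 for
  duplications — deletion calling is easier on arrays); false calls arrive
  per genome at type-specific Poisson rates with log-normal lengths and
  random placement; probe counts are deterministic at 0.2 probes/kb
  (array-like density) so that a noiseless configuration reproduces the
  truth exactly through the ≥5-probe filter; QC metrics are drawn from
  clean distributions except for a configured fraction of failing samples,
  which receive LRR s.d. above the 0.28 threshold.

Fixed seed implies byte-identical output. What the simulations do *not*
emulate: LRR/BAF intensity data (QC metrics are drawn, not derived), probe
placement and breakpoint uncertainty (detected calls reuse true
boundaries), population structure beyond country labels, multi-generation
kinship, and calendar-time effects (birth cohort and array are independent
covariates). Passing tests therefore demonstrate the statistical machinery
under the modelled structure, not robustness to artefacts the generator
does not produce.

## Problem sizes and numerical choices

The packaged test suite calibrates the score test on 5,000 replicates of
~2,000-subject cohorts (sibships of two, proband-ascertained, 20% CNV
frequency) and the weighted model on 100 replicates of ~20,000-subject
cohorts with a true HR of 1.5; the acceptance script repeats both at
reduced replication (1,500 and 30 replicates, ~10,000 subjects) as its
standing reproduction sizes. The brute-force likelihood oracle uses a
$\beta$ grid of step 0.005 over $[-2, 2]$ with the nuisance frequency
profiled by golden-section search per grid point. Interval engines are
validated against quadratic brute force on random instances. Rounding of
percentages is half-up at one decimal (with a $10^{-9}$ guard against
binary representation of exact halves); threshold display uses one
significant figure.

## Known limitations

* The retrospective score test conditions each subject on her own
  phenotype; it does not model the family-level ascertainment event
  jointly, so residual second-order bias is possible for strong effects in
  small, heavily ascertained families.
* The one-step HR degrades away from $\beta = 0$; use the weighted model
  for effect estimation.
* The weighted model's correction is exact only for the band-marginal
  affected composition; genotype-dependent within-family sampling is
  corrected only approximately.
* Incidence tables are piecewise-constant; sub-band shape is flattened.
  Any band structure is accepted, 5-year bands are the convention.
* `map_support()` and `concordance_report()` use binary ≥1 bp overlap; no
  reciprocal-overlap or breakpoint-accuracy scoring is provided.
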