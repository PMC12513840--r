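---
title: "metabogen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metabogen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metabogen)
```

# Scope

`metabogen` implements the analytic chain of a genome–metabolome association
study at desk scale: medication correction of metabolite measures,
per-variant association scans, fixed-effect meta-analysis across ancestral
strata, regional clumping and approximate-Bayes-factor fine-mapping with 95%
credible sets, classification of molecular pleiotropy into five modes,
machine-learning effector-gene scoring, rare-variant mask/burden testing with
Cauchy combination and polygenic-score conditioning, allelic-series
convergence, and causal integration of metabolite *levels* (Mendelian
randomization) versus *loci* (colocalization) against disease outcomes.

Every stage is exercisable against a built-in synthetic cohort whose planted
truth makes calibration measurable. This vignette documents the models, the
parameters that matter, the numerical choices and the places where the design
was genuinely open.

# The synthetic cohort

## Genotypes

`generate_genotypes()` draws diploid genotypes as mosaics of stratum-specific
haplotype pools. Within each LD block a pool of haplotypes (default 2,000) is
generated by thresholding a stationary AR(1) Gaussian process at the quantile
of each variant's allele frequency, so adjacent-variant correlation decays
with the `ld_decay` parameter (in `[0, 1)`; 0 gives linkage equilibrium).
Individuals sample two pool haplotypes per block, which recombines pool
haplotypes across blocks. Strata get separate pools with logit-jittered
allele frequencies, producing stratum-specific frequencies and LD — the
feature the trans-ancestry machinery needs. Rare variants (`rare_fraction`,
MAF below 5×10⁻⁴) are drawn per individual in linkage equilibrium, since a
finite pool cannot represent such frequencies.

This emulates what the downstream statistics assume — blockwise LD, allele
frequency spectra, strata — and deliberately omits recombination maps,
phasing, imputation error and relatedness. Passing tests therefore speak to
the correctness and calibration of the statistical machinery, not to
robustness against those real-data complications.

Positions are 1-based and monotone within a block; distance is
`|pos_a − pos_b|` in bp. Missing genotypes use an `NA` sentinel and are
mean-imputed at association time, matching common dosage practice.

## Trait panel

`generate_trait_panel()` builds a correlated metabolite panel
`Y = F L' + G B + E`: iid standard-normal factor scores `F`, a traits×factors
loading matrix `L`, planted genetic effects `B` on centered dosages (betas
are per allele, in trait-SD units), and Gaussian noise. Traits are
standardized to unit variance after generation. Choosing the per-trait noise
SD as `sqrt(1 − rowSums(L^2))` makes the implied trait correlation exactly
`L L'`, which keeps planted effect sizes on their nominal scale.

The five planted-effect modes mirror the association patterns a metabolite
locus can display:

* **specific** — direct effects on ≤3 traits of one factor;
* **pathway** — effects on one factor's traits, proportional to loadings;
* **proportional** — the effect is injected on the factor itself, so
  per-trait effects scale with each trait's correlation to the lead trait;
* **disproportional** — effects on one factor's traits with magnitudes
  permuted until they are discordant with the loadings (correlation ≤ 0);
* **nonspecific** — direct effects on traits across several factors, with
  constant magnitude and random signs.

Two details of the discordant/nonspecific constructions are deliberate.
First, nonspecific magnitudes are constant: a variant's own planted effect
induces trait–lead correlations proportional to the effect sizes, and with
varying magnitudes that mechanically couples association strength to
lead-trait correlation — the signature of the *proportional* mode — even
though no such biology was planted. Second, disproportional magnitudes use a
fresh random (discordance-constrained) permutation per variant rather than a
strict anti-ranking: a fixed anti-rank profile would give every such variant
on a factor the same beta pattern, and their summed genetic covariance would
coherently distort the empirical trait correlations the classifier consumes.

The panel emulated in the benchmark (`simulate_mode_panel()`) has 6 tight
"lipoprotein-subclass-like" factors (8 traits each, loadings evenly spaced
over 0.78–0.95), 4 wide factors (10 traits each, loadings evenly spaced over
0.25–0.90) and 8 factor-free "small molecules": 96 traits. Loadings are
evenly spaced rather than drawn uniformly because a clustered draw starves
the classification statistic of correlation spread for a whole factor at
once; pathway and disproportional effects are planted on disjoint tight
factors so each mode's injected covariance cannot distort the other's
correlation structure. The real NMR panel's factor structure is not
characterized publicly; this layout is a modeling choice that reproduces its
salient features (tightly correlated subclass blocks, weakly correlated
composition measures, independent small molecules).

## Medication, rare-variant QC fields, outcomes

`generate_medication()` shifts the baseline measures of treated individuals
by `med_effect` (medication affects measures taken while on medication) and
produces a follow-up copy for a subset untreated at baseline with test–retest
correlation `retest_rho` (default 0.9); a fraction of that subset starts
medication between visits, shifting their follow-up values.
`generate_rare_annotations()` draws consequence classes, LOFTEE-like
confidence, CADD/REVEL-like scores and per-genotype DP/GQ/AB fields with
known pass/fail truth. `generate_outcomes()` uses a liability-threshold
model: liability = θ·trait + direct variant effects + N(0,1), cases being
the top `prevalence` quantile.

# Association core

`adjust_medication()` fits, per trait and per sex, `baseline ~ followup +
age + BMI + medication` on the untreated-at-baseline subset with both
visits. Under the generating model the raw medication term estimates
`−rho·effect` (the follow-up slope absorbs the retest correlation), so the
package reports the rescaled `−beta_med / beta_followup`, which is on the
medication-effect scale, and subtracts it from treated baselines
sex-specifically. Fewer than 100 eligible individuals per sex (configurable)
skips that sex with a warning — small medication classes cannot be reliably
estimated.

`run_scan()` performs per-variant OLS after projecting trait and dosages on
the covariates, with a MAF ≥ 0.5% filter for the common-variant scan. This
replaces whole-genome-regression machinery (two-step LOCO prediction), which
exists to absorb cryptic relatedness and polygenic background; the synthetic
cohort has neither unless planted, so plain covariate adjustment is the
appropriate desk-scale equivalent.

`inverse_variance_meta()` is fixed-effect IVW (`w = 1/se²`) and requires a
variant×trait in at least two strata, with Cochran's Q attached; ancestral
heterogeneity is flagged at p < 1×10⁻⁴ and sex heterogeneity at p < 5×10⁻⁸
(both configurable). Alleles are assumed harmonized by the generator; strand
flips are out of scope for synthetic data. `variance_explained()` uses the
standard `2f(1−f)β²`. `significance_threshold()` divides 5×10⁻⁸ by the
number of phenotypes — 2.0×10⁻¹⁰ for a 249-trait panel.

# Fine-mapping

`clump_regions()` merges ±500 kb windows around sentinels (book-ended
intervals merge) and absorbs anything touching the extended MHC
(chr6:25.5–34.0 Mb) into one region excluded from fine-mapping, where LD
complexity defeats the single-region assumptions.

`wakefield_log_abf()` is the closed form `0.5·log(1−r) + 0.5·z²·r` with
`r = W/(se² + W)`, computed in log space (stable beyond |z| = 40). The prior
effect variance defaults to `W = 0.04` — prior SD 0.2 on standardized
per-allele effects, a conventional weakly-informative choice for molecular
traits; it is configurable everywhere it appears.

`multisignal_finemap()` replaces a sum-of-single-effects variational model
with stepwise approximate conditional decomposition: greedily add the variant
with the smallest conditional p (COJO-style conditioning through the LD
matrix, `b_cond = b − R[,S] R_S⁻¹ b_S`), stop at the cap or when conditional
p > 5×10⁻⁸; per signal, a Wakefield credible set is computed from its
conditional statistics, members with |r| < 0.1 to the lead are dropped, and
sets whose leads are correlated at r² > 0.25 are pruned (smaller p wins,
position tie-break — deterministic and order-independent). The procedure is
evaluated for caps 2..10 and the configuration with the most surviving
signals is reported. Conditional standard errors are kept at the marginal
scale, a standard approximation accurate for modest effect sizes; the
rank-deficient LD case is ridge-regularized (1e-8, escalating to 1e-4 with a
log entry). The greedy path is computed once; caps are prefixes of it.

`joint_concordance_filter()` refits all leads of a region×trait jointly and
keeps signals that are genome-wide significant in both marginal and joint
statistics, sign-concordant, and within ±25% relative magnitude. Aliased
(collinear) leads are dropped by the fit itself and the weaker signal is
removed. `group_mqtls()` builds mQTL groups as connected components of the
r² ≥ 0.6 graph over lead variants (via igraph). `transancestry_refine()`
sums per-variant log ABFs across ancestries for credible sets with >1
variant and suggestive evidence (p < 1×10⁻⁵, a choice documented here since
no published value exists) in a non-discovery ancestry; the
independent-evidence summation is approximate and flagged as such, and the
refined set is not guaranteed smaller — both sizes are reported. Pruned-away
credible sets are discarded, not reassigned.

# Pleiotropy classification

For each mQTL group, `classify_mqtl()` computes `q25`, the 25th percentile
of pairwise absolute Pearson correlations among associated traits (absolute,
because particle-size and concentration measures are anticorrelated by
construction), and `statcor`, the Pearson correlation between per-trait
association strength (−log₁₀ p) and squared correlation with the lead trait.
The squared form is used for the correlation axis because it is sign-free.
Two deliberate choices:

* The lead trait itself is excluded from the statcor computation. Its point
  is (x = 1, y = max) *by definition*, carries no information about whether
  association tracks correlation, and its leverage dominated the estimate in
  small groups — collapsing disproportional and nonspecific groups into
  pathway/proportional in benchmark runs.
* With fewer than four associated traits (three non-lead points) statcor is
  undefined and the call falls back to the q25 rule alone: specific if
  q25 ≥ 0.6, else nonspecific. Groups of ≤3 weakly-correlated traits are
  therefore routed to nonspecific — the boundary the rule table leaves open.

`efo_pleiotropy()` quantifies phenotypic pleiotropy: catalog rows are kept
with a mapped trait, p < 5×10⁻⁸ and location information; rows under
excluded ontology roots (metabolite-like measurement terms) are dropped;
remaining terms are walked up to the children of the ontology roots (cycle
guard; orphans fall into an `unmapped` pseudo-parent) and distinct parent
categories counted over the group's variants and r² > 0.8 proxies. Fewer
than five parent terms is phenotypically `specific`.
`category_enrichment()` is per-category logistic regression of category hits
on pleiotropic-vs-specific, Bonferroni-corrected, with separation detection.

# Effector genes

Candidates are up to the ten closest genes within ±1 Mb (distance 0 inside
the gene body; ties broken by gene id). Features are binary evidence flags —
coding consequence, per-tissue eQTL, metabolic-database membership, OMIM,
phase III/IV drug target — set if the variant or any r² > 0.6 proxy supports
them, plus distance and closeness rank.

Three putative-true-positive (PTP) sets pair fine-mapped variants of a
metabolite class (cholesterol, lipid, amino acid) with pathway-database
genes of that class; negatives are the other candidates of the same
variants. Variants eligible for several classes are assigned to exactly one
by the fixed priority cholesterol > lipid > amino acid (the assignment must
be single; the priority follows set size in the source databases). Splits
are 7:3 by variant, so no variant straddles train and test — asserted in the
test suite for every split. Features that define the labels are excluded
from the model.

`train_classifier()` fits a random forest tuned by fivefold CV grouped by
variant, with majority-class subsampling per fold, selected by balanced
accuracy; held-out ROC-AUC and balanced accuracy are reported.
`score_genes()` sums the three positive-class probabilities into the 0–3
effector score (the median is kept as a diagnostic column); per variant the
assigned set is the top block above the largest gap between consecutive
scores, with tiers at ≥1.5 (moderate) and ≥2 (high). If all gaps are equal
(including all-zero) no assignment is made and the variant is flagged
low-confidence. Cross-validation of assignments against an external
protein-QTL colocalization resource is out of scope; a set-intersection
utility (`compare_assignments()`) is provided for comparing two assignment
tables.

# Rare variants

`genotype_qc()` masks genotypes with DP < 7 (SNV) / DP < 10 (indel) or
GQ < 20, excludes variants with any heterozygote at allele balance outside
[0.25, 0.8] (the strict reading; a fraction-based alternative is available
behind `ab_fraction` since the rule is ambiguous at biobank scale), and
excludes variants with post-masking missingness above 50%. The filter is
idempotent. The packaged 10-variant toy VCF (synthetic, with constructed
failures) pins the expected behavior exactly.

`build_masks()` implements the six overlapping masks — high-confidence pLOF;
any pLOF; pLOF + high-impact missense (CADD > 20 or REVEL > 0.5); pLOF + any
missense; high-impact only; missense-only — plus the synonymous negative
control, each crossed with MAF bins below 0.5% and 0.005%. The nesting
M1 ⊆ M2 ⊆ M4 and the disjointness of the synonymous control are asserted on
every fixture. Burden is the capped allele count `min(2, Σ alt)` per
individual (the collapsing scheme of the reference tooling is not published;
the cap bounds the influence of multi-carrier individuals), with missing
genotypes counted as 0 and per-gene missingness reported.

`acat()` combines p values by the Cauchy transform. Numerically,
`tan((0.5−p)π)` is evaluated as `1/tan(pπ)` — the direct form evaluates tan
near its pole and loses about five digits — the tail is computed through the
Cauchy distribution function (no cancellation at small p), and p < 10⁻¹⁵
uses the tangent asymptote `1/(pπ)`. ACAT of k copies of p returns p to
machine precision.

`burden_test()` fits the trait on each mask×bin burden with and without the
per-trait polygenic score of lead credible-set variants, combines per-mask p
values by ACAT, and flags a finding `robust` only if significant in both
models (gene-level threshold 1.2×10⁻⁸ by default; the alternative printed
value 1.1×10⁻⁸ is inconsistent with the stated correction and not used)
with effect sizes within 20%. `exwas()` tests single rare variants at
MAC > 5 and reports at MAF < 5×10⁻⁴. `disease_burden()` is plain logistic
regression with a ≥10-carrier guard and separation detection — a saddle-point
tail approximation is unnecessary at the simulated case counts and carrier
frequencies, where the Wald test is well behaved. `allelic_series()` links
rare hits to the nearest same-trait lead credible-set variant (flags at
100 kb, 500 kb, 1 Mb) and sets the series flag when an effector assignment
within 200 kb names the rare hit's gene.

# Causal integration

`coloc_abf()` enumerates the five colocalization hypotheses from per-variant
Wakefield log ABFs of the two traits with priors p1 = p2 = 1×10⁻⁴ (the
conventional defaults of the methodology; only the shared prior is
study-specific) and p12 = 5×10⁻⁶, in log space throughout; H3 uses the
log-difference identity rather than the explicit pair sum, and the test
suite checks it against literal enumeration to 10⁻¹⁰. Pairs with fewer than
10 shared variants are flagged low-confidence. `coloc_all_pairs()` caps the
outcome decomposition at five signals. A locus effect is declared at
PP4 ≥ 0.8.

`ivw()` implements `β = Σ(βx·βy/se_y²)/Σ(βx²/se_y²)` with
`se = 1/sqrt(Σ(βx²/se_y²))`, deferring to the Wald ratio for a single
instrument; `mr_egger()` is weighted least squares with intercept after
orienting exposure effects nonnegative, with the intercept tested against
the 1×10⁻⁴ pleiotropy rule. Instrument tiers: sentinels; lead credible-set
variants; leads from groups classed specific/pathway (molecular filter);
additionally EFO-specific (phenotypic filter) — nested by construction.
Concordance across IVW, Egger and the median Wald ratio is enforced as sign
agreement; no numeric rule is published, and sign agreement is the weakest
defensible reading. Level effects are controlled at FDR 5%
(Benjamini–Hochberg).

`level_locus_convergence()` intersects passing level effects with locus
effects (excluding disproportional/nonspecific loci from locus-effect
reporting) and evaluates LDL independence: no variant at the locus reaches
p < 2.0×10⁻¹⁰ on LDL cholesterol *and* — under the default `exclude_top`
reading — no variant's |LDL effect| sits at or above the 80th percentile of
the locus's |effect| distribution across measures. The sentence defining the
percentile clause admits two readings; both are implemented
(`rank_rule = "p_only"` applies only the p-value clause) and the strict one
is the default.

# Benchmark problem sizes

The packaged calibration experiments use: 300 single-causal regions
(n = 50,000, 50 variants, β = 0.15, MAF 0.2) for credible-set coverage;
100 + 100 colocalization replicates (n = 2×25,000 halves, 30 variants) for
shared/distinct causal separation; 250 planted mQTL groups (50 per mode,
n = 50,000, 96 traits, all effects ≥ 0.1 SD) for mode recovery; 100 IVW and 1,000
Egger replicates (50 instruments) for MR calibration; 200 simulated genes
(n = 20,000, ~80 carriers) for the PGS-robustness rule; 60 synthetic loci
(6 candidate genes each) for effector scoring; and 10,000 replicates for the
null distribution of Cochran's Q. These sizes keep every experiment
reproducible on a single CPU while leaving the measured rates comfortably
clear of their calibration bounds.

# Known limitations

* LD is blockwise-autoregressive; long-range LD, structural variation and
  imputation uncertainty are not modeled, so fine-mapping results speak to
  calibration under correct LD, not to robustness against mis-specified LD.
* The stepwise conditional decomposition shares the failure modes of all
  conditional approaches when causal variants are in near-perfect LD; the
  r² > 0.25 pruning rule then keeps a single representative signal.
* Trans-ancestry refinement assumes independent evidence across strata,
  which overstates precision when strata share haplotypes.
* The effector-gene benchmark plants fully informative features; real
  annotation evidence is sparser and noisier, and held-out performance on
  real data would be correspondingly lower.
* Binary-outcome burden tests use plain logistic regression; at very low
  case counts a small-sample tail correction would be needed.
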