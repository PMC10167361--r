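---
title: "dishmap: statistical methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dishmap: statistical methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dishmap)
```

## Scope

Diffuse idiopathic skeletal hyperostosis (DISH) is an ectopic calcification
of spinal ligaments that fuses adjacent vertebrae.  Large imaging biobanks
make it possible to score DISH severity at scale (a Kuperus-style ordinal
"flow score" per intervertebral junction, summed over the spine) and to
treat the aggregate score as a quantitative trait for genetic analysis.
`dishmap` implements the downstream statistical machinery of such a study
as reusable, tested components:

1. summary-statistics quality control and locus definition;
2. approximate conditional/joint analysis to split loci into distinct
   association signals;
3. per-signal fine-mapping with approximate Bayes factors and ranked
   credible sets;
4. Bayesian colocalization of two traits with strong/suggestive decision
   rules and an effect-direction call;
5. two-sample Mendelian randomization (Wald ratio, IVW, MR-Egger, weighted
   median, weighted mode) with a gene-screen driver and multiple-testing
   control;
6. a bin-based projection of population prevalence from flow scores and a
   score-to-diagnosis curve.

Cohort-scale individual-level data (UK Biobank genotypes, GTEx eQTL
summary statistics) are access-controlled, so the package ships a
synthetic-data module that generates every input the pipeline consumes
with known ground truth.  All empirical claims about the methods are made
by the test suite and `scripts/acceptance.R`, which run entirely on that
synthetic data.

## Data model

Summary statistics are position-sorted tables of per-variant records
(chromosome, 1-based GRCh37 position, effect/other allele, effect-allele
frequency $f_j$, effect $\hat\beta_j$, standard error, p-value, sample
size $n_j$, optional imputation quality and missingness).  Coordinates are
1-based inclusive everywhere.  QC applies the usual filters — MAF $\ge$
0.01, info $\ge$ 0.9, missingness $\le$ 0.10, exact Hardy–Weinberg p $\ge$
10⁻¹⁰ (computed on reference-panel genotypes when available, skipped
otherwise) — and reports per-rule exclusion counts, attributing a variant
failing several rules to the first rule in that order so the counts add up.
Loci are defined greedily: the smallest-p variant with p < 5×10⁻⁸ indexes
a ±500 kb window; significant variants inside are absorbed; indices inside
the GRCh37 MHC interval (6:28,477,797–33,448,354) are excluded because of
its extreme LD structure.  Multi-allelic records (duplicate position with a
different allele pair) are rejected with a warning rather than guessed at.

## Fine-mapping

For variant $j$ with estimated effect $\hat\beta_j$ and variance
$V_j = \mathrm{se}_j^2$, the natural-log approximate Bayes factor under a
Gaussian effect prior $b \sim N(0, \omega)$ is the Wakefield closed form

$$\Lambda_j = \tfrac12 \log\frac{V_j}{V_j+\omega}
  + \frac{\omega\,\hat\beta_j^2}{2 V_j (V_j+\omega)},$$

equivalently the log-ratio of the marginal likelihood
$N(\hat\beta_j; 0, V_j+\omega)$ to the null likelihood
$N(\hat\beta_j; 0, V_j)$; the test suite verifies this against numerical
quadrature of the prior integral to 10⁻⁸ relative.

The prior variance is $\omega = (0.15\,\sigma)^2$, with the phenotype
standard deviation $\sigma$ recovered from the summary statistics
themselves: for a linear-regression scan,
$\mathrm{Var}(\hat\beta_j) \approx \sigma^2 / (2 n_j f_j (1-f_j))$, so
$\sigma^2$ is estimated as the no-intercept least-squares slope of
$2 n_j f_j (1-f_j)$ on $1/\mathrm{Var}(\hat\beta_j) - 1$.  The $-1$ is
kept as part of the estimator's definition; it is numerically negligible
whenever effect variances are small, and it contributes a deterministic
relative bias of order $\mathrm{Var}(\hat\beta)$ that shrinks with sample
size.  $\sigma$ is a global property of the trait and is estimated once
from all available variants, never per locus.  For a standardized
phenotype $\sigma \approx 1$ and $\omega \approx 0.0225$, which the tests
use as a reference point.

Posteriors over the $l$ variants of a region include an explicit
no-association model with prior mass $\gamma$ and Bayes factor 1:

$$\pi_j = \frac{\frac{1-\gamma}{l}\, e^{\Lambda_j}}
  {\gamma + \frac{1-\gamma}{l} \sum_{k=1}^{l} e^{\Lambda_k}},$$

with $\pi_0$ the complementary null mass, computed in log space so that
$|\Lambda|$ in the hundreds cannot overflow.  The default $\gamma = 0.05$
reflects that regions enter fine-mapping only after passing the
genome-wide threshold, so a 5% prior false-discovery allowance is
appropriate.  The credible set ranks variants by descending $\Lambda$
(ties broken by position for determinism), renormalizes $\pi$ over the
variants only — the set is defined conditional on the region containing a
signal — and accumulates until the cumulative mass reaches the threshold.
The default threshold is 0.99, the value the procedure is defined with;
variants with $\pi_j >$ 1% are additionally flagged as potential causal
variants.

In loci with several distinct signals, fine-mapping is run twice per
signal: on the marginal statistics and on conditional statistics that
adjust for the locus's other index variants (below), which isolates one
signal at a time.

## Distinct signals: approximate joint and conditional analysis

Joint effects for a set of selected variants are reconstructed from
marginal effects and a reference LD matrix in the GCTA-COJO manner: with
per-variant genotype sums of squares $D_j$ (defaulting to the
Hardy–Weinberg value $2 f_j (1-f_j)(n-1)$, or realized dosage variances
when a panel is supplied), $X'X = D^{1/2} R D^{1/2}$ and
$X'y_j = \hat\beta_j D_j$, so the joint solution and its covariance follow
from ordinary regression algebra with the residual variance recomputed
from the phenotypic variance $\sigma^2$ and the current fit (floored at
10⁻¹²; degrees of freedom $n-k-1$).  With in-sample LD and realized
variances this equals the individual-level multiple regression to
numerical precision, which the tests verify at 10⁻⁸ relative.  With
reference-panel LD a ridge of 10⁻⁸ (relative to the mean diagonal) guards
against finite-panel noise.

Stepwise selection starts from the locus index variant (which must be
genome-wide significant), repeatedly adds the variant with the smallest
conditional p-value provided its joint p-value stays below 10⁻⁶, skips
candidates with $r^2 > 0.9$ against any selected variant (the usual COJO
collinearity guard; forward-with-backward-check is the conventional step
order for these tools and is adopted here), and
after each addition drops any previously selected variant whose joint
p-value has risen above the threshold.  Conditional statistics for a
variant are its coefficient in a joint fit with the conditioning set;
conditioning variants themselves (and candidates with $r^2 > 0.9$ against
them) report a conditional effect of zero.

## Colocalization

Under the one-causal-variant-per-trait assumption, the five hypothesis
posteriors (H0 none, H1/H2 one trait only, H3 two distinct causal
variants, H4 one shared causal variant) are sums of per-variant ABF
products weighted by per-variant priors $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$, evaluated in log space and verified against exhaustive
configuration enumeration.  Each trait's $\omega$ comes from its own
$\sigma$ estimate, since the traits are on different scales.  Variants
present in only one trait are dropped (two-sample intersection practice).
Classification follows fixed rules: *strong* if PP3+PP4 ≥ 0.99 and
PP4/PP3 ≥ 5; *suggestive* if PP3+PP4 ≥ 0.8 and PP4/PP3 ≥ 3; otherwise
*none*, with a numerically zero PP3 treated as an infinite ratio.  The
effect direction (correlated vs anti-correlated) is the sign of
$\hat\beta_1 \hat\beta_2$ at the variant maximizing the per-variant H4
contribution.

## Mendelian randomization

Instruments are genome-wide-significant exposure variants pruned greedily
by p-value at $r^2 < 0.01$ within 250 kb, harmonized to the outcome and
aligned to the exposure-increasing allele (the orientation the median and
mode estimators require; all estimators are invariant to the original
allele coding, which the tests check).  Per-instrument Wald ratios
$\hat\beta_{out}/\hat\beta_{exp}$ carry first-order delta-method standard
errors.  The estimators:

* **IVW** — fixed-effect inverse-variance combination of Wald ratios,
  identical to zero-intercept weighted regression of outcome on exposure
  effects with weights $1/\mathrm{se}_{out}^2$ (verified against the WLS
  closed form).
* **MR-Egger** — the same regression with a free intercept; the slope is
  the causal estimate, the intercept flags directional pleiotropy.
  Standard errors keep the regression dispersion when it exceeds 1;
  p-values use $t_{k-2}$.
* **Weighted median** — Wald ratios ordered, inverse-variance weights
  turned into cumulative percentiles $(S_i - w_i/2)/S$, linear
  interpolation at one half.
* **Weighted mode** — mode of the weighted Gaussian-kernel density of the
  ratios (weighted-Silverman bandwidth × configurable factor; grid search
  plus local optimization).  As the bandwidth grows the estimate
  approaches the weighted mean, a limit the tests exercise.

Median and mode standard errors come from a seeded parametric bootstrap
(default 1000 replicates) over the instrument estimates.  The gene screen
dispatches the Wald ratio for single-instrument genes and IVW otherwise,
attaches Egger/median/mode sensitivity estimates when at least three
instruments exist, flags sign concordance across estimators, and adjusts
primary p-values across genes.  Because "Bonferroni with an FDR cutoff"
conflates two procedures, Benjamini–Hochberg at FDR 0.1 is the primary
adjustment — FDR is the stated cutoff quantity — with Bonferroni reported
alongside.

## Prevalence projection

The aggregate flow score is the sum of per-junction ordinal scores (0–3
over up to 14 junctions, range 0–42).  A weak-ridge logistic fit (penalty
10⁻³ on the slope, intercept unpenalized) maps scores to the probability
of an expert DISH diagnosis; the ridge keeps the fit finite under the
complete separation that small per-bin validation samples invite, and a
negative fitted slope is rejected as inconsistent with the severity scale.
Stratum prevalence is $\sum_b f_b\,\hat p(m_b)$ over score bins of width 4
(bins 0–3, 4–7, …, matching a design that samples validation images per
score bin; the width is configurable since exact bin edges are a free
choice), with $f_b$ the stratum's bin frequency and $m_b$ the bin
midpoint.  Projected counts scale prevalence by stated population stratum
sizes; uncertainty is a seeded bootstrap resampling both the cohort and
the validation labels (curve refit per replicate).  Empty strata are
reported as missing, not zero.

## The synthetic-data module

Genotype panels: each sample is the sum of two independent haplotypes; a
haplotype is, per LD block, a first-order Markov chain over binary alleles
whose adjacent-pair correlation targets the configured `rho`, with allele
frequencies following a bounded logit-scale random walk inside the
configured MAF range.  This yields Hardy–Weinberg dosages whose realized
adjacent LD matches the target (≈0.9 at `rho = 0.9`) and decays
geometrically with distance.  A latent-Gaussian threshold scheme was
considered and rejected: discretization attenuates the realized dosage
correlation far below the latent value (≈0.62 at 0.9), while the Markov
construction controls the realized quantity directly.  Locally smooth
allele frequencies are required because the attainable correlation
between binary variables shrinks as their frequencies diverge (Fréchet
bounds) — also a feature of real tightly-linked variants.

Phenotypes are additive, $y = \sum_c \beta_c g_c + \varepsilon$, with the
noise variance set from the realized genetic variance so the realized
heritability matches the target, then standardized to unit variance (so
$\sigma = 1$ and $\omega \approx 0.0225$ are known reference points).
Marginal scans are per-variant simple regressions matching an independent
least-squares oracle to 10⁻¹⁰.  Trait pairs for colocalization are two
independent cohorts drawn from the same LD structure, sharing or not
sharing a causal variant (distinct causals constrained to realized
$r^2 < 0.3$).  MR scenarios are summary-level: true instrument effects
$\,\sim |N(0.2, 0.1^2)|$, outcome effects
$\theta\,\beta_{exp,i} + \alpha_i$ with $\alpha_i$ zero / zero-mean /
positive-mean on a configurable fraction of invalid instruments, and
independent estimation noise in the two studies on the
$1/\sqrt{2f(1-f)n}$ scale.  The instrument-strength spread (sd 0.1) is a
deliberate study condition: the Egger intercept is identified by variation
in instrument strength, and with near-equal instrument effects directional
pleiotropy is essentially undetectable by any implementation.  Spine-score
cohorts have ages 45–85, both sexes, and an age- and sex-dependent ordinal
junction model plus a known logistic diagnosis curve used to draw expert
labels.

All generators are pure functions of (configuration, seed); a single
master seed expands into per-stage substreams through a counter scheme, so
adding a stage never perturbs earlier draws.

What the generator does **not** emulate: population structure and
relatedness (the mixed-model GWAS step is out of scope), genotyping or
imputation error (`info` is an input, not simulated), sample overlap
between the two MR studies, linkage between MR instruments, and
multi-causal colocalization.  Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery under its own
assumptions, not robustness to those real-data complications.

## Parameters at a glance

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| locus p-threshold | 5×10⁻⁸ | `define_loci` | genome-wide significance |
| locus window | ±500 kb | `define_loci` | span around index variant |
| joint p-threshold | 10⁻⁶ | `stepwise_selection` | locus-wide signal evidence |
| collinearity guard | r² 0.9 | `joint_effects` | COJO convention |
| ridge | 10⁻⁸ | `joint_effects` | reference-panel noise |
| `omega_scale` | 0.15 | `finemap_config` | prior sd as fraction of σ |
| `gamma` | 0.05 | `finemap_config` | prior mass of no association |
| `credible_mass` | 0.99 | `finemap_config` | cumulative set threshold |
| PIP flag | 0.01 | `finemap_signal` | potential-causal threshold |
| coloc priors | 10⁻⁴/10⁻⁴/10⁻⁵ | `coloc_config` | p1, p2, p12 |
| instrument p | 5×10⁻⁸ | `select_instruments` | instrument significance |
| pruning | r² 0.01, 250 kb | `select_instruments` | instrument independence |
| FDR cutoff | 0.1 | `mr_pipeline` | BH across genes |
| score bin width | 4 | `estimate_prevalence` | prevalence bins |
| ridge penalty | 10⁻³ | `fit_diagnosis_curve` | separation guard |
| ambiguity MAF | 0.4 | `harmonize_alleles` | palindromic drop rule |

## Numerical choices

Hypothesis and posterior sums are computed in log space throughout
(log-sum-exp; a guarded `log1p` difference for the H3 term).  Ranking ties
break by genomic position.  Residual variances are floored at 10⁻¹²;
p-values at the smallest positive double so they stay in (0, 1].  The
Hardy–Weinberg test is the exact conditional test on genotype counts.
The weighted-mode density maximum is located by a 512-point grid followed
by local optimization, so bandwidth limits behave analytically.

## Problem sizes used by the checks

The test suite and acceptance script size their simulations to be
informative at desk scale: credible-set coverage over 200–500 loci of 200
variants at n = 5000 with effects giving median causal p ≈ 10⁻¹⁰;
two-signal recovery over 60–100 loci meeting the stated separation and
significance conditions (redrawn until met, since the conditions define
the scenario); colocalization discrimination over 60–100 trait pairs per
hypothesis; MR calibration over 200 replicates (null uniformity over
300–500); prevalence recovery over 60–100 cohorts of 800.  The bundled
end-to-end demo runs a two-locus genome of 240 variants at n = 2000 with
total h² = 0.1 (one causal per block), deterministic and byte-identical
under a fixed seed.

## Known limitations

Fine-mapping is strictly per-signal single-causal (the conditional
decomposition is the method; no SuSiE/FINEMAP-style joint search).
Colocalization assumes at most one causal variant per trait at the locus.
The σ estimator assumes a quantitative trait analyzed by linear
regression.  No genome-build liftover, no binary genotype formats, no
X-chromosome dosage model, and no genome-wide joint stepwise across loci.
The prevalence projection inherits any miscalibration of the
score-to-diagnosis curve outside the fitted score range.
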