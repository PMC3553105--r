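---
title: "Spike-and-slab stochastic search for gene-nutrient case-control studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-and-slab stochastic search for gene-nutrient case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Candidate-gene case-control studies of diet-related cancer risk face a joint
selection problem: dozens of tag SNPs in linkage disequilibrium (LD), a
panel of correlated nutrient intakes, and their pairwise gene-nutrient
interactions, all competing to explain a binary disease outcome measured on
a few hundred subjects per smoking stratum. Stepwise selection is unstable
in this regime; `folatessvs` instead implements stochastic search variable
selection (SSVS), a Bayesian model-averaging approach, as a complete
three-stage pipeline: quality control and tag-SNP selection, per-block
screening by posterior inclusion probability, and a joint final model with
interactions selected by marginal Bayes factor.

## Model

For subjects $i = 1, \dots, n$ in one smoking stratum with case status
$y_i \in \{0, 1\}$,

$$\mathrm{logit}\, P(y_i = 1) = x_i^{f\top} \beta_f + x_i^{s\top} \beta_s,$$

where $x^f$ collects the forced-in covariates (intercept, sex, age, family
history, and the stratum's smoking covariate: ETS exposure for never
smokers, a 3-level age-at-cessation factor for former smokers, a 4-level
pack-year factor for current smokers) and $x^s$ the selectable variables
(SNP additive codes, energy-adjusted nutrients, interaction products).

Each selectable coefficient carries a spike-and-slab prior driven by a
binary inclusion indicator $\gamma_j \sim \mathrm{Bernoulli}(p_j)$ with
$p_j = 0.5$ by default:

$$\beta_s \mid \gamma \sim N(0, D_\gamma R D_\gamma), \qquad
D_\gamma = \mathrm{diag}\{c\tau \text{ if } \gamma_j = 1,\ \tau
\text{ otherwise}\}.$$

$R$ is a prior correlation matrix: pairwise LD $r^2$ between SNPs within
400 kb on the same chromosome, zero for farther or cross-chromosome pairs,
and identity for nutrients and interactions (independent normal priors
centered at zero). Forced coefficients get vague independent
$N(0, \sigma_f^2)$ priors and never enter selection.

Inference quantities follow standard Bayesian model-averaging definitions:

- **PPI**: the fraction of kept posterior draws with $\gamma_j = 1$;
- **marginal Bayes factor**: posterior odds over prior odds,
  $\mathrm{BF}_j = \frac{\mathrm{PPI}_j/(1-\mathrm{PPI}_j)}{p_j/(1-p_j)}$;
- **expected FDR** of a selected set $S$:
  $\frac{1}{|S|}\sum_{j \in S}(1 - \mathrm{PPI}_j)$;
- **conditional model-averaged OR**: $\exp$ of the posterior mean of
  $\beta_j$ over inclusion draws, with a percentile credible interval.

The three-stage flow screens SNPs and nutrients in separate stochastic
searches (advance if PPI > 0.35, strict), then jointly searches the
survivors plus their pairwise interaction products (selection if BF > 3,
strict, which at $p = 0.5$ equals PPI > 0.75 and keeps the expected FDR of
reported sets near or below 0.15). Both thresholds are strict inequalities,
and the convention is recorded in the output.

## Sampling

The posterior over $(\beta, \gamma)$ is explored by Markov chain Monte
Carlo. The default kernel is Polya-Gamma augmented Gibbs: with
$\omega_i \sim \mathrm{PG}(1, x_i^\top\beta)$ the conditional of the full
coefficient vector is multivariate normal with precision
$X^\top \Omega X + P_\gamma$ and mean solving
$(X^\top \Omega X + P_\gamma)\, m = X^\top(y - \tfrac12)$, where
$P_\gamma$ is the block prior precision. PG(1, z) variables are drawn
exactly by the alternating-series rejection sampler, implemented in C++
along with the whole chain; all randomness flows through R's RNG so a seed
makes runs bit-identical. Indicators are updated by Gibbs in a random scan
using the spike/slab multivariate-normal density ratio with the
precomputed $R^{-1}$. An adaptive component-wise random-walk Metropolis
kernel (`algorithm = "rwmh"`, tuned toward 0.44 acceptance during burn-in
only) targets the identical posterior and serves as a cross-check.

Two chains with distinct starting points are run by default — the first
from the null model ($\gamma = 0$), the others from independent
Bernoulli($p$) draws — for 300,000 iterations each, keeping the last two
thirds. Chains are pooled when their PPI vectors correlate at 0.95 or
better (with a max-absolute-difference fallback of 0.05 when a PPI vector
is constant); otherwise the pipeline warns and reports the pooled summary
alongside the disagreement. The bundled validation scenarios use a 20,000
iteration, 2-chain profile, which the enumeration oracle shows is
converged for problems of that size.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tau` | 0.05 | spike sd: an excluded log-OR is effectively zero |
| `c` | 10 | slab multiplier: slab sd 0.5 admits per-unit ORs ~0.4-2.7 at 1 sd |
| `p` | 0.5 | prior inclusion probability per selectable variable |
| `sigma_forced` | 10 | vague sd for forced coefficients and intercept |
| `max_distance` | 400 kb | LD-prior independence distance |
| screen threshold | 0.35 | stage-2 PPI rule (strict) |
| final threshold | 3 | stage-3 marginal-BF rule (strict) |
| `tag_r2` | 0.8 | greedy tag-binning threshold |
| `hwe_alpha` | 0.001 | Hardy-Weinberg exclusion level, controls only |
| `collinearity_r2` | 0.8 | interaction pruning cutoff |

The spike and slab scales are the package's own defaults (the methodology
literature gives no canonical value); they are configurable everywhere and
recorded in the results bundle metadata. Continuous selectable columns are
standardized inside the sampler so one slab scale is meaningful across
units; SNP columns stay on the 0/1/2 scale so their ORs read per minor
allele, and reported ORs can be rescaled per unit on request. No
strong-heredity constraint links interactions to their main effects: an
interaction can be selected while its mains are not, which is a deliberate
property of the screening design.

## Design choices where the design was open

- **Major allele**: determined empirically from the full data set before
  stratification; 50/50 ties break to the lexicographically smaller allele.
  Deterministic and stratum-consistent.
- **2x2 chi-square**: Yates continuity correction for 2x2 descriptive
  tables (plain Pearson for larger tables); the missingness-vs-status check
  uses plain Pearson, which keeps its type-I rate at the nominal level in
  calibration runs.
- **Alcohol bins**: the published category labels leave (29.9, 30)
  unassigned; bins are closed as [0], (0,5), [5,15), [15,30), [30, Inf), so
  29.95 g/day falls in the 15-29.9 category.
- **Wilcoxon tests**: exact below 25 subjects per arm, otherwise the
  normal approximation with tie correction.
- **Energy adjustment**: residual method; the residual is re-centered at
  the predicted intake at mean energy, which for simple least squares
  equals the nutrient mean, keeping adjusted values on the intake scale.
  Subjects missing a nutrient are dropped from that nutrient's analyses
  only, and per-analysis complete-case counts are logged.
- **LD for tagging**: squared Pearson correlation of additive codes
  (composite LD) on pairwise-complete observations; haplotype phasing is
  out of scope and unnecessary for r-squared binning. Tagging uses all
  subjects by default; Hardy-Weinberg testing uses controls only, the
  case-control QC convention.
- **Tag tie-breaks**: max-connectivity seeds and equal-coverage tags
  resolve by rsID order, for determinism.
- **Prior correlation entries** use the unsigned $r^2$ itself; the sign of
  LD is unavailable from an $r^2$ table. The matrix is repaired to positive
  definite by flooring eigenvalues at 1e-6 and rescaling to unit diagonal.
- **Interaction pruning order** is lexicographic by (SNP, nutrient), so
  which member of a collinear pair is dropped is reproducible.
- **Former smokers missing cessation age** (and current smokers missing
  pack years) are dropped from their stratum with a warning rather than
  imputed.
- **Descriptive medians** are computed on energy-adjusted intakes, and the
  report labels them as such.

## The synthetic cohort generator

Raw cohort data of this kind are rarely shareable, so the generator is a
first-class module that emulates the statistical structure the analysis
assumes: six gene blocks totalling 115 tag-level SNPs with within-block LD
(latent AR decay, or calibrated to explicit r-squared targets through the
bivariate-normal orthant probability), Hardy-Weinberg-exact genotypes (two
independent thresholded Gaussian copies per subject), 15 energy-correlated
log-normal nutrient intakes with an alcohol zero-mass, three smoking strata
of 316/427, 453/266 and 406/357 cases/controls, logistic disease risk with
a few planted SNP, nutrient and interaction effects of magnitude
|log OR| ~ 0.5-0.74, per-SNP missingness around 0.1% (with a few
high-missingness SNPs that the QC filter should catch, and a higher rate in
current smokers), and exact retrospective case/control sampling from a
20-fold oversampled source population.

What the generator does **not** emulate: food-frequency measurement error,
population stratification, relatedness, haplotype-level LD beyond pairwise
targets, and genotyping batch effects. Passing tests on synthetic cohorts
therefore validate the selection machinery — calibration under the null,
power against planted effects of published magnitude, determinism — not the
reproduction of any particular study's findings, whose raw data are not
publicly deposited.

## Numerical choices and validation scale

- The enumeration oracle computes every model's marginal likelihood by
  adaptive Gauss-Hermite quadrature (11 nodes per dimension, centered at
  the per-model mode and curvature) and is practical to m ~ 6 selectable
  variables; MCMC PPIs from 2 x 20,000 iterations agree with it within
  0.03 on the n = 60, 3-variable validation instance.
- Signal recovery uses 10 replicates of a planted per-allele OR 2.0 SNP
  (MAF 0.3) in 350/350 retrospective strata; null calibration uses 20
  replicates of an all-null 50-SNP stratum of 500 subjects. Both run the
  20,000-iteration 2-chain profile.
- The end-to-end demonstration pipeline uses a reduced 20-SNP panel and
  short chains: its role is to exercise every stage and verify bit-level
  determinism of the results bundle, not posterior accuracy.
- The Hardy-Weinberg exact test uses a numerically stable log-scale
  recurrence and is checked against full enumeration for all counts with
  n <= 30.
- Degenerate inputs are handled explicitly: monomorphic SNPs encode
  all-zero (then fail the MAF filter), zero-variance energy errors, empty
  selected sets report a not-applicable expected FDR, and odds ratios are
  reported only when a variable has at least 20 inclusion draws.

## Known limitations

- With small strata and many correlated candidates the stage-2 screen is
  permissive (that is its purpose); stage-3 BF > 3 selection, not the
  screen, controls the reported set.
- The LD-informed prior depends on the r-squared source supplied; with the
  bundled generator the empirical LD of the simulated cohort stands in for
  an external reference panel, and results inherit that choice.
- PPIs near the 0.75 selection boundary carry Monte Carlo noise of a few
  hundredths at the validation profile; borderline selections should be
  re-run at the full 300,000-iteration profile.
- Conditional ORs for rarely included variables are percentile summaries
  of few draws and are flagged unstable rather than suppressed.
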