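---
title: "Multi-source Bayesian regression for cross-study drug-response biomarkers"
author: "bmsr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source Bayesian regression for cross-study drug-response biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmsr)
```

## The problem

Ex vivo drug screens profile primary patient samples (for example AML
mononuclear cells) against large drug panels, alongside bulk gene expression.
Two screens of the same disease rarely agree in their details: different
panels, concentration designs, culture media, and cohorts. Biomarker models
trained on one study often fail to transfer to another. This package
implements a joint, hierarchical treatment of that problem: one regression
per study, with the studies' coefficient vectors tied to a shared, sparse
vector. The shared vector is the cross-study biomarker profile; the per-study
vectors absorb study-specific deviation.

Around that core the package provides the standard processing a drug screen
needs before any regression is meaningful: log-logistic dose-response
fitting, a normalized area-under-curve (AUC) response summary, quality
control, the *general response across drugs* (GRD) statistic and its use as
a covariate, single-sample gene-set scoring, and synthetic-data generators
that make every step testable without access-restricted patient data.

## Dose-response processing

A series is one drug on one sample in one replicate. Responses are percent
inhibition, rising with dose; viability input is converted as
`100 - viability` at read time, because the monotonicity criterion below
presumes an increasing curve.

Curves are fit with the four-parameter log-logistic family

$$f(x) = c + \frac{d - c}{1 + \exp\{b(\log x - \log e)\}},$$

in the `drc`-style parameterization: `d` and `c` are the high- and low-dose
asymptotes, `e` the inflection concentration, and a rising curve has
`b < 0`. LL3 fixes `c = 0` (zero response at vanishing dose). Fitting is
penalized-free least squares by Levenberg-Marquardt descent from a fixed
grid of slope and inflection starts, so results are deterministic; box
constraints keep the asymptotes on a physically sensible percent scale and
the inflection within two decades of the tested range. Without those bounds
the three-parameter family can mimic almost any gentle monotone trend over a
finite range by sending `d` to absurd values, which silently defeats the
LL3-vs-LL4 quality-control comparison below.

AUC integrates the fitted curve over log10 concentration across the drug's
tested range, after clipping the curve to 0-100, and divides by
`100 * range width`. The result lives in [0, 1]: 0 means no inhibition
anywhere, 1 complete inhibition everywhere. Integration in log10 dose with
that normalization follows the PharmacoGx convention; the quadrature is
adaptive and is tested against a dense trapezoid oracle.

Screens are filtered before analysis:

* per drug, only series on the *modal* `(min, max, n_points)` concentration
  design are kept (ties break to the lexicographically smaller tuple, so the
  rule is deterministic); a series missing an interior point fails the tuple
  match and is excluded;
* one sample per patient — the sample assayed on the most drugs, ties broken
  by sample id.

Three outlier *annotations* (they flag, they do not remove — exclusion is
the caller's decision): (1) `non_monotone` when the fitted LL4 curve
decreases anywhere on the tested range by more than `1e-6`; (2)
`ll3_ll4_divergent` when constraining the low-dose asymptote to zero moves
the AUC by more than `delta = 0.2`; (3) `replicate_discordant` when two
replicates' AUCs differ by more than `rho = 0.3`. The two AUC thresholds are
in normalized-AUC units and are deliberate, config-exposed defaults: the
choice of exact values is a judgment call about screen quality, not a fact
about the model.

## GRD, MRP and cross-study concordance

GRD is a sample's mean raw AUC over a drug panel — a one-number summary of
how generally sensitive the sample is to *any* drug. MRP is the mirror
statistic for drugs. Supporting statistics quantify cross-study consistency:
within-study drug-drug correlation matrices, the correlation of those
matrices between studies over shared drugs ("correlation of correlations"),
a per-drug concordance that represents each drug by its correlation vector
to the other drugs, and a bootstrap that correlates GRD from random drug
subsets against full-panel GRD. Correlations use pairwise-complete
observations (screens have structured missingness after QC) and cells backed
by fewer than `min_pairs = 5` complete pairs are suppressed; GRD requires
`min_drugs = 10` observed drugs by default. Neither threshold is dictated by
the method; both are exposed.

When GRD serves as a covariate in a model of drug *d*, drug *d* is excluded
from the panel before averaging (leave-drug-out), so a drug's own responses
never leak into its covariate. This discipline is enforced structurally in
`cross_study_evaluate()`.

## The model

For studies $d = 1, \dots, D$ with standardized expression
$X^{(d)} \in \mathbb{R}^{N_d \times G}$ and standardized response
$y^{(d)}$:

$$
y^{(d)} \sim N(X^{(d)} \beta^{(d)}, \sigma^{(d)2} I), \qquad
\sigma^{(d)} \sim \mathrm{IG}(1, 1),
$$

with a shared sparse vector $\beta$ carrying a Finnish (regularized-global)
horseshoe prior:

$$
\beta_g \sim N(0, \lambda_g^2 \tau^2), \quad
\lambda_g \sim C^+(0, 1), \quad
\tau \sim C^+(0, \tau_0), \quad
\tau_0 = \frac{p_0}{G - p_0} \sum_d \frac{\sigma^{(d)}}{\sqrt{N_d}}.
$$

`p0` is the a-priori number of active genes, the single most consequential
tuning parameter; it defaults to 10 and is always exposed. The $\tau_0$
expression groups each study's noise with its own $\sqrt{N_d}$ (the
`per_source` option); a pooled variant dividing the summed noise by the
square root of the total sample count is selectable for comparison.

### How the studies are coupled

The per-study coefficients deviate from the shared vector with scale 0.5.
The package applies that scale **relative to each coefficient's own
shrinkage scale**:

$$\beta^{(d)}_g \sim N(\beta_g,\ (0.5\, \lambda_g \tau)^2).$$

This is a deliberate design choice, and the reasoning deserves space. The
naive alternative — a constant offset scale,
$\beta^{(d)} \sim N(\beta, 0.5^2 I)$, selectable here as
`source_coupling = "fixed"` — gives every study $G$ offset coefficients
with standard deviation 0.5 and **no per-gene shrinkage**. When $G$ exceeds
$N_d$ (always, in transcriptome-wide regression) that offset channel is an
essentially unregularized dense ridge that can interpolate each study's
response on its own: the shared vector then collapses to zero, the noise
scales are driven below their true values by overfitting, and the studies
decouple — the opposite of the model's purpose, under which coefficients
should be either large in all studies or small in all studies. We verified
this collapse with two independent samplers on data with known planted
signal. Scaling the offset by $\lambda_g \tau$ removes the degeneracy: a
gene whose shared coefficient is shrunk to zero also has its study offsets
pinned near zero, while a gene with a large shared coefficient is allowed
study-to-study variation of half its own scale.

One consequence worth knowing: with a *single* study, the split between the
shared coefficient and the offset is decided by the prior alone, so the
shared posterior mean is attenuated by the factor $1/(1 + 0.5^2) = 0.8$
relative to the study-level coefficient $\beta^{(d)}$. Prediction and
prioritization therefore use $\beta^{(d)}$ where a specific study is in
play; the shared vector is the cross-study summary.

Scale parameters written as `N(mean, scale)` are interpreted as standard
deviations, the convention of the major probabilistic-programming languages;
`interpret_scale_as = "variance"` re-reads them as variances for sensitivity
analysis. The plain horseshoe is the default; an optional regularized slab
(`slab_scale`) caps the scale of escaped coefficients and is off by default.

### Multi-task extension

For a set of drugs $\mathcal{I}$ screened in every study, the multi-task
model shares one profile per study across drugs and gives each drug a scalar
weight:

$$y^{(d,i)} \sim N(X^{(d)} \beta^{(d)} w^{(i)}, \sigma^{(d)2} I), \qquad
w^{(i)} \sim N(0.5, 0.5^2).$$

Samples missing a drug's response are dropped for that drug only. Responses
across drugs must arrive on one common scale — the weights carry exactly the
relative response magnitude, so per-drug standardization would destroy their
meaning (divide all drugs by a single constant instead). The
$\beta^{(d)} w^{(i)}$ product is invariant to reciprocal rescaling; the
weight prior centers the scale softly at 1-ish values rather than resolving
the non-identifiability exactly. With a single drug the weight is fixed at 1
and the model is exactly the single-response model.

## Inference

Sampling is by the package's own No-U-Turn Hamiltonian Monte Carlo sampler:
the joint log-posterior and gradient are evaluated in compiled code
(RcppArmadillo) on an unconstrained parameterization — non-centered
coefficients ($\beta = z \lambda \tau$ with $z \sim N(0,1)$, likewise the
offsets), log transforms with Jacobian corrections for $\lambda$, $\tau$,
$\sigma$ — and the tree building, dual-averaging step-size adaptation, and
diagonal mass-matrix estimation (one adaptation window in the first half of
warmup) run in R. The default budget honors a 2-chain, 500-warmup +
500-draw schedule; the acceptance-rate target defaults to 0.95, the
standard prescription for funnel-shaped horseshoe posteriors, which keeps
divergent transitions near 1% on the packaged simulations. Diagnostics
attached to every fit: split-$\hat R$ for each shared coefficient and for
$\tau$, an autocorrelation-based effective sample size, divergence counts,
and mean tree depth. A divergent fraction above 10% or a shared-coefficient
$\hat R$ above 1.1 triggers a warning, never a failure.

## Biomarker prioritization

Per study, posterior-mean coefficients are standardized across genes to
z-scores; Stouffer's method combines them, $z = \sum_d z^{(d)} / \sqrt{D}$,
with a two-sided normal p-value and a 0.01 selection threshold. Standardizing
empirically across genes (rather than using posterior standard errors) is a
choice: it asks "is this gene extremal relative to the other genes,
concordantly across studies?", which matches how cross-study coefficient
plots are read, and it is robust to the global shrinkage level. Genes strong
in one study and absent in the other cancel rather than average.

## Single-sample enrichment (GSVA-style)

The eight-gene monocytic signature (BCL3, CD14, LILRB1, LRP1, MAFB, PSAP,
SLC15A3, SLC7A7) is compressed to one score per sample by the gene-set
variation analysis recipe for continuous expression: per gene, a
Gaussian-kernel CDF estimate across samples (bandwidth = gene sd / 4); per
sample, genes ranked by that statistic and transformed to the symmetric
statistic `|rank - G/2|`; a weighted Kolmogorov-Smirnov-like walk down the
ranked list (weight exponent `tau = 1` on set genes, uniform down-steps on
the rest); the score is the maximum positive plus the maximum negative walk
deviation (signed sum). All three knobs — kernel, exponent, score
convention — are exposed, since published uses of the algorithm vary them.
The implementation is tested to 1e-10 against an independently coded
step-by-step oracle, and the score is invariant to per-gene affine
rescaling, which is what lets one signature travel across platforms. Genes
absent from a dataset are dropped with a warning, never imputed. A higher
monocytic score marks a more monocytic sample; against a BCL-2-inhibitor
AUC the expected correlation is therefore negative (resistance convention).

## Ridge baselines and the GRD covariate design

The baseline is closed-form ridge regression,
$\hat\beta = (X^\top X + \kappa I)^{-1} X^\top y$ via SVD, with the penalty
chosen on a 13-point log-spaced grid ($10^{-3}$ to $10^3$) by 10-fold inner
cross-validation. Cross-study evaluation trains on one study and tests on
the other under four covariate modes: expression alone; expression plus the
test study's own observed GRD; expression plus a GRD *predicted* from
expression by a ridge model trained on the training study; GRD alone. The
GRD column is standardized within study, appended to the gene matrix, and
penalized identically — penalizing it separately would add a tuning
dimension the comparison does not need. Model pairs are compared per drug by
a one-sided paired Wilcoxon signed-rank test; for 25 or fewer drugs the
exact null distribution is computed by convolution (valid under tied
differences, where the usual implementations fall back to an
approximation), zero differences dropped per convention.

## What the synthetic data emulate — and what they do not

The generators are pure functions of configuration and seed, and their
defaults are the package's study conditions:

* `simulate_multisource()`: equicorrelated gene blocks (size 10, correlation
  0.5) mimicking co-expressed modules, implemented by a shared latent factor
  per block; a sparse shared coefficient vector whose nonzero entries have
  equal magnitude `effect_sd` with random signs — the equal-magnitude
  planted-signal convention of the sparse-recovery literature, chosen so the
  benchmark measures the method's separation ability rather than the tail of
  a magnitude distribution; actives placed in distinct blocks, because two
  actives inside one equicorrelated block (particularly with opposite
  signs) plant a partially self-canceling signal that no method can
  attribute correctly; per-study coefficients perturbed with sd 0.1; noise
  either explicit or calibrated to an in-sample $R^2$ target.
* `simulate_grd_structure()`: `AUC = clamp01(mu + sample effect + drug
  effect + noise)` — the additive structure behind GRD; clamping reflects
  the normalized AUC scale; missing cells are injected as an exact count so
  the requested fraction is never exceeded by more than one cell.
* `simulate_dose_response()`: noisy log-logistic replicates with an optional
  end-point swap creating exactly the non-monotone artifact the QC flags.
* `simulate_signature_cohort()`: signature genes loading on a latent
  per-sample gradient, all other genes noise.

What they deliberately do **not** emulate: heavy-tailed or count-distributed
expression, batch and plate effects, missing-not-at-random screens,
drug-drug correlation beyond the additive sample effect, and the marginal
distributions of any real cohort. Passing tests on these fixtures
demonstrates the algorithms' correctness and the model's behavior under its
own assumptions — not transfer performance on real screens.

Problem sizes used by the packaged checks: the recovery simulation uses two
studies of 120 and 60 samples over 300 genes with 8 active, $R^2 = 0.5$;
the multi-task check uses 80 + 60 samples over 100 genes with weights
(1.0, 0.7, 0.4); the GRD simulation uses 100 samples by 60 drugs. These are
the conditions under which all reported quantities are computed.

## Numerical choices and degenerate inputs

Curve fitting treats optimizer runs that exhaust their iteration budget as
best-effort candidates (a model family that cannot represent the data still
needs its least-squares curve for the divergence flag) and reports
`converged = FALSE` only when every start fails; constant-response series
fit flat and are flagged `degenerate`. Zero-variance drug rows standardize
to zero with a warning. Correlation utilities error below three complete
pairs. Harmonization requires at least three responded samples per study
and is idempotent. All tie-breaks (modal concentration tuple, patient
sample selection) are lexicographic and documented. The exact signed-rank
computation doubles average ranks to stay in integer arithmetic.

## Known limitations

* At the packaged study conditions the weakest planted effects sit near the
  information-theoretic detection boundary: rankings derived from the
  posterior place most, but not always all, active genes ahead of 292
  nulls, and reference rankings (combined marginal correlations, ridge) do
  no better. Conclusions about ranking quality at the margin are
  seed-sensitive by nature.
* Held-out correlation in k-fold cross-validation is bounded by
  $\sqrt{R^2}$ and, at 30-40 test samples per fold, carries substantial
  fold-level sampling variance; the median fold is reported to match common
  practice, not because it is a stable estimator.
* The multi-task weight/profile scale is only softly identified by the
  weight prior.
* The sampler is single-threaded; chains run sequentially.
* No batch correction across studies is attempted: the hierarchy is the
  model's mechanism for cross-study variation, and inputs are standardized
  within study.
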