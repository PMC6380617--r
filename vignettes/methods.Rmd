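---
title: "Estimating and optimizing genomic-prediction accuracy for a given training set"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and optimizing genomic-prediction accuracy for a given training set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethacc)
```

## Two models, one prediction

Everything in this package revolves around the distinction between the model
that *makes* a genomic prediction and the model that *generates* the trait.

The predictor is RR-BLUP/GBLUP. With training phenotypes $y$ (length $T$)
and a column-centered training dosage matrix $X_c$ ($T \times M$), the model
$y = 1\mu + X_c\beta + \varepsilon$, $\beta \sim N(0, \sigma^2_\beta I)$,
$\varepsilon \sim N(0, \sigma^2_\varepsilon I)$ yields the prediction for a
test individual with centered genotype row $x_i$:

$$\hat u_i = x_i' X_c' H^{-1}(y - \bar y), \qquad
  H = X_c X_c' + \lambda I, \quad \lambda = \sigma^2_\varepsilon/\sigma^2_\beta.$$

All computations go through the $T\times T$ ridge matrix $H$, never through
Henderson's equations: $H$ is positive definite for any $\lambda > 0$, while
a VanRaden kinship built from fewer markers than individuals is singular.
Column-centering makes the genotypes orthogonal to the intercept, so
centering $y$ by its training mean is the exact GLS treatment of $\mu$; test
genotype columns are centered with the *training* column means, so a
prediction never depends on the composition of the test set.

The trait, however, is treated as coming from a *causal-QTL model*
$y = 1\mu + Q\theta + e$, $e \sim N(0, \sigma^2_e I)$, with a finite set of
$p$ causal loci $Q$ among the markers. The estimators below differ precisely
in which of the two models they trust.

## The accuracy estimators

`ts_accuracy()` is the empirical target: the Pearson correlation between
test phenotypes and their predictions. It is an oracle — it requires test
phenotypes — and serves as ground truth in evaluation settings.

`cd_accuracy()` / `pev_accuracy()` work entirely inside the GBLUP model.
There, the coefficient of determination of test individual $i$ is
$CD_i = (x_i' X_c' H^{-1} X_c x_i)/(x_i'x_i)$, the squared correlation
between $u_i$ and its BLUP, and $PEV_i = \mathrm{Var}(u_i)(1 - CD_i)$ with
$\mathrm{Var}(u_i) = \sigma^2_\beta x_i'x_i$. Because the target correlation
involves the *phenotype* rather than the genetic value, each term is scaled
by the square root of the individual heritability
$h_i^2 = \mathrm{Var}(u_i)/(\mathrm{Var}(u_i) + \sigma^2_\varepsilon)$:

$$\hat\rho_{CD} = \frac1{n_{test}}\sum_i \sqrt{h_i^2\, CD_i}.$$

A `sqrt_link = FALSE` switch gives the plain average of $h_i^2 CD_i$ for
users who want the unscaled reading. Since $1 - PEV_i/\mathrm{Var}(u_i) =
CD_i$ algebraically, the two estimators coincide to round-off; both are kept
because practitioners ask for them separately. Per-test values are clipped
into $[0,1]$ at round-off, a test individual identical to the training
centroid ($x_i = 0$) contributes zero with a warning, and the fixed-effect
uncertainty of $\mu$ is ignored (centering absorbs it; projection-matrix
refinements are out of scope and noted here deliberately).

`ethacc()` evaluates the theoretical accuracy of the ridge predictor under
the causal model:

$$\rho = \frac{\theta' A\, X_c' H^{-1} Q_c \theta}
  {\sqrt{\sigma^2_e\, \overline{\|H^{-1}X_c x_i\|^2} + w' V w}\;
   \sqrt{\sigma^2_g + \sigma^2_e}},$$

with $A$ the mean over test individuals of $q_i x_i'$, $w = X_c'H^{-1}Q_c\theta$,
$V$ the covariance of test genotype rows, and $\sigma^2_g$ the variance of
the test genetic values $q_i'\theta$. Two plug-in conventions matter:

* **Sample moments use divisor $n_{test}$** (a `divisor = "n-1"` switch is
  provided). These are direct sample estimates of population expectations.
* **Test-side moments are centered on test means.** The theory treats
  $E(q x')$, $\mathrm{Var}(x)$, $\sigma^2_g$ and the noise norm as moments of
  a zero-mean genotype distribution for a random test individual. When the
  test set is mean-shifted relative to the training population — the normal
  situation in structured panels — plugging in raw second moments about the
  training means injects a $\mu_g\,\mu_{\hat u}$ cross term into the
  numerator, the estimate stops being a correlation, and values above 1
  appear. Centering the test rows on their own column means restores the
  Cauchy–Schwarz structure ($|\rho| \le 1$), leaves the unshifted case
  numerically unchanged, and uses only test *genotypes*, which are always
  available. The ridge side ($H$, $w$) stays training-centered.

An empty causal model returns 0 with a warning, so optimization loops can
proceed. Degenerate inputs ($\sigma^2_g + \sigma^2_e = 0$) are errors.

`cdmean()` is the training-set design criterion: the mean CD of the
contrasts $c_i = e_i - \tfrac1N\mathbf 1$ between each test genetic value
and the mean of the combined (training + test) population. Because the
contrast is defined against the combined population, the design matrix is
centered on the *combined* set for this criterion only. Its variance
components are estimated once by REML on the entire candidate panel and held
fixed — that is what makes CDmean cheap inside an optimization loop, and it
follows the criterion's standard protocol.

## Variance components and the GWAS scan

`reml_variance_components()` profiles the restricted likelihood of the
RR-BLUP model down to one dimension: after a single eigendecomposition of
$X_cX_c'$, the REML criterion is maximized in $\log\lambda$ on $[-10, 10]$
(natural log) by Brent search with tolerance $10^{-8}$. Solutions on a bound
are flagged — the upper bound is the "no detectable marker variance" case
(e.g. a pure-noise trait) and the flag is the caller's cue to treat
$\sigma^2_\beta$ as effectively zero. The same engine, with an arbitrary
fixed-effect matrix and a VanRaden kinship, fits the polygenic null model of
the GWAS scan.

`gwas_scan()` tests each marker by a 1-df F test of its effect added to the
null model $y = 1\mu + X_{cof}\gamma + u + e$, $u \sim N(0, \sigma^2_u K)$,
with variance components held at the null fit within a step (the P3D
shortcut — the data are rotated and whitened once, then every marker test is
an OLS update). An F test rather than a Wald $\chi^2$ is used because the
panels of interest are small. Markers collinear with the cofactors get NaN
p-values with a warning. No structure covariates are included: kinship
absorbs structure.

`mlmm()` is the forward selection loop: scan, add the minimum-p marker as a
fixed cofactor (ties broken deterministically by lowest column index,
logged via the model's step record), re-estimate variance components, and
stop when the polygenic pseudo-heritability $\sigma^2_u/(\sigma^2_u +
\sigma^2_{res})$ falls below `h2_stop` or `max_qtls` is reached. "Close to
zero" is not a number anywhere, so the default is `h2_stop = 0.01`; the QTL
cap defaults to $\lfloor T/10\rfloor$ and in practice never binds. The
selected markers are then refit *jointly by OLS* (`fit_causal_ols()`),
including $\sigma^2_e = RSS/(T - p - 1)$ — mixed-model or penalized effect
estimates are deliberately not reused because shrinkage biases them, and
the theoretical formula needs unbiased $\theta$.

`penalized_locate()` wraps coordinate-descent LASSO/elastic-net paths
(glmnet) with seeded 10-fold CV and the two standard penalty rules (CV
minimum, and the one-standard-error rule, which is sparser). It returns
marker *locations* only; effects again go through OLS.

## Training-set optimization

`hill_climb()` is a plain exchange-move climber over fixed-size training
sets: per move, one member and one outside candidate are drawn uniformly,
swapped, and the swap is kept only on *strict* improvement (ties revert, so
trajectories are deterministic given the seed). There is no stopping rule —
exactly `n_moves` moves are always executed (default 5000; a constraint
rejection consumes its move) — and every evaluation is recorded in a trace
whose accepted subsequence is strictly increasing by construction.

The `ethacc_criterion()` re-runs REML, MLMM and the EthAcc formula on every
proposed training set. Two safeguards address the failure mode of
EthAcc-driven search, namely training sets whose overfit causal model makes
EthAcc large while the realized accuracy is poor:

* the phenotype must be standardized to unit variance up front
  (`standardize_phenotype()`), and
* a proposed set is **rejected** when the sample variance (divisor
  $n_{test}$) of its predicted test genetic values $Q_c\theta$ reaches the
  phenotypic variance — implemented as $\ge 1 - 10^{-12}$, i.e. "strictly
  less than 1" up to round-off. Inflated sets are typically driven by rare
  alleles whose few carriers earn enormous OLS effects; their signature is
  exactly this variance blow-up.

Inside the criterion, MLMM runs with reduced defaults (`max_qtls = 10`) to
bound per-move cost; this is a documented knob, not a hidden constant. The
`ts_oracle_criterion()` (maximize realized accuracy using test phenotypes)
exists to construct the "optimal start" of criterion comparisons and is
flagged as an oracle.

## What the generator emulates — and what it does not

`simulate_genotypes()` draws ancestral allele frequencies Uniform(0.1, 0.9)
and cluster frequencies from the Balding–Nichols Beta distribution with
divergence `fst`, then dosages Binomial(2, p) — or $2\times$Bernoulli for
inbred (doubled-haploid) panels, the default, since the motivating material
is inbred crop lines coded 0/2. Local LD is induced by Markov copying:
within blocks of `ld_block` markers, a sample's dosage is copied from the
previous marker with probability 0.7. Each cluster draws its own *phase
orientation* per marker (with probability 1/2 the copy is the flipped dosage
$2 - x$), so LD diverges between clusters in sign, not just magnitude. This
choice is essential: with same-phase copying, individuals from another
cluster are merely uninformative for GBLUP and a bigger training set is
never worse, whereas real structured panels show divergent LD phase between
subpopulations — the very phenomenon that makes "bigger not always better"
and that separates EthAcc from CD. `simulate_phenotype()` samples QTL
positions among polymorphic markers, standard-normal effects, residual
variance tuned to the target $h^2$, an optional cluster mean shift for
structure-confounded traits, and returns the full truth for oracle tests.

The generator does **not** emulate a recombination map, pedigree structure,
multi-allelic markers, genotyping error or missingness. Consequently,
passing tests say nothing about those aspects of real data; what they do
establish is the statistical behavior of the estimators under structure,
linkage and sparse architectures. One study condition deserves emphasis:
the "within-cluster training beats combined training" phenomenon is
evaluated with the causal columns *held out* of the prediction panel
(tagging-only prediction). That mirrors array data, where causal variants
are essentially never genotyped; when the causal variants themselves are
markers, effect estimates transfer across clusters and a larger training
set always wins.

## Numerical choices and degenerate inputs

* REML: eigenvalues are floored at 0; the search interval $[-10,10]$ in
  $\log\lambda$ spans ridge ratios from $4.5\times10^{-5}$ to $2.2\times10^4$;
  bound solutions are flagged, not errors.
* Dosage coding is never assumed: centering and kinship are covariant under
  affine recoding, and MAF is computed on the observed 0–2 scale.
* Markers constant within a training subset are dropped from the centered
  design with a warning (their effect is unidentifiable there); monomorphic
  markers are always removed at load time, and the default MAF filter is
  0.05.
* Collinear QTL columns are dropped by pivoted QR in the OLS refit, with a
  warning; a causal model that is rank-deficient against the intercept is an
  error.
* Contrast CDs with zero genetic variance in the denominator contribute 0
  with a warning; per-test CDs are clipped into $[0,1]$ at round-off.
* All simulation, CV-fold and optimizer randomness is seeded explicitly;
  functions that use the RNG save and restore the caller's RNG state.

## Problem sizes used by the test suite

The shipped tests run on one CPU in a few minutes: identity checks on panels
up to $T = 200$, $M = 500$; the theoretical-accuracy calibration at $T =
250$, $n_{test} = 50$, $M = 500$, 10 QTLs, $h^2 = 0.5$ with 500 Monte-Carlo
noise draws; REML recovery at $T = 500$ over 50 seeds per heritability
level; GWAS power/null at $T = 200$, $M = 200$ over 50 seeds; structured
two-cluster comparisons on 300–450-line panels over 20–30 replicates; and
optimization comparisons on 100-line panels with 80-move climbs from
200-move oracle starts. These sizes are the package's choice of a desk-scale
study; the estimators themselves have no size limits beyond memory for the
$T\times T$ and $N\times N$ matrices.

## Known limitations

* EthAcc's precision degrades sharply when MLMM has little power (small
  training sets, weak heritability): selected proxies suffer winner's-curse
  inflation and EthAcc can overestimate accuracy by large margins even with
  the variance constraint — which is why optimal-start optimization works
  well while random-start optimization remains hard.
* Hill climbing has no restarts or tempering built in; finding the global
  EthAcc maximum is a hard combinatorial problem and 5000 moves explore only
  a neighborhood. Restarting from several seeds is the practical remedy.
* Single-trait, additive models only: no dominance or epistatic kinships,
  no multi-trait selection indices, no pedigree kinship.
* The CD/PEV estimators ignore fixed-effect uncertainty, and the standard
  errors of accuracy estimates across overlapping test-set draws are not
  corrected for dependence.
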