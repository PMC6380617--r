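# ethacc

Accuracy estimation and training-set optimization for genomic prediction.

## The problem

Genomic selection trains a whole-genome regression (GBLUP / RR-BLUP) on a
*training set* of genotyped and phenotyped individuals and predicts the
genetic values of genotyped-only *test* individuals. The value of the whole
exercise hinges on the prediction accuracy — the Pearson correlation between
the test phenotypes and their predicted genetic values — yet that accuracy is
exactly what cannot be measured before the test individuals are phenotyped.
Breeders need it *given a candidate training set*, both to decide whether
genomic selection is worth deploying and to choose which past material to use
(or to phenotype) as training data.

The classical answers come from inside the mixed model itself: the
coefficient of determination (CD) of each test genetic value, or equivalently
its prediction error variance (PEV, with CD = 1 − PEV/Var(u)). Both assume
the trait really is generated by the GBLUP model — every marker a causal
locus, effects iid Gaussian — and in structured panels they systematically
overestimate the achievable accuracy.

**EthAcc** (Estimated THeoretical ACCuracy) instead separates the two models
involved: an *instrumental* ridge-regression model that makes the prediction,
and a *causal* fixed-effect model `y = 1μ + Qθ + e` with a finite set of QTLs
that generates the phenotype. For a known causal model the accuracy of the
ridge predictor for a random test individual has a closed form:

    ρ = θ'E(q x') X' H⁻¹ Q θ
        ─────────────────────────────────────────────────────────────
        √( σ²ₑ E‖H⁻¹ X x‖² + w' Var(x) w ) · √( σ²_g + σ²ₑ )

with `H = X X' + (σ²_ε/σ²_β) I` the ridge matrix of the training design
(column-centered), `w = X' H⁻¹ Q θ`, `σ²_g = Var(q'θ)`, and expectations
taken over the test individual's genotypes (estimated by sample means over
the test set). EthAcc plugs in a causal model *estimated on the training
set*: QTL positions from multilocus mixed-model (MLMM) forward-selection
GWAS, effects and σ²ₑ re-estimated jointly by OLS (penalized-regression
locators, LASSO/elastic net with CV-chosen penalties, are provided as
alternates). Because the causal model is re-estimated for every training
set, EthAcc can drive hill-climbing training-set optimization, where it is
compared against the CDmean criterion (mean CD of contrasts between each
test genetic value and the combined-population mean).

The package implements the full chain as plain S3 R:

- `read_dosage()` / `read_phenotype()` — dosage-CSV and PLINK-`--recode A`
  style input, MAF filtering;
- `rrblup()` with `print/summary/coef/predict/residuals` methods;
  `reml_variance_components()` (EMMA-style one-dimensional REML),
  `ridge_matrix()`, `gblup_predict()`;
- `ts_accuracy()`, `cd_accuracy()`, `pev_accuracy()`, `ethacc()`,
  `cdmean()` — the accuracy estimators;
- `gwas_scan()`, `mlmm()`, `penalized_locate()`, `fit_causal_ols()` — the
  causal-QTL machinery;
- `hill_climb()` with `ethacc_criterion()` (including the predicted
  genetic-variance constraint), `cdmean_criterion()`,
  `ts_oracle_criterion()`;
- `simulate_genotypes()` / `simulate_phenotype()` — a seeded
  Balding–Nichols generator of structured inbred panels with
  cluster-divergent local LD and sparse QTL architectures;
- `run_experiment()` / `write_report()` — the repeated test-set-draw
  harness; a CLI wrapper lives at `inst/cli/ethacc.R`
  (`simulate | estimate | gwas | optimize | experiment`).

## Worked example

Simulate a two-cluster inbred panel (300 lines × 300 markers, 8 QTLs,
h² = 0.6), fit RR-BLUP on 240 lines and estimate the accuracy for the other
60 three ways:

```r
library(ethacc)
cfg <- sim_config(n_samples = 300, n_markers = 300, n_clusters = 2,
                  fst = 0.3, ld_block = 5, n_qtl = 8, h2 = 0.6, seed = 42)
panel <- simulate_genotypes(cfg)
sim <- simulate_phenotype(panel, n_qtl = 8, h2 = 0.6, seed = 43)
y <- sim$phenotype

split <- train_test_split(train = 1:240, test = 241:300, n = 300)
fit <- rrblup(y, panel, split)
summary(fit)
#> RR-BLUP model: 240 training / 60 test individuals, 300 markers
#> variance_components: sigma2_beta = 0.03762, sigma2_eps = 5.425, lambda = 144.2
#>   genomic variance (train): 9.715, pseudo-h2: 0.642

ts_accuracy(predict(fit), y[241:300])   # oracle: needs test phenotypes
#> accuracy estimate (TS): 0.4035
cd_accuracy(fit$design, fit$vc)         # mixed-model CD estimate
#> accuracy estimate (CD): 0.5988

model <- mlmm(y[1:240], panel$dosages[1:240, ], max_qtls = 10)
model
#> causal_model (mlmm): 9 QTL(s), sigma2_e = 5.163
#>   indices: 261, 216, 296, 149, 7, 196, 44, 76, 231
ethacc(panel, split, model, fit$vc)
#> accuracy estimate (EthAcc): 0.4379
```

The realized accuracy is 0.40. The CD estimate (0.60) overestimates it —
the structured panel violates the "every marker a QTL" assumption — while
EthAcc (0.44), built on the nine MLMM-discovered QTLs (seven of the eight
simulated ones plus two proxies), lands close to the truth. Training-set
optimization from this point is one call:

```r
opt <- hill_climb(cdmean_criterion(panel, 241:300, fit$vc),
                  start = sort(sample(1:240, 50)), candidates = 1:240,
                  n_moves = 5000, seed = 1)
```

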