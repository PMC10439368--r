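# anuromorph

Phylogenetic ecomorphometrics of anuran skeletal proportions.

Frogs span walkers, hoppers, burrowers, terrestrial and arboreal jumpers
and dedicated swimmers, and their skeleton tracks that functional
diversity: sacral expansion, limb-segment proportions and limb robustness
differ systematically among locomotor modes, habitats and clades.
`anuromorph` provides the complete comparative toolchain for analysing a
table of linear skeletal measurements (cm) across species on a phylogeny:

- **Size correction** — Mosimann shape variables: each specimen's
  measurements divided by their geometric mean,
  `size_i = (∏_j x_ij)^(1/p)`, `shape_ij = x_ij / size_i`, used
  log-transformed so each row sums to zero. Structural totals (snout-vent,
  hindlimb, forelimb lengths) and the ten classical diagnostic ratios
  (HL/FL, ESD/HL, tib/fem, ...) are derived from the raw columns.
- **Ordination** — phylogenetic PCA under Brownian motion
  (`a = (1'C⁻¹1)⁻¹1'C⁻¹X`, `R = (X−1a)'C⁻¹(X−1a)/(n−1)`, eigenanalysis of
  `R`), and shape PCA in isometry-free shape space with PCA **ratio
  spectra** and allometry spectra, with 68% bootstrap intervals (999
  species resamples by default).
- **Inference** — one-way PERMANOVA with pairwise contrasts (Anderson's
  pseudo-F, free permutation of rows), and PGLS with maximum-likelihood
  Pagel's λ (profile likelihood over a 0.01 grid up to the
  positive-definiteness bound, which may exceed 1 on
  substitutions-per-site trees), ranked across candidate designs by AIC.
- **Discriminant prediction** — Gaussian LDA and phylogenetic flexible
  discriminant analysis (pFDA): predictors and class indicators whitened
  by the inverse Cholesky factor of `C(λ)` with λ chosen by a whitened
  multivariate-regression likelihood, optimal-scoring discriminant
  directions, confusion matrices, case-wise posterior reports with
  secondary-label checks, and held-out tip prediction via whitening
  conditioned on the training tips.
- **Synthetic data** — pure-birth trees, Mk-evolved locomotor regimes,
  matrix-normal trait evolution with tunable λ, regime mean shifts, a
  shared Brownian log-size factor and measurement noise, with full ground
  truth for recovery studies.
- **Pipeline** — `run_pipeline()` drives the whole analysis from a YAML
  config and writes a deterministic, checksummed report bundle.

## Worked example

```r
library(anuromorph)

ds  <- simulate_traits(sim_config(n_tips = 164, seed = 42))
tab <- ds$measurements
vars <- setdiff(attr(tab, "variable_set"), "iliac_angle")

sh  <- mosimann_shape(tab, vars)            # log-shape, rows sum to 0
cov <- brownian_covariance(ds$tree)
ppca(shape_matrix(sh)[cov$tip_order, ], cov)
#> pPCA of 16 variables, 164 species
#>  axis eigenvalue percent
#>   PC1     1.2020    33.5
#>   PC2     0.7573    21.1
#>   PC3     0.4609    12.8
#>   PC4     0.2351     6.5
#>   PC5     0.2318     6.5

permanova(shape_matrix(sh), tab$locomotor_mode, n_perm = 999, seed = 1)
#> PERMANOVA (999 permutations)
#> Groups: AJ (30), AQ (23), BWH (52), TJ (43), WH (16)
#> pseudo-F = 32.59, R2 = 0.4505, p = 0.001

X   <- shape_coordinates(shape_matrix(sh))  # full-rank shape basis
fit <- lda_fit(X, tab$locomotor_mode)
confusion(as.character(fit$labels), as.character(predict(fit)$class))
#> Overall accuracy: 93.3% (153 / 164)
```

The pPCA table gives each axis's share of the evolutionary
(phylogenetically weighted) trait covariance — here a third of shape
variance loads on PC1, the axis dominated by sacral and limb-robustness
contrasts built into the generator. The PERMANOVA says locomotor groups
occupy significantly distinct regions of shape space (45% of squared
distance between groups), and the confusion matrix reports resubstitution
accuracy of the locomotor classifier per class (rows true, columns
predicted).

The full pipeline from files on disk:

```r
make_dataset(sim_config(seed = 1), "demo")   # measurements.csv, tree.nwk, truth.json
cfg <- read_config("config.yaml")            # paths + n_perm, n_boot, seed, ...
bundle <- run_pipeline(cfg)                  # writes the report bundle
```

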