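---
title: "Methods: size correction, phylogenetic ordination and discriminant prediction of anuran skeletal ecomorphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size correction, phylogenetic ordination and discriminant prediction of anuran skeletal ecomorphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anuromorph)
```

`anuromorph` analyses linear skeletal measurements of frog species on a
phylogeny: it removes isometric size, ordinates shape, tests group
structure, regresses shape scores on ecological predictors with
phylogenetic error, and asks how well the skeleton predicts locomotor
mode, habitat and clade. This vignette records the models, the tunable
parameters, the numerical choices, and the places where the design was
genuinely open.

## Measurement data and size correction

The measurement table holds 16 length measurements in centimetres (skull,
vertebral column, pelvis, sacral width, expansion of the sacral
diapophyses ESD, ilium, urostyle, femur and femur width, tibiofibula,
calcaneus, foot, humerus and humerus width, radioulna, hand), the iliac
angle θ in degrees, and three categorical labels: locomotor mode (WH
walker-hopper, BWH burrower-walker-hopper, TJ terrestrial jumper, AJ
arboreal jumper, AQ aquatic swimmer), habitat (terrestrial, arboreal,
riparian, aquatic) and clade (basal, Hyloidea, Ranoidea, plus a small
'Neobatrachia' group used only as held-out cases). A *structural* set of
nine variables replaces individual segments by totals: SVL = skull +
vertebrae (pelvis optional), HL = femur + tibiofibula + calcaneus + foot,
FL = humerus + radioulna + hand. The exact axial composition of SVL is
not uniquely fixed by the published variable lists, so the composition
map is configuration (`default_composition()`), logged with every
derived table, rather than hard-coded.

Size correction uses Mosimann shape variables: each specimen's
measurements are divided by their geometric mean, so shape is
dimensionless and depends only on the specimen itself. We compute
log-shape as log-then-row-centre, which is algebraically identical to
divide-then-log but avoids under/overflow on products of many small
numbers; both representations are exposed. Two constraints follow by
construction and are asserted in the tests: each log-shape row sums to
zero, and each row of Mosimann ratios multiplies to one (1e-9 relative
tolerance). The iliac angle is never entered into a geometric mean — it
is not a length, and mixing units would make the geometric mean
meaningless — so shape analyses of the "16-variable" set actually use the
15 length columns, with θ carried along untransformed for descriptive
tables. Diagnostic ratios (HL/FL, HL/SVL, ESD/HL, fem/HL, tib/HL,
calc/HL, foot/HL, tib/fem, fem_w/fem, hum_w/hum) are always computed per
specimen and then averaged — never as ratios of group means.

Because log-shape rows sum to zero, the p shape columns span a p−1
dimensional subspace and their pooled covariance is singular.
Distance-based methods (PERMANOVA) and eigen-methods (pPCA, SPCA) are
unaffected, but discriminant analysis needs a full-rank design;
`shape_coordinates()` therefore projects shape onto a fixed orthonormal
Helmert basis of the isometry-free subspace. The projection preserves all
pairwise Euclidean distances, and classifiers are affine-invariant, so no
result depends on the particular basis.

## Phylogeny and the Brownian covariance

Trees are read and written as Newick through `ape` and need not be
ultrametric; the reference trees in this field carry branch lengths in
substitutions per site. The Brownian covariance `C` has `C[i, j]` equal
to the shared root-to-MRCA path length, computed from node depths and
MRCA lookups and cross-checked in the tests against an independent
path-sum oracle. Pagel's λ multiplies the off-diagonal entries only.
The admissible upper bound `lambda_max()` is found by binary search for
the largest λ keeping `C(λ)` positive definite (capped at 2): for
ultrametric trees it sits at or just above 1, for non-ultrametric trees
it can be considerably larger. The bound is deliberately not clamped at
1, so ML estimates above 1 — signal stronger near the root than the tips
— remain expressible whenever the covariance allows them.

All solves use Cholesky factorisations, never explicit inverses. Zero
length terminal branches duplicate rows of `C`; when a factorisation
fails, a diagonal jitter of 1e-8 × tree height is added once, with a
message, so jittered runs are auditable. Ancestral states of continuous
scores are the Brownian GLS estimates: the root is the phylogenetic mean
`(1'C⁻¹1)⁻¹1'C⁻¹x` and each internal node the conditional expectation
given the tips; a grid-search likelihood oracle on a three-tip tree pins
the implementation down in the tests.

## Ordination

**pPCA.** The phylogenetic mean `a` and evolutionary covariance
`R = (X−1a)' C⁻¹ (X−1a)/(n−1)` feed an eigen-decomposition; scores are
`(X−1a)V`. Covariance mode is the default (the correlation mode is one
switch away) because shape variables share a scale. Percent variance per
axis is taken from the eigenvalues of `R` — conventions based on score
variances differ, and the choice is documented here because it changes
the printed percentages. With `C = I` the whole construction collapses
to ordinary covariance PCA, which is asserted at 1e-8.

**SPCA.** Shape PCA row-centres log-measurements (projection orthogonal
to the equal-loading isometry direction — identical to log-Mosimann
shape) and then runs ordinary covariance PCA. At most p−1 eigenvalues are
nonzero; the trace identity (eigenvalue sum = total shape variance) is
asserted. A dataset with no shape variance at all (pure isometric growth)
yields all-zero eigenvalues and undefined (NA) percentages rather than an
error.

**Ratio spectra.** One axis's loadings, ordered, form the PCA ratio
spectrum: the gap between two variables approximates how much of the
component's variance their log-ratio explains, and the two end variables
form the dominant ratio. Uncertainty comes from resampling species (rows,
never variables) with replacement, 999 replicates and a central 68%
percentile interval by default, matching the conventions of published
spectra. Three numerical choices matter and are fixed: eigenvector signs
are set so the largest-magnitude loading is positive; each bootstrap
replicate's axis is matched to the point estimate by maximal |dot
product| (axis swapping is counted and reported, Procrustes rotation is
deliberately not applied); and the percentile interval is widened, in the
rare small-sample cases where axis mixing pushes a quantile past the
point estimate, so every bar brackets its point. Degenerate resamples are
dropped and redrawn up to 10 × n_boot attempts. The allometry spectrum
replaces loadings by the per-variable slope of log-shape on log size (the
row mean); "shape uncorrelated with size" is operationalised as every
pairwise slope difference having an interval covering zero.

## PERMANOVA and PGLS

PERMANOVA uses Euclidean distance on log-shape — the natural metric for
these variables and the default of the standard implementations; nothing
in the published analysis names a different one. The pseudo-F comes from
the Gower-centred partition of squared distances, permutes row labels
freely (no strata), and reports `p = (1 + #{F* ≥ F}) / (1 + n_perm)` with
999 permutations by default. Pairwise contrasts rerun the test on each
group pair with Bonferroni adjustment by default (Holm and BH available);
the adjustment was likewise not stated in the source analyses, so it is
explicit configuration. A univariate two-group call reproduces the
classical ANOVA F exactly, which the acceptance tests assert.

PGLS fits GLS with error covariance `C(λ)`, profiling λ on a 0.01 grid
over `[0, lambda_max]` plus local refinement. The log-likelihood is the
exact Gaussian one (ML σ²); coefficient standard errors use the unbiased
`RSS/(n−k)`, so the λ = 0 fit matches `lm` output column for column.
`AIC = −2logLik + 2(k+2)` counts the coefficients plus σ² and λ.
`select_model()` fits candidate designs with ML λ and ranks by AIC,
breaking exact ties by declaration order. Published coefficient tables
for these analyses print a single coefficient per factor, implying
integer-coded levels; `code_levels()` reproduces that coding with the
level order as explicit configuration (the order is a reporting choice,
not an inference), and conventional dummy coding is available through the
ordinary formula interface.

## Discriminant analysis

LDA is the classical Gaussian shared-covariance classifier: priors
default to observed class frequencies, discriminant directions come from
the symmetric eigenproblem in the pooled-covariance-whitened space, and
proportion-of-trace is the normalised eigenvalue share. The
implementation is cross-checked against the standard reference
implementation in the tests (predictions, posteriors and trace shares).

pFDA whitens both the predictors and the class-indicator matrix by the
inverse Cholesky factor of `C(λ)`, residualises against the whitened
intercept (the phylogenetic mean), and obtains discriminant directions by
optimal scoring — canonical correlations between the two whitened blocks.
Classification happens in the discriminant-variate space with the same
Gaussian rule. At λ = 0 on a unit-height ultrametric tree the whitening
is the identity and the model coincides with LDA exactly (asserted on
confusion matrices and posteriors). Held-out tips — the 'Neobatrachia'
route in the pipeline — are whitened by factorising the covariance over
training plus held-out tips with the training block first, so forward
substitution conditions each held-out row on the training tips before the
trained directions and classification rule are applied.

The λ used by pFDA ("optimal λ") maximises, over the same grid, the
exact Gaussian log-likelihood of the whitened multivariate regression of
traits on class indicators, including the `−p/2 log|C(λ)|` Jacobian term;
without that term the criterion is not a likelihood and does not recover
the generating λ in simulation. The full grid trace is stored in the
fitted object so any alternative criterion can be audited against it.
The published description of this step is verbal ("maximises the
correlation"), so the likelihood operationalisation is a documented
design decision, not an inference about anyone's code.

One behaviour of pFDA deserves emphasis because it surprises at first
sight: whitened rows are phylogenetic innovations, so a species whose
ancestor shares its class contributes almost no class signal after
whitening. When classes are phylogenetically conserved, pFDA
resubstitution accuracy saturates well below LDA's regardless of how
large the class mean shifts are; it approaches 100% only when class
membership churns quickly on the tree. This is the designed behaviour of
the method — it discounts exactly the component of class separation that
phylogeny alone would produce — and it is why the package's recovery
tests drive the regime transition rate up when they need high pFDA
accuracy. Tie-breaks in the posterior argmax go to the first class in
declared level order.

## The synthetic-data generator

`simulate_traits()` draws the study conditions the analyses assume: a
pure-birth tree scaled to unit height (164 tips by default), locomotor
regimes evolved by a symmetric Mk process (rate q = 1.5 per unit height —
slow enough for realistic phylogenetic clustering, fast enough that all
five regimes appear; draws are repeated until each has at least 2 tips,
since smaller classes cannot enter a pooled covariance), a matrix-normal
log-shape signal with row covariance `C(λ)` (λ = 1 by default) and
exchangeable trait covariance `Σ = 0.04·(0.7 I + 0.3 J)` (per-trait
Brownian sd 0.2 over the tree height, mildly correlated as skeletal
measurements are), regime mean shifts δ on the log scale (pattern:
burrowers and swimmers gain wide sacra and robust limb shafts, jumpers
long distal hindlimb segments; scale 0.3, i.e. up to ≈35% differences,
comparable to the between-mode contrasts in published descriptive
tables), a Brownian log-size factor (rate 0.25, offset 0.3 log-cm) added
to every trait, and iid log-scale measurement noise (sd 0.05, ≈5%
measurement error). Habitat follows a deterministic locomotor-to-habitat
map with a 10% confusion rate; clades are taken from the tree's own
structure (the two large disjoint clades become Hyloidea and Ranoidea)
with 10 tips relabelled 'Neobatrachia' for hold-out prediction. The iliac
angle is drawn around regime-specific means near 9° and is independent
of the trait covariance.

The generator reproduces the *structure* the methods assume — Brownian
shape evolution with tunable signal, clustered discrete regimes, a shared
latent size factor, multiplicative noise — and records full ground truth
for recovery tests. It does not attempt to mimic real frog measurement
distributions (no allometric curvature, no heteroscedastic measurement
error, no missing data, no intraspecific sampling), so green tests
demonstrate that the machinery recovers known structure under its own
assumptions, not that those assumptions hold for any particular empirical
dataset.

## Pipeline, determinism and problem sizes

`run_pipeline()` runs read → validate → prune → derive → size-correct →
pPCA/SPCA/spectra → PERMANOVA (three groupings, pairwise) → PGLS model
selection on PC1/PC2 → LDA/pFDA (three groupings, 'Neobatrachia' held
out) → case-wise reports → ancestral states, writing delimited-text
artifacts and a JSON manifest with a config hash and per-file checksums.
Stage s seeds its RNG with `1000·seed + s`, so a stage rerun reproduces
the full-pipeline result, and no artifact contains a timestamp — the
bundle is byte-identical under identical config and seed, which the
acceptance tests assert. Any stage error aborts with the stage name. The
pipeline is driven from R (or the YAML config file); the package's
functions and the acceptance script are its interfaces.

The statistical test-bench sizes are chosen to estimate each property
precisely while keeping the suite quick on a laptop: 500 null simulations
at n = 60 with 199 permutations for the PERMANOVA type-I error, 100
replicates on 128-tip trees for PGLS λ recovery (per truth at λ = 1 and
λ = 0), 100-species datasets for the discriminant recovery ladder, and
999 bootstrap replicates wherever spectra are reported (reduced in unit
tests that only exercise plumbing).

## Known limitations

- PERMANOVA is one-way only; no dispersion (PERMDISP) companion test, so
  significant results can reflect spread as well as location differences.
- PGLS covers main-effect designs with a single λ; no interactions
  beyond those configured, no OU or rate-shift error models.
- pFDA uses a linear optimal-scoring basis only, and resubstitution is
  the headline metric to match the published tables; cross-validation is
  available but reported separately.
- The reproduction of the published per-species results requires the
  study's supplementary measurement table and pruned reference tree,
  which are not redistributed here; the corresponding check runs
  whenever those files are placed under `inst/extdata/`.
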