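---
title: "Predicting lanthanide-ligand stability constants with lanbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lanthanide-ligand stability constants with lanbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lanbind)
```

## The modeling problem

For the 1:1 complexation equilibrium M + L ⇌ ML, the stability constant
K1 = [ML]/([M][L]) measures how strongly a ligand L binds a metal cation M.
Its decadic logarithm, logK1, is the quantity tabulated in curated
compilations of experimental measurements and the regression target of this
package. Binding strength depends on the ligand structure, the cation, the
background medium, the temperature and the ionic strength, so a useful
predictive model must see all five.

`lanbind` casts this as a QSPR (quantitative structure-property
relationship) regression. Every measurement becomes a fixed 102-dimensional
feature vector:

* **83 molecular descriptors** of the ligand (topological/compositional;
  see below),
* **14 properties of the metal** (atomic number, electrons beyond the
  xenon core, first three ionization energies, electron affinity, atomic /
  covalent / ionic radii, Pauling electronegativity, melting and boiling
  point, density, standard entropy of the solid element),
* **3 properties of the medium** (density, molar mass and melting point of
  a representative compound; 1-octanol stands in for "alcohol" and
  methylammonium chloride for tetraalkylammonium halides),
* **temperature (K) and ionic strength (mol/L)**.

Fifteen cations are supported: the trivalent series Ce³⁺–Lu³⁺ plus Ce⁴⁺.
Metal properties are element-level values from standard reference tables;
ionic radii are Shannon effective radii for 6-coordination, and "standard
entropy" is S°(298 K) of the solid element — both conventions are recorded
in the shipped `metals.tsv`. No descriptor of the M–L complex itself
(denticity, coordination geometry) is used, which is what makes the model
applicable to arbitrary screening libraries where the complex structure is
unknown.

## The descriptor block

Structures enter as SDF/MOL files or SMILES and are parsed, laid out and
hydrogenated through OpenBabel (via ChemmineR/ChemmineOB). The descriptor
engine computes a candidate set of ~135 descriptors: element and bond
counts, hydrogen-bond donors/acceptors, ring statistics, rotatable bonds,
the Kier–Hall connectivity (`Chi0`–`Chi4v`/`Chi4n`) and shape
(`Kappa1`–`Kappa3`) indices, Balaban's J, Wiener and Zagreb indices,
Morgan-environment fingerprint densities (`FpDensityMorgan1`–`3`), PEOE
partial-charge extrema, van der Waals surface-area partitions binned by
PEOE charge (`PEOE_VSA1`–`14`) and by atomic refractivity
(`SMR_VSA1`–`10`), `LabuteASA`, OpenBabel's logP/molar-refractivity/TPSA,
and a block of `fr_*` functional-group counts.

Implementation notes worth knowing:

* **PEOE charges** are computed by the classic Gasteiger–Marsili partial
  equalization of orbital electronegativities (six damped rounds). The
  implementation reproduces OpenBabel's `gasteiger` charges to ~5×10⁻⁵ on
  C/H/O/Cl chemistry, which the test suite uses as an independent oracle;
  nitrogen planarity typing differs slightly between toolkits.
* **VSA partitions** use a spherical-cap approximation of per-atom van der
  Waals surface area (Bondi radii, covalent-radius bond lengths shortened
  10% per extra bond order), with hydrogen areas folded into the bonded
  heavy atom. Refractivity contributions are element-level atomic
  refractions. The bins follow the conventional PEOE/SMR breakpoints (e.g.
  `PEOE_VSA2` sums atoms with charge in [−0.30, −0.25)).
* All shipped descriptors are **coordinate-independent**, so values are
  identical for any embedding of the same connection table. The 3D
  pipeline (`embed_and_refine()`) exists for users who need refined
  geometries: it builds a deterministic rule-based 2D layout, adds a
  seeded out-of-plane perturbation, and relaxes by steepest descent under
  UFF. One conformer per molecule; a fixed seed reproduces coordinates
  bit-exactly.

### Pruning and the frozen 83-name layout

`prune_descriptor_set()` screens the candidate matrix by three rules:
fragment-count descriptors (`fr_` prefix) are dropped as redundant with the
compositional block; descriptors null/zero for more than 95% of molecules
(configurable) are dropped; and of exactly identical columns only the
alphabetically first survives. The survivors are frozen to a JSON config so
feature columns are bit-stable across runs — the layout is *loaded*, never
recomputed implicitly. The shipped default was generated from a 150-ligand
synthetic reference set; when more than 83 descriptors survive, the
lowest-variance extras are dropped to preserve the canonical 102-column
layout. Users fitting their own corpus can regenerate and freeze their own
layout with `freeze_descriptor_config()`.

Molecules whose featurization fails are skipped with a logged warning and
an entry in a rejects table — never zero-filled, because imputed zeros
would poison the applicability-domain bounding box.

## Preprocessing

Six scalers are provided (`minmax`, `standard`, `maxabs`, `robust`,
`uniform_quantile`, `normal_quantile`), always fitted on training columns
only. The quantile transforms use a 1,000-point empirical quantile grid
with linear interpolation; values beyond the training range clip to the
boundary quantile, and the normal variant composes the uniform transform
with the standard normal inverse CDF (uniform values clipped to
[10⁻⁷, 1−10⁻⁷]). Constant columns under a scale-by-zero method map to 0
with a logged message. Scalers serialize to JSON with 17-significant-digit
doubles, which round-trip bit-exactly — important because the tie structure
of a quantile grid changes results if perturbed in the last bit.

`pca_variance()` standardizes internally before the eigendecomposition
(a documented choice; diagnostics on unscaled data would be dominated by
the largest-magnitude descriptors). `l1_select()` wraps an L1-penalized
linear fit (glmnet); with no explicit strength it takes the
cross-validated λ and keeps features whose |coefficient| is at least the
median nonzero magnitude.

## The regressor zoo

Ten variants with tuned default hyperparameters and their paired scaler:

| algorithm | defaults | scaler |
|---|---|---|
| random_forest | 60 trees, min leaf 2 | normal_quantile |
| knn | k = 2, Minkowski p = 2 | robust |
| svm_linear | C = 48 | minmax |
| svm_rbf | C = 450, γ = 0.073 | uniform_quantile |
| krr_linear | α = 0.25 | robust |
| krr_poly | α = 0.030, γ = 0.082, degree 3 | uniform_quantile |
| krr_rbf | α = 0.002, γ = 0.006 | robust |
| krr_laplacian | α = 0.001, γ = 0.012 | uniform_quantile |
| mlp | layers 700/800, ReLU, Adam | normal_quantile |
| adaboost | 20 estimators, depth 40 | normal_quantile |

Kernel ridge regression solves the dual system (K + αI)a = y directly; the
Laplacian kernel is k(x, x′) = exp(−γ‖x − x′‖₁). KNN is implemented with
an explicit Minkowski exponent because no installed regressor exposes one.
AdaBoost is the AdaBoost.R2 algorithm over weighted regression trees
(rpart), with linear loss by default (square/exponential configurable) and
weighted-median prediction. Two backend caveats are deliberate: rpart caps
tree depth at 30, so the depth-40 default is clamped (inert at the data
sizes used here — grown depth stays well below 30); and the random-forest
backend grows trees to the leaf-size limit rather than a depth limit, which
for deep limits is equivalent. The MLP is a small fully connected network
(ReLU, Adam, full-batch, seeded initialization, early stopping off); its
exact optimizer trajectory is the least reproducible part of the zoo
across platforms, which is why none of the package's checks depend on it.

The target logK1 is never transformed. `evaluate()` reports MAE, RMSE, R²,
per-cation metrics and the regression-error curve (empirical CDF of
absolute errors); zero-variance targets yield an explicit NA sentinel for
R². `grid_search()` minimizes mean k-fold CV MAE with ties broken toward
the earlier grid point.

## Interpretation

`impurity_importance()` gives normalized mean decrease in variance for the
tree ensembles (for AdaBoost, per-tree importances averaged with the
estimator weights). `permutation_importance()` is model-agnostic: the mean
MAE increase over 10 seeded shuffles of one column (negative values mean
noise). Held-out evaluation data is recommended — on training data a tree
ensemble's overfitted noise splits inflate null-feature scores.
`mae_vs_dimensionality()` retrains a spec on the top-k ranked features and
records train/test MAE per k, which shows where added descriptors stop
helping.

## Applicability domain and screening

The applicability domain is a bounding box: per-descriptor [min, max] over
the training molecules, with closed intervals, so every training molecule
is in-domain by construction. `screen_library()` streams a (gzipped) SDF
in chunks — memory is bounded by the chunk size — and per molecule:
deduplicates by canonical SMILES, drops nonzero net formal charge,
featurizes, applies the AD filter, and predicts logK1 for each requested
cation under the given conditions (default 298 K, 0.1 M, NaClO4). Per-stage
counters (read / duplicate / charged / featurization-failed /
out-of-domain / predicted) are conserved: they always sum back to the
record count read.

## Selectivity

For a cation pair (A, B), `match_pairs()` finds (ligand, conditions) cells
measured for both cations — medium matched exactly, temperature within
0.01 K, ionic strength within 10⁻⁶ M — averaging replicate measurements
within a cell. The selectivity is ΔlogK1 = logK1(A) − logK1(B); swapping
the pair negates it, and the MAE/RMSE of (Δpred − Δexp) from
`selectivity_metrics()` are invariant to the order. Any pair list can be
supplied; nothing is hardwired to adjacent cations.

## The synthetic data generator

Because curated stability-constant compilations cannot be redistributed,
the package ships a seeded generator that emulates their *statistical
shape*, giving every downstream module a testable ground truth:

* ligands are assembled from four scaffolds (para/tri-substituted benzene,
  pyridine, aliphatic chain) and twenty carboxylate / amine / phosphonate /
  nitrile / halide substituents — neutral, single-fragment, valence-valid;
* logK1 is a clipped affine-plus-smooth function of five standardized
  informative descriptors (`NumHAcceptors`, `TPSA`, `BalabanJ`, `MolWt`,
  `NumAromaticRings` by default), the metal ionic radius, √(ionic
  strength) and temperature, plus Gaussian noise (default σ = 0.5 logK1
  units) and a sparse quadratic tail that produces the rare high-affinity
  measurements; values are clipped to the empirical range [−1.4, 30.7];
* per-cation counts are skewed, with Pm drawn at ~0.3% so one cation is
  rare, and roughly two-thirds of values fall in [0, 10].

What it does *not* emulate: real chelation chemistry (denticity effects,
medium-specific activity corrections), inter-laboratory error structure,
or the ligand-class clustering of real compilations. Passing tests on this
generator therefore demonstrate that the pipeline's algorithms behave per
contract (recovery of known signals, error floors near σ√(2/π), counter
conservation), not that any particular accuracy will transfer to real
measurements.

## Numerical choices and problem sizes

* Embedding seed default 42; every stochastic fit takes an explicit seed.
* Splits and folds sort ids before seeded sampling, so partitions are
  invariant to input row order.
* The test and acceptance runs use 2,000-row synthetic tables over ~100
  ligands with an 80/20 split — sizes chosen so the full pipeline
  (featurization, four-model zoo, importance, screening) completes in
  well under a minute while keeping per-cation subsets non-trivial.
* Degenerate inputs are explicit: unsupported cations/media, schema
  violations, layout mismatches, empty pair lists and zero-variance
  targets raise typed conditions or sentinels rather than silent defaults.

## Known limitations

* Real-data headline accuracies cannot be asserted without a curated
  experimental table; the package reproduces the published out-of-sample
  validation arithmetic from its bundled nitrogen-donor comparison table
  and validates everything else against synthetic ground truth.
* The descriptor engine is this package's own: named families follow the
  field's conventions but are not bit-compatible with other toolkits'
  implementations (the frozen-layout mechanism makes any corpus
  reproducible within `lanbind`).
* Successive constants (logK2, logK3), acid dissociation constants and
  neutral-complex stoichiometry are out of scope.
* Splitting is by measurement row, not by ligand; ligands present in both
  partitions make random-split metrics optimistic relative to truly novel
  chemistry.
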