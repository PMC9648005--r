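---
title: "A virtual articular chondrocyte: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual articular chondrocyte: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondronet)
```

## The biological question

Articular chondrocytes maintain joint cartilage. In osteoarthritis some of
them undergo a maturation switch called hypertrophy (RUNX2, type-X collagen,
MMP13 and IHH turn on; SOX9 and type-II collagen turn off), which drives
matrix degradation and mineralization. Whether a chondrocyte sits in the
healthy or the hypertrophic regime is decided by a densely interconnected
web of growth-factor signaling (WNT, BMP, TGF-β, FGF, IGF-I, PTHrP, IHH) and
pro-inflammatory pathways (NF-κB, MAPKs), feeding a transcription-factor
layer that in turn rewires the signaling proteins' expression. `chondronet`
implements an executable, semi-quantitative model of this two-layer system,
plus the screening machinery used to search it for anti-hypertrophic
(combination) treatments, and a consensus pipeline to learn additional
gene-regulatory edges from expression compendia.

## The model

Every biological component $i$ carries up to two sub-variables in $[0,1]$: a
**fast** one, $f_i$ (protein activation, post-translational time scale) and a
**slow** one, $s_i$ (gene expression, transcription/translation time scale).
What downstream rules consume is the **global functional activity**

$$ a_i = f_i \, s_i, $$

so a protein acts only if it is both expressed and activated. A component
absent from one layer contributes the neutral value 1 there.

Each participating (component, layer) pair has exactly one update rule. The
default transfer is additive:

$$ x_i \leftarrow \mathrm{clamp}_{[0,1]}\!\Big( \tfrac{1}{\kappa}\big(
   \textstyle\sum_{j \in A_i} a_j - \sum_{k \in I_i} a_k \big) \Big), $$

with activator set $A_i$, inhibitor set $I_i$ and saturation constant
$\kappa$ (default 1). $\kappa$ controls how fast excess net activation
saturates the variable at its maximum; it is the model's only free numeric
parameter, is configurable per rule, and rules transcribed from a published
model should carry that model's values. A product combiner
$\mathrm{clamp}(\prod_{A} a_j \prod_{I}(1-a_k))$ exists for the exceptional
mechanisms in which regulators act as a conjunction. A rule with no terms
marks an input (e.g. a growth factor): it holds its value unless clamped.

### Updating scheme (priority classes)

Simulation is asynchronous and stochastic, with fast reactions prioritized:

1. relax the fast layer — asynchronous passes over a freshly reshuffled
   order of fast sub-variables, until a full pass changes none by more than
   the tolerance;
2. update one uniformly chosen slow sub-variable;
3. stop when a full fast+slow sweep changes nothing by more than the
   tolerance (a stable state), or when step caps are hit (reported as
   non-convergence — a possible cyclic regime — never silently truncated).

One *time step* is one sub-variable update event; this is the unit in which
perturbation durations and convergence caps are counted. The random update
order is the model's only source of stochasticity, so the same initial state
can reach different stable states, and every result in this package is an
average over repetitions with a seeded RNG (identical seeds reproduce
identical trajectories bit for bit).

### Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `tolerance` | stability threshold per sub-variable | 1e-2 | matches the convergence/grouping tolerance used for the published attractors |
| `saturation` | $\kappa$ in the additive transfer | 1 | neutral choice; per-rule values come with a transcribed model |
| `duration` | clamp length of a perturbation, in steps | 1000 | perturbed regimes settle in ≲200 steps; longer clamps change nothing |
| `n_reps` | repetitions per perturbation condition | 100 | percentage resolution of 1%, with SD over 3 experiment blocks |
| `n_init` | Monte Carlo initializations | 10,000 (reference) | basin estimates are insensitive well below this; fixtures use hundreds |

The stability tolerance is applied per sub-variable by default; an option
applies it to global activities instead (the published description is
ambiguous between the two; both are exposed, the per-sub-variable reading is
stricter and is the default).

### Attractors, basins, phenotypes

`monte_carlo()` samples every unclamped sub-variable i.i.d. uniform on
$[0,1]$, simulates to convergence, and groups the finals by single linkage
under "max componentwise difference of global activities ≤ tolerance".
Basin fractions estimate reachability; growth-factor profiles can be clamped
throughout to emulate environments. Attractor profiles are matched to
phenotypes by marker signatures (high markers above $1-\text{band}$, low
markers below band, band 0.2): the shipped chondrocyte signatures encode
SOX9/NKX3.2/COL-II-high for *Healthy*, RUNX2/COL-X/MMP13/IHH-high for
*Hypertrophic*, and everything-low for the trivial *None* state. Signatures
are configuration (YAML), not code.

### Perturbations and screening

A perturbation clamps components to levels in $[0,1]$ (0 = inhibition,
1 = activation) for `duration` steps, then releases. During the clamp,
consumers see the clamp level as the component's global activity and its
sub-variables are frozen. On release, a component whose frozen sub-variables
already realize the clamp level is left untouched — this makes "clamp at the
attractor value" an exact no-op, as the interactive app documentation
promises — otherwise it carries the imposed level into the free phase
(protein side takes the level, expression set to 1). How an intermediate
level should partition between the two layers is genuinely open; we chose
the protein side because small-molecule treatments act post-translationally.

`screen_single()` enumerates all $2N$ one-component conditions,
`screen_pairwise()` all $\binom{N}{2} \times 4$ pair conditions (7080 for a
60-component model), streaming JSON-lines with per-condition seeds so
interrupted screens resume. `markov_summary()` averages the single-condition
ensemble into attractor-to-attractor transition probabilities (rows sum to 1
by construction). `select_candidates()` applies the published
candidate-treatment filter — more than 70% of repetitions reaching the
healthy state and fewer than 5% reaching None — bins survivors by healthy
percentage (100–90, 89–80, 79–70) and drops conditions touching excluded
components (e.g. transcription factors, which small molecules cannot target
directly). `dose_grid()` clamps two components over level grids, covering
both drug-dose screens (PKA × FGFR1) and receptor-balance sweeps
(ALK1/ALK5).

## The inference pipeline

The gene-regulatory layer can be augmented from a merged expression
compendium. The pipeline is: quantile normalization (every sample mapped to
the mean order-statistic reference) → ComBat-style empirical-Bayes batch
correction (per-gene standardization; per-batch location/scale estimates
shrunk towards across-gene priors — normal for location, inverse-gamma for
scale, method-of-moments fits, one-step posterior) → hierarchical-clustering
QC (Euclidean, complete linkage; majority-phenotype group accuracy) → three
edge scorers → consensus.

The scorers are re-implementations of the three standard families, not
bindings:

* **MI + DPI** (ARACNE family): plug-in mutual information on
  equal-frequency rank bins over all gene pairs, then data-processing-
  inequality pruning: in each triangle the weakest edge is removed (5%
  relative tolerance) as presumably indirect. Pruned edges are **absent**
  (NA) from the result — they can never pass a threshold. This sparsity is
  what makes the consensus selective.
* **Tree importance** (GENIE3 family): per-target extremely-randomized
  regression trees (100 bootstrap trees, `mtry = sqrt(p)`, random
  thresholds); importance is total variance reduction, normalized per
  target.
* **Stability regression** (TIGRESS family): selection frequency of each TF
  over 50 half-sample subsamples with random feature reweighting, along the
  leading 5 lambdas of a lasso path (glmnet).

An edge is *present* for a method when its score strictly exceeds that
method's threshold, mean − SD of all its finite scores; the consensus keeps
edges present in all three methods and signs each by the Spearman
correlation of source and target in the corrected matrix (activation if
positive). `integrate_edges()` appends consensus edges to the slow layer
with provenance `inferred`, skipping duplicates of curated terms.

A note on the mean − SD threshold: for sparse, spiky score distributions the
threshold is typically negative, so it excludes little on its own — the
selectivity of the consensus comes from the DPI-pruned (absent) entries and
the triple intersection. The stated monotonicity of the consensus ("raising
scores never removes an edge") holds for affine rescalings of a method's
matrix but is not a theorem when a single below-mean score is raised (the
threshold moves too); the tests assert the provable forms.

## The synthetic world

`simulate_expression()` emulates the merged multi-platform compendium the
inference pipeline is designed for: a linear-Gaussian DAG (5 TFs, 15 target
genes with 1–2 TF parents each, signed weights in 0.7–1.2, intrinsic noise
SD 0.3 on a unit signal scale), an OA-like vs WT-like mean shift (1.0) on
two TFs, and per-gene per-batch location (SD 1.0) and scale (log-SD 0.25)
distortions with the first batch as undistorted reference. These magnitudes
were chosen once as representative of cross-platform microarray merges —
batch offsets comparable to biological signal, scale wobble of tens of
percent — and are not tuned to tests. What the generator does **not**
emulate: probe-level artifacts, platform chemistry, nonlinear regulation,
feedback loops (the linear model must be acyclic so recovery has a tractable
ground truth). A green recovery test therefore establishes that the pipeline
recovers planted linear-Gaussian structure under batch distortion — not that
it recovers real regulatory biology.

Measured on this world (see the test suite): the full pipeline attains
pooled consensus precision ≈ 0.67 against the planted edges over a 10-seed
battery (every seed ≥ 0.45), and 100% of recovered edges carry the planted
sign on noiseless data. Per-method AUPR enrichment over random ranking is
1.7–3.2×; the ceiling is structural, since reverse TF→TF edges cannot be
oriented from observational data and collinear co-parents split credit.

The dynamic fixtures are: a two-component toggle (self-activation plus
mutual inhibition at saturation 0.5, i.e. gain 2), whose three isolated
fixed points (0,0), (1,0), (0,1) are enumerable by the shipped grid oracle
`brute_force_attractors()`; an activation chain with a clamped input; and
seed-deterministic random two-layer networks. The toggle's all-off state has
a measure-zero basin (only the diagonal reaches it), so Monte Carlo finds
exactly the two polarized states — the documented discrepancy between the
sampling view and the grid view of the attractor landscape. The grid oracle
itself misses off-grid fixed points (e.g. the toggle's unstable interior
point at 2/3); it is an oracle for on-grid stable states only, and is
restricted to ≤ 4 free sub-variables.

## Numerical choices and degenerate inputs

* All sub-variables are clamped into $[0,1]$ at every update; non-finite
  rule outputs raise immediately.
* Grouping uses max-norm on global activities; states are first collapsed
  onto a tolerance/10 grid (converged finals pile up on attractors) before
  exact single linkage, keeping the grouping $O(u^2)$ in the number of
  unique profiles rather than samples.
* Child seeds for Monte Carlo replicates, screen conditions and scorer
  targets are derived from the master seed by a multiplicative hash kept
  below $2^{31}-1$, so any condition can be re-run in isolation.
* Zero-variance genes score 0 with a warning; a zero-variance pair at the
  consensus sign step is dropped with a warning; a method matrix with fewer
  than two finite scores uses SD 0 in its threshold.
* Empty networks are valid for I/O and invalid for topology statistics;
  unclamped inputs make the grid oracle error (they generate fixed-point
  continua).
* Batch correction re-anchors every gene to its pooled pre-correction mean, so
  merging does not move the dataset's location.

## Known limitations

* The curated 60-component chondrocyte rule set is distributed through
  external supplementary material and model repositories; it is not shipped
  here. The acceptance tests that depend on it (full-model topology, basin
  percentages, Markov exit probability, inflammation/TGF-β scenario) run
  only against a user-supplied transcription at
  `inst/extdata/full_model/network.xml` and fail with an explanatory message
  otherwise. The growth-factor profile tables (profiles A/B) and the
  inflammation/TGF-β clamp sets are figure-embedded in the source
  publication and likewise must be transcribed
  (`inst/extdata/growth_factor_profiles.yaml` is a documented placeholder).
* Only singleton attractors are characterized; cyclic regimes are detected
  (non-convergence) but not analyzed.
* The engine is not an ODE model: time is event-counted, not physical, and
  magnitudes are semi-quantitative activities, not concentrations.
* The inference pipeline consumes a clean gene × sample matrix;
  probe-to-gene collapsing and platform-specific preprocessing are out of
  scope.
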