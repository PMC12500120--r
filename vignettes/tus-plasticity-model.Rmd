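---
title: "Modeling stimulation-induced plasticity in high-order brain interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling stimulation-induced plasticity in high-order brain interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tusplast)
```

## What this package models

Focal neuromodulation (for example low-intensity transcranial ultrasound)
perturbs one brain region, but its functional consequences spread through the
anatomical network. `tusplast` implements a complete, testable pipeline for
studying that spread in terms of *high-order interactions* (HOI): the
redundancy and synergy carried jointly by pairs of regional signals across
time. The pipeline has five scientific components:

1. **Gaussian integrated information decomposition** (`phiid_core`
   functions): pairwise redundancy/synergy atoms from lagged covariances.
2. **Structural communication models** (`comm_model_set()`): distance,
   shortest-path efficiency, search information, communicability.
3. **A heterogeneous Stuart–Landau whole-brain simulator**
   (`simulate_hopf()`, `run_hopf()`) with a stimulation-intensity parameter.
4. **Two-stage calibration** (`fit_global_coupling()`, `fit_bias_scale()`).
5. **Permutation group statistics and intensity sweeps**
   (`perm_ttest()`, `regionwise_contrast()`, `alpha_sweep()`).

Everything runs on synthetic cohorts with known ground truth
(`make_region_table()`, `make_connectome_cohort()`,
`make_ground_truth_cohorts()`), so every stage is verifiable without any
imaging data.

## Integrated information decomposition

For two z-scored regional signals $x, y$ and lag $\tau$, consider the jointly
Gaussian 4-vector $(x_{t-\tau}, y_{t-\tau}, x_t, y_t)$. The time-delayed
mutual information $I(x_{t-\tau}, y_{t-\tau};\, x_t, y_t)$ is decomposed over
the product of two copies of the partial-information redundancy lattice
$\mathcal{A} = \{\{1\}\{2\}, \{1\}, \{2\}, \{12\}\}$, giving $4 \times 4 = 16$
atoms $\alpha \to \beta$ ("source composition $\to$ target composition").
Cumulative values use the minimum-mutual-information (MMI) redundancy
function,

$$ f(\alpha \to \beta) \;=\; \min_{a \in \alpha,\; b \in \beta}
   I\!\left(\text{past}_a;\ \text{present}_b\right), $$

with all informations in closed Gaussian form
($I(A;B) = \tfrac12 \log \frac{\det \Sigma_{AA}\,\det \Sigma_{BB}}
{\det \Sigma_{AB}}$, nats). Atoms follow by Möbius inversion along a linear
extension of the product order; by construction they sum exactly to the
time-delayed mutual information, which the test suite asserts to $10^{-8}$
and cross-checks against an independent $16 \times 16$ linear solve of
$f = Z\,\mathrm{atoms}$ (zeta matrix $Z$) to $10^{-10}$.

The pipeline surfaces two atoms: **persistent redundancy**
($\{1\}\{2\} \to \{1\}\{2\}$, written `rtr`) and **persistent synergy**
($\{12\} \to \{12\}$, `sts`). Per subject, `hoi_matrices()` assembles the
symmetric $N \times N$ maps of both, takes per-region row medians (diagonal
excluded — self-decomposition is undefined in the pairwise scheme), and
ranks regions by strength (ascending, ties averaged). Contrasts can run on
either the absolute medians or the ranks; the two scales are sensitive to
different effects (see *Contrasts* below).

Choices worth knowing:

* `tau` defaults to 1 sample — the minimal-lag convention; configurable.
* Series are z-scored per region first, so atoms are comparable across
  regions and reported in nats.
* A non-positive-definite pair covariance (e.g. duplicated signals) is
  ridged by $10^{-9}$ on the diagonal with a warning.

## Communication models

From a cohort of connectomes, the representative distance and weight
matrices are elementwise means normalized by their maxima. On the cost
matrix $L = 1/\bar M$ (cost $\infty$ where no edge):

* **SPE** — inverse of the minimal transmission cost $\Lambda^*_{ij}$
  (Dijkstra); 0 where unreachable.
* **SI** — bits to bias a random walk onto the stored shortest route:
  $-\log_2 \prod T_{uv}$ along the route, with $T$ the row-normalized weight
  matrix. When several geodesics tie, the lexicographically smallest node
  sequence is stored, so SI is reproducible; the alternative convention of
  summing over all geodesics is deliberately not used, matching the printed
  single-path product formula.
* **CMY** — matrix exponential of the strength-normalized weights. The
  default normalization divides by the product of endpoint strengths
  ($W_{ij}/(s_i s_j)$, as printed); the square-root normalization
  conventional in the communicability literature is available via
  `normalization = "symmetric_sqrt"`. Strength is row strength (the printed
  self-referential strength formula is treated as a typo).

`model_vector()` reduces any model matrix to a per-region vector: the row at
the stimulated target (for target-anchored associations) or the min–max
scaled row median (the heterogeneity vector $\beta$ fed to the simulator).

## The whole-brain model

Each region is a Stuart–Landau oscillator — the normal form of the
supercritical Hopf bifurcation — diffusively coupled through the structural
weights $M$ (max-normalized so the coupling constant is unit-free):

$$ \dot x_i = \left(a_i - x_i^2 - y_i^2\right) x_i - \omega y_i
   + G \textstyle\sum_j M_{ij} (x_j - x_i) + \gamma \eta_i(t), $$

and symmetrically for $y_i$ with $+\omega x_i$. For $a_i < 0$ the node is a
noise-driven stable focus; for $a_i > 0$ it oscillates on a limit cycle of
radius $\sqrt{a_i}$; near $a_i = 0$ the two regimes mix. Defaults follow the
study protocol: $f = 0.05$ Hz, $\gamma = 0.02$, $G = 0.16$,
Euler–Maruyama at $dt = 0.1$ s (noise increments $\gamma\sqrt{dt}\,N(0,1)$,
independent per node and component), 1100 s runs, 100 s trimmed at each end
(15 min retained). At these settings the discrete map's invariant radius
deviates from $\sqrt a$ by under 1% for $a \le 0.3$, which the tests assert.

One printed form of the model carries the amplitude bracket $x^2 - y^2$;
only $x^2 + y^2$ yields the limit cycle the model is described to have, so
the normal form is the default and the subtractive variant survives behind
`printed_bracket = TRUE` for auditing.

Heterogeneity and stimulation enter through the bifurcation parameters:

$$ a_i = \mathrm{bias} + \mathrm{scale}\,(\beta_i + \alpha\,[i = s]), $$

with $\beta$ a communication-model summary in $[0,1]$, $s$ the stimulated
target and $\alpha$ the intensity ($\alpha = 0$ is the control condition;
fitted control parameters in the source study were
$(\mathrm{bias}, \mathrm{scale}) = (-0.17, 0.24)$ for the distance model).

### The filter-band question

The stated post-processing band (0.001–0.01 Hz) lies *below* the 0.05 Hz
oscillation. We honor it as the `preprocess_sim()` default, but note that a
15-minute series has only $O(10)$ degrees of freedom in that band, so FC
computed there is statistically empty — grid searches against such FC are
provably uninformative (we verified this directly: score surfaces are flat
noise). All calibration and HOI experiments in this package therefore use
the carrier-inclusive band 0.01–0.1 Hz (also the default phase band for the
Kuramoto order parameter), set explicitly via `band = c(0.01, 0.1)`. Both
bands are plain configuration; nothing in the code privileges either.

### Synchrony

`kop()` band-passes each region, extracts instantaneous phases
$\theta_j(t)$ from the FFT-based analytic signal, and returns the time-mean
and SD of $R(t) = |N^{-1} \sum_j e^{i\theta_j(t)}|$ after discarding 10% of
samples at each edge (filter and Hilbert warm-up).

## Two-stage calibration

A fit target is an FC matrix plus a mean-synchrony level. The score for a
parameter cell is

$$ \mathrm{score} = r_{\mathrm{FC}} \times (1 - |\Delta \mathrm{KOP}|), $$

with $r_{\mathrm{FC}}$ the Pearson correlation of off-diagonal upper
triangles of cohort-averaged FC. Multiplying the two criteria rewards only
simulations matching both pattern and level; the orientation of the
synchrony factor ($1 - |\Delta|$, larger is better) is this package's
resolution of an ambiguity in how the two columns are combined.

Stage 1 fits the global coupling $G$ on a homogeneous model
($a_i = -0.02$); stage 2 fits $(\mathrm{bias}, \mathrm{scale})$ at fixed $G$
given $\beta$. Ties break deterministically (smallest $G$; smallest
$|\mathrm{bias}|$, then smallest scale). A constant $\beta$ leaves
$(\mathrm{bias}, \mathrm{scale})$ identifiable only through
$\mathrm{bias} + \mathrm{scale}\,\bar\beta$; this ridge is detected and
warned about. Two facts shape the recovery experiments in the tests:

* A homogeneous proxy fitted to a *heterogeneous* generator confounds $G$
  with the mean of $a$; recovery experiments therefore match generator and
  fitting model stage by stage.
* The $(\mathrm{bias}, \mathrm{scale})$ surface has a ridge along constant
  $\mathrm{bias} + \mathrm{scale}\,\bar\beta$; discriminating along it needs
  cohort averaging (8 connectomes in the test configuration).

The recovery experiments run at 16 regions, 8 connectomes (backbone density
0.5 — small backbones disconnect at the 84-region default density), grids
with step 0.04 spanning $G \in [0.08, 0.24]$,
$\mathrm{bias} \in [-0.25, -0.09]$, $\mathrm{scale} \in [0.16, 0.32]$, and
10 repetitions per stage. These sizes are the package's scaled-down standard
experiment; the same code runs any grid.

## Contrasts, associations, and the intensity sweep

`perm_ttest()` uses the Welch statistic (the emulated design is unbalanced,
11 vs 22) with two-sided permutation p-values and the add-one correction,
so $p \ge 1/(n_{\mathrm{perm}}+1)$; its type-I error is asserted against the
binomial interval in the tests. `regionwise_contrast()` applies it per
region to per-subject HOI strengths, on the absolute or rank scale, at the
two-sided 0.05 level per region (the analysis's per-region permutation
correction; an optional max-statistic across-region correction is
available). Permutation streams are seeded per region.

The two scales are complementary, and the stimulation-intensity sweep shows
why. Quenching one region (strongly negative $\alpha$) changes its standing
*relative* to other regions — a rank-scale effect, localized at and around
the target. Strong excitation (large positive $\alpha$) raises synchrony and
redundancy *globally* — an absolute-scale effect that cancels in ranks.

Which series the HOI stage consumes matters here. Gaussian mutual
information is invariant to per-region rescaling, so quenching a region
changes its HOI *only* insofar as its correlations change. In a diffusively
coupled network a quenched node keeps receiving coherent input from its
neighbors; inside a narrow analysis band that input dominates and the
node's correlations — hence its redundancy — barely move. On the broadband
series the node's white-noise floor is retained, so losing intrinsic
signal amplitude genuinely lowers its correlations. The HOI stage therefore
consumes the raw trimmed series by default (`band = NULL` in the cohort
configuration), consistent with treating empirical-side filtering as an
open hook; the narrow-band option remains configuration.

A related finite-sample caveat: two cohorts drawn from the *same* generator
with different seeds can drift apart in overall synchrony, and because an
absolute HOI shift of that kind is shared across regions, the absolute-scale
contrast can flag many regions at once even under the null. Ranks cancel
such common shifts. Null-zone and localization claims are therefore read on
the rank scale, while the widespread regime — whose genuine effect
(synchrony rising toward 1) dwarfs any drift — is read on the absolute
scale.
`alpha_sweep()` therefore records significant-region counts and the Spearman
similarity to a reference t-map across the $\alpha$ grid; the control cohort
is simulated once and shared across grid points, since the $\alpha = 0$
generator is identical everywhere.

`model_association()` correlates (Spearman by default; the headline figure
labels Spearman) a model vector with a per-region HOI change vector,
Bonferroni-corrected for the 8-test family (4 models × 2 measures per
target); unreachable-pair entries are removed pairwise.

## The synthetic cohort generator

`make_region_table()` places mirrored hemispheres in ellipsoids of brain-like
dimensions (half-axes 30/60/45 mm) with subcortical structures pulled toward
the midline; the default 84-region table carries the standard 34 cortical
plus 8 subcortical names per hemisphere. `make_connectome_cohort()` builds an
exponential-distance-rule backbone ($w_{ij} \propto e^{-d_{ij}/\lambda}$,
$\lambda = 30$ mm), thresholds to a target density (default 0.35), and draws
subjects by mean-1 lognormal jitter (CV 0.2) on both weights and lengths —
defaults chosen once as plausible connectome statistics: subjects correlate
with the backbone above 0.9, lengths are Euclidean up to jitter, and a
disconnected backbone raises an error that reports the largest component.

What the generator does *not* emulate: real cortical geometry and folding,
tractography biases (gyral bias, distance-dependent false negatives),
hemodynamics (no Balloon–Windkessel stage — the simulator's $x(t)$ is
"BOLD-like" only), head motion, or session-to-session variability. Passing
tests therefore demonstrate internal correctness and recoverability of the
method under its own assumptions, not robustness to those empirical
nuisances.

### Where the localized-to-global transition lives

The transition of stimulation effects from localized (strongly negative
$\alpha$) through silent ($\alpha \approx 0$) to widespread (strongly
positive $\alpha$) is a *network-size-dependent* phenomenon. In small dense
networks (≈20 regions) every node is within one or two hops of the target
and single-node perturbations can tip global synchrony, so the localized
regime is unstable; at 84 regions localization is robust, but a single
region needs a proportionally larger intensity to entrain the whole
network. The package's standard transition experiment (`regime_experiment()`)
therefore runs at 84 regions with 8 subjects per cohort and probes the
three zones at $\alpha = -4, 0, +4$ — on the $a_i$ scale the stimulation
term is $\mathrm{scale}\cdot\alpha \approx \mp 1$, deep on either side of
the bifurcation. The generic sweep grid stays $\alpha \in [-1, 1]$ (step
0.1) by default for target-scale dose-response curves; both are plain
configuration.

## Degenerate inputs and numerical conventions

* Constant (zero-variance) regional series: error listing the regions.
* Duplicated signals: ridged covariance with a warning.
* Unreachable pairs: SPE 0, SI $\infty$, excluded from correlations; the
  model set records the count.
* Isolated (zero-strength) nodes: error in SI and CMY.
* Numerical blow-up in the integrator ($|x| > 10^6$): error with the step
  index.
* All randomness flows from explicit seeds through a deterministic
  seed-spawning helper (`derive_seed()`), so cohorts, permutation streams
  and grid cells are independently reproducible; equal seeds give
  bit-identical output.

## A small end-to-end run

```{r demo, eval = FALSE}
cfg <- load_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "tusplast"))
cfg$out_dir <- tempfile("tusplast_demo")
manifest <- run_pipeline(cfg)
read.table(file.path(cfg$out_dir, "sweep.tsv"), header = TRUE)
```

The demo uses 8 regions, 4 subjects and 3 intensities and completes in
about a minute; outputs land as TSV/CSV/JSON with a manifest recording every
seed and parameter.

## Known limitations

* Gaussian MMI is the only redundancy function; non-Gaussian estimators and
  alternative redundancies (CCS, Broja) are out of scope.
* The HOI stage is $O(N^2)$ pairs per subject with small-matrix determinants
  in R; at 84 regions a subject takes a few seconds.
* Group contrasts are unpaired by design fidelity, although synthetic
  cohorts share connectomes across conditions; a paired design would be more
  powerful but would not mirror the emulated between-group protocol.
* The empirical 14 vs 42 minute session asymmetry is emulated only as a
  robustness fixture for covariance estimation, not in the default protocol
  (which uses the 15-minute simulated series throughout).
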