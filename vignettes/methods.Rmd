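---
title: "From NMR fingerprints to metabolic sub-networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From NMR fingerprints to metabolic sub-networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`fingernet` implements a complete analysis chain for untargeted
^1^H-NMR metabolomics of exposed cell cultures: binned spectra are filtered
with orthogonal signal correction (OSC), modelled with PLS-DA, reduced to a
*metabolic fingerprint* (the discriminant metabolites of each exposure
condition), and the fingerprint is projected onto a genome-scale metabolic
network to extract the sub-network most plausibly modulated by the exposure.
Set algebra on sub-networks then separates effects shared between two
compounds from compound-specific effects. This vignette explains the
statistical machinery, the tunable parameters, and the design decisions
taken where the underlying methods leave genuine freedom.

## The data model

The central container is a `spectra_matrix`: an `n x p` matrix of
non-negative binned intensities with a ppm axis, plus a one-way scaling
state (`raw -> normalized -> centered/pareto`). The state machine exists
because normalizing or Pareto-scaling twice is a silent, hard-to-spot
mistake; here it is an error.

A `sample_design` table assigns every sample to exactly one group
(compound x dose), with one group flagged as the vehicle control. Group
sizes of 17 controls plus 12 per dose group (three doses per compound) are
the package default, matching a typical in-vitro dose-range design.

## Preprocessing

- **Binning** (`bin_spectra`): half-open bins `[left, right)` of 0.01 ppm
  by default, edges anchored at multiples of the bin width. Bins
  intersecting an exclusion interval are dropped whole; the defaults
  exclude the residual water region (4.5–5.0 ppm) and the TMSP reference
  region (−0.05–0.05 ppm). These are community defaults, not values taken
  from any particular acquisition.
- **Total-area normalization** (`normalize_total_area`): each spectrum is
  divided by its summed intensity, removing cell-number and dilution
  differences. Idempotent; zero-area samples are reported by id.
- **Scaling** (`scale_spectra`): mean-centering and/or Pareto scaling
  (division by the square root of the column SD, denominator n−1). Pareto
  scaling damps — but does not flatten — the dynamic range between strong
  and weak spectral regions. Zero-variance columns are left unscaled and
  reported. The package default for modelling is `center_pareto`.

## The multivariate engine

### PCA screening

`pca_screen` is an SVD-based PCA with Hotelling T² outlier flagging over
the retained components: sample *i* is flagged when its T² exceeds
`a(n−1)/(n−a) * qf(1−alpha, a, n−a)`. It is a screening aid; the pipeline
reports flags but does not drop samples automatically — outlier exclusion
is an analyst decision.

### Orthogonal signal correction

`osc_filter` removes structured variation *orthogonal to the class
structure* — instrument drift, batch effects, culture-plate effects — that
can overshadow treatment effects. Per removed component:

1. seed the score `t` with the first principal component of `X`;
2. orthogonalize `t` against the column-centered class dummy matrix `Y`;
3. find the unit weight vector `w` minimizing `||Xw − t||` (via the
   pseudoinverse of `X`, computed once per component from its SVD) and set
   `t = Xw`; iterate to convergence (relative score change `< 1e-10`,
   at most 100 iterations — non-convergence is an error that reports the
   last relative change);
4. orthogonalize the converged score once more (so the removed score is
   label-orthogonal to machine precision), compute the loading
   `p = X't/(t't)` and deflate `X <- X − t p'`.

Two invariants are enforced and tested: the removed scores are uncorrelated
with every dummy column (|corr| < 1e-6), and `filtered_X + sum(t p')`
reconstructs the input to 1e-8. One component is removed by default — the
conservative choice; how much orthogonal structure a data set carries is an
empirical question, and `variance_removed` is reported so the analyst can
judge.

A consequence worth stating plainly: OSC removes *only* label-orthogonal
variance. Any part of a confounder that is, by finite-sample accident,
correlated with the class labels stays in the data and is indistinguishable
from treatment signal. No filter can fix this; it is a property of the
design, not of the implementation.

### PLS-DA

`fit_plsda` is a two-block NIPALS partial least squares regression against
the column-centered class dummy matrix (one column per group, supporting
the 4-group and 7-group comparisons a dose-range study needs). Per
component the weight/score/loading triplet is iterated to convergence
(tolerance 1e-12), both blocks are deflated on the X-score, and the Y sum
of squares captured per component is recorded. Invariants: unit-norm
weights, pairwise-orthogonal scores, `R²Y` non-decreasing in the number of
components.

### Cross-validated Q² and component selection

`cross_validated_q2` uses stratified k-fold cross-validation (7 folds by
default, assignment seeded): `Q² = 1 − PRESS/SS`, with held-out dummy
responses centered by training-fold means and per-component values computed
sequentially. Training folds are re-centered internally, so fold models
never see held-out means.

`select_components` adds components while the cumulative Q² improves by at
least `min_improvement = 0.05`, the classic chemometrics significance limit
for an additional component, with a hard cap (10 by default, 4 in the demo
config). A bare "any increase" rule was considered and rejected: cumulative
Q² routinely fluctuates upward by 0.02–0.03 when an added component models
cross-validation noise, and such components dilute the VIP scores with
noise directions.

### Permutation validation

`permutation_test` refits the model under uniformly random label
permutations (200 by default) with the same component count and folds, and
reports `empirical_p = (1 + #{Q²_perm >= Q²_obs}) / (n_perm + 1)` — so the
attainable minimum with 200 permutations is 1/201 ≈ 0.005. The
Simca-style intercept criterion is deliberately not implemented: the
empirical p-value is well-defined and assumption-free.

### VIP and the discriminant rule

`vip_scores` implements
`VIP_j = sqrt(p * sum_a ssy_a (w_ja/||w_a||)² / sum_a ssy_a)`, which is
mean-square normalized (`sum VIP² = p`, tested to 1e-8). A bin enters a
fingerprint iff `VIP > 1.5` *and* its Kruskal–Wallis p-value across the
comparison's groups is below 0.05 — a multivariate influence criterion
confirmed by a univariate rank test. Both thresholds are the conventional
ones and both are recorded on every selection.

Two deliberate choices here:

- The rank test runs on the *unfiltered* (pre-OSC) scaled data. OSC
  shrinks within-group variance while leaving group contrasts, so running
  a univariate test on filtered data inflates significance across all
  bins.
- No multiple-testing correction is applied by default, matching the
  conventional raw-0.05 practice this chain reproduces; `p_adjust = "BH"`
  is available and tightens the univariate gate considerably. With ~200
  bins and a raw 0.05 threshold, a handful of chance selections per
  comparison is statistically expected — users who need a sharp bin list
  should switch BH on.

`annotate_bins` assigns each selected bin the metabolite owning the
nearest tabulated chemical shift within `tol_ppm = 0.02` (two default
bins), ties broken by distance then alphabetically; unassigned bins are
kept, never dropped. Three shift tables transcribing published
discriminant-metabolite assignments for a BPA dose series, an E2 dose
series and the joint comparison ship with the package.

## The synthetic-data generator

Because raw spectra for this kind of study are rarely deposited, every
stage is validated against `simulate_spectra`, which generates exactly the
structure the chain assumes:

- a smooth positive baseline (uniform 5–15 x noise SD per bin);
- additive Gaussian noise of known SD — effect sizes are specified in
  units of this SD;
- per-group effects planted on signature bins (`signature_spec`), with
  directions assigned arbitrarily: published tables report *which*
  metabolites discriminate, not the sign, so no test may assert direction;
- a per-sample multiplicative size factor (lognormal, sd 0.05 on the log
  scale) on the baseline, motivating total-area normalization — it can be
  switched off (`size_factor_sd = 0`) to recover the pure additive model
  whose group-mean contract (`|Δ| < 4 noise_sd/sqrt(n)`) is tested
  exactly;
- one rank-one confounder `s v'` with unit-norm loading and scores drawn
  independently of the labels — precisely the structure OSC removes;
- a single global offset if needed so intensities are non-negative; a
  common offset leaves every group contrast untouched.

An earlier design multiplied lognormal noise on log-intensities; it was
dropped because it makes "effect in units of noise SD" ill-defined on the
intensity scale, where the generator's contracts are stated.

What the generator does *not* emulate: Lorentzian peak shapes, J-coupling
multiplets, peak-position jitter between samples, baseline distortions,
and correlated noise between neighbouring bins. Passing tests therefore
show the statistical machinery is correct under its stated assumptions,
not that the chain is robust to misaligned or badly phased real spectra —
alignment and baseline correction are upstream of this package.

One empirical note on study design, established with this generator: with
identical effect sizes at every dose, the dose-group dummy columns are
inherently unpredictable by a linear model (a single graded score cannot
separate a middle dose from its neighbours), capping Q² well below the
usual robustness threshold however strong the signal. Realistic
dose-*specific* response patterns — different metabolite sets per dose, as
published fingerprint tables show — make the groups linearly separable and
are what the strong-signal demonstrations use.

## The network side

`read_sbml`/`write_sbml` handle SBML Level 2/3 core (species,
compartments, reactions, reversibility, stoichiometry) — parsing is
all-or-nothing, never a partial network. `merge_compartments` collapses a
multi-compartment reconstruction to one compartment, because untargeted
metabolomics cannot localize metabolites within the cell: metabolite ids
are collapsed by stripping a configurable compartment suffix
(`_[A-Za-z0-9]+$` by default), pure transport reactions disappear, and
duplicated reactions are deduplicated keeping the lexicographically
smallest id. The operation is idempotent and returns the old-to-new id
mapping.

`build_compound_graph` builds the bipartite metabolite–reaction graph,
dropping side compounds (water, protons, nucleotide and nicotinamide
cofactors, CO2, phosphate, O2 — shipped as an editable TSV) and any
reaction left without a substrate or product. Metabolite node weights
default to squared degree, the established hub-avoidance criterion;
`degree` and `unit` schemes are available.

`lightest_path` minimizes the sum of node weights over the path, endpoints
included. Node weights are turned into edge weights as the mean of the two
endpoint weights — path edge cost then equals node cost minus half the
(fixed) endpoint weights, so the transformation is exact, not heuristic.
Ties are broken deterministically toward the lexicographically smallest
node sequence. `extract_subnetwork` unions the lightest paths over all
unordered seed pairs and records per-pair provenance and unreachable
pairs; `subnetwork_algebra` applies intersection/difference/union
independently to metabolite and reaction id sets (refusing to mix
sub-networks from different parent networks).

The reaction graph is undirected by default: sub-network extraction
recovers substrate–product adjacency, not flux directionality. Name
mapping from fingerprints to network ids is case-insensitive exact
matching on a curated synonym table; unmapped names are returned, never
silently dropped, and a synonym pointing at two ids is an error. Note that
AMP is both a plausible fingerprint metabolite and a default side
compound: if it is filtered from the graph it will surface as an unmapped
seed rather than vanish.

## The pipeline

`run_pipeline` wires the stages together from one YAML config: simulate
(or read) spectra, normalize and scale, PCA-screen, then per comparison
re-center the group subset, OSC-filter, select the component count by
cross-validation, fit, permutation-test, compute VIP, select and annotate
discriminant bins; finally map fingerprints onto the (collapsed) network,
extract sub-networks, and compute common/specific pairs. Every source of
randomness derives from the single master seed by fixed offsets, so
identical config + seed reproduces identical numbers, which the test suite
checks byte-for-byte on the serialized summaries.

Problem sizes in the shipped demo and test suite (200 bins, 53 samples,
50-run recovery batches, 100-graph oracle sweeps, toy networks of tens of
nodes) were chosen so the entire suite exercises every contract in about a
minute on one core; they are demonstration scales, and every routine
accepts full-size inputs.

## Known limitations

- No OPLS-DA; OSC + PLS-DA is the implemented (and historically
  equivalent) route.
- No peak alignment, baseline correction or phasing — upstream.
- Score plots are plain ggplot2 scatter plots without confidence ellipses.
- The SBML reader covers core constructs only (no FBC extension, no
  annotations); enough for compartment collapsing and graph building.
- Numerical agreement with any particular commercial chemometrics package
  is approximate: deflation order and scaling conventions differ between
  implementations, so R²Y/Q² agree to a few percent, not to machine
  precision.
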