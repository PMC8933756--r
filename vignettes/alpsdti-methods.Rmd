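---
title: "Methods: the perivascular diffusivity index, structural connectomes and cohort statistics in alpsdti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the perivascular diffusivity index, structural connectomes and cohort statistics in alpsdti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

The glymphatic system clears interstitial waste from the brain along
perivascular spaces. A widely used non-invasive proxy for its function is a
diffusion-tensor MRI statistic computed "along the perivascular space": at
the level of the lateral-ventricle body, the deep medullary veins — and
their perivascular spaces — run left–right (the scanner x axis), while the
adjacent projection fibers run head–foot (z) and association fibers
anterior–posterior (y). Because the perivascular direction is orthogonal to
both fiber populations, extra water mobility along x that is *shared* by
both fiber regions is attributable to perivascular flow rather than to the
fibers themselves.

`alpsdti` implements that index together with the stages that surround it
in a typical clinical study: diffusion tensor estimation with global FA /
MD / AD / RD summaries, deterministic streamline tractography with weighted
structural-connectome graph measures, and a group-comparison / correlation
statistics layer. Since patient diffusion MRI cannot be redistributed, the
package ships a synthetic-data module — tensor phantoms with a closed-form
ground-truth index, and two-group cohorts with imposed correlation
structure — so that every stage is testable end to end.

## The index

For a selected projection-fiber voxel and association-fiber voxel, with
scanner-frame tensor elements \(D_{xx}, D_{yy}, D_{zz}\):

\[
\mathrm{index} \;=\;
\frac{\mathrm{mean}(D_{xx}^{\mathrm{proj}}, D_{xx}^{\mathrm{assoc}})}
     {\mathrm{mean}(D_{yy}^{\mathrm{proj}}, D_{zz}^{\mathrm{assoc}})}
\]

The numerator is diffusivity along the perivascular axis in the two fiber
regions; the denominator is diffusivity perpendicular to both the fibers
and the perivascular spaces. An isotropic medium gives exactly 1; larger
values indicate greater perivascular water mobility. Three points are
deliberate and fixed:

* **Raw tensor elements, not eigenvalues.** The formula's symbols are
  scanner-frame diagonal elements; `alps_pipeline()` extracts `Dxx`,
  `Dyy`, `Dzz` from the fitted tensor directly.
* **Voxel selection by modal orientation.** Within each rectangular ROI
  the dominant axis of every voxel (argmax of the principal eigenvector's
  absolute components, ties broken x < y < z) is computed; the modal axis
  is taken, and among voxels attaining the mode the one with the largest
  alignment \(|e_1 \cdot \hat a|\) is selected, with lexicographic
  voxel-index tie-break. This reads "the most frequent orientation" as a
  mode over the ROI and then picks the purest fiber voxel —
  deterministic, and on homogeneous phantoms equivalent to any other
  reasonable reading.
* **"On the same x-axis"** is enforced structurally: the projection,
  association and (optional, reported-only) subcortical boxes of one
  hemisphere must share their z-range, so the selected voxels lie on one
  mediolateral line in a single axial band.

Hemisphere handling is configurable because usage in the field varies:
`alps_pipeline()` accepts one ROI spec or a list of them and averages the
per-hemisphere indices (the bilateral default phantom supplies both).

## Tensor estimation

`fit_tensor()` uses log-linear ordinary least squares on
\(\ln(S/S_0) = -b\, g^\top D g\), with \(S_0\) the mean of all b = 0
volumes. OLS (rather than weighted or robust variants) is the reproducible
baseline and is exact in the noiseless limit, which is what the closed-form
phantom checks exploit. Signals at or below zero are floored to `1e-12`
before the log; all-zero voxels are marked invalid rather than fatal.
Negative eigenvalues — possible under noise — are clamped to zero and the
clamp count is reported on the field, which keeps FA within [0, 1].
Eigenvalues are sorted descending; FA, MD = mean eigenvalue,
AD = \(\lambda_1\), RD = \((\lambda_2+\lambda_3)/2\) follow the standard
closed forms, with FA of the zero tensor defined as 0.

Global DTI parameters are unweighted voxel means over a summary mask.
Which voxels enter such "region statistics" is not standardised, so both
options are provided with provenance recorded: the set of voxels visited by
at least one accepted streamline (`visited_mask()`, mirroring whole-brain
seeded region statistics) or a plain FA > 0.2 mask (`fa_mask()`).

## Tractography and the connectome

`track()` is deterministic principal-eigenvector (FACT-style) tracking:
seeds uniform inside the FA > 0.15 mask, bidirectional following with
nearest-voxel orientation lookup, termination on mask exit or a turning
angle above the threshold. Defaults are 10,000 seeds, 60°, 30 mm minimum
length, step = half the smallest voxel dimension. Streamline endpoints
("extreme points") falling in two different parcels of an integer label
volume increment that edge's count; counts below 0.001 of the total matrix
sum are zeroed, and the matrix is divided by its maximum ("fixed density"
here is the deterministic consequence of the sum threshold — no density
value is asserted). Any integer label volume is accepted; anatomical
atlases are out of scope and toy parcellations are supplied by the phantom
module.

The nine global measures use the weighted conventions standard for brain
networks whose weights encode connection strength:

* clustering / transitivity: Onnela geometric-mean triangle intensity
  (weights scaled by the matrix maximum); nodes of binary degree < 2
  contribute 0;
* path metrics on edge lengths \(1/w\): characteristic path length
  averages over connected ordered pairs, disconnected pairs contribute 0
  to global efficiency, and radius/diameter are eccentricity extremes over
  the largest connected component — all choices that avoid infinities and
  are logged when triggered;
* local efficiency: mean over nodes of the neighborhood subgraph's global
  efficiency;
* assortativity: Pearson correlation of node strengths across edge
  endpoints (both orientations), flagged undefined when strength variance
  is zero, e.g. on regular lattices;
* small-worldness: \((C/C_{\mathrm{rand}})/(L/L_{\mathrm{rand}})\) against
  degree-preserving (Maslov–Sneppen) rewired nulls with the original
  weights shuffled onto the rewired edges; 20 nulls and 10 swaps per edge
  by default. Degree preservation is asserted on every rewire.

Open conventions — whether the 0.001 threshold is against the whole-matrix
sum or a row sum, and whether path lengths use \(1/w\) — are implemented as
the stated defaults and flagged here rather than presented as settled.

## The synthetic-data generators

**Phantoms.** `make_phantom()` lays disjoint boxes of diagonal tensors:
each fiber region puts its parallel eigenvalue on its fiber axis, and a
perivascular boost `g` (in 10⁻³ mm²/s) is added to `Dxx` everywhere in the
region. The default phantom is 24 × 24 × 12 voxels at 2 mm — a desk-scale
stand-in for a 120 × 120 acquisition matrix — with left/right symmetric
subcortical (x), projection (z) and association (y) boxes along one
mediolateral line, white-matter-like eigenvalues (1.4, 0.4, 0.4) · 10⁻³
mm²/s and isotropic background 0.8 · 10⁻³ (physiologic orders of
magnitude). Its ground-truth index is \((0.4+g)/0.4\) in closed form: 1.5
at the default g = 0.2. `simulate_dwi()` applies the mono-exponential
forward model \(S = S_0 e^{-b\,g^\top D g}\) over a deterministic
32-direction b = 1000 s/mm² Fibonacci-hemisphere scheme with one b = 0
volume, and adds Rician noise (Gaussian perturbations of two quadrature
channels, scale \(S_0/\mathrm{snr}\)) — the standard magnitude-MRI noise
model. The phantoms emulate orientation geometry and noise, **not**
anatomy: no crossing fibers, no partial volume, no distortion, no T2/TE
signal dependence. Passing tests therefore demonstrate correctness of the
computations, not clinical validity on real brains.

**Cohorts.** `make_cohort()` draws each group from a Gaussian copula:
latent standard normals correlated by the target matrix, pushed through
per-variable marginal quantile transforms. The default spec is a
109-patient / 88-control study: ages 38.2 ± 19.0 vs 41.5 ± 16.6 years
(truncated below 1 year so ages stay positive), male proportions
0.532/0.534, DTI marginals (e.g. FA 0.352 ± 0.048 vs 0.339 ± 0.012) and
graph-metric marginals at published scale, and the index at 1.67/1.68. No
dispersion for the index is published, so its SD is fixed once at 0.18 — a
typical cohort spread for this statistic. Clinical variables reported only
as median (IQR) are modelled as: onset age, truncated normal (35.5, 24);
days from first seizure to MRI, log-normal (meanlog log 105, sdlog 1.84,
matching the reported IQR span on the log scale); seizure count, Poisson
(2.5). The correlation matrix is an "arrowhead": each variable's target
correlation with the index on the first row/column, other off-diagonals
zero — verified positive semidefinite (the index correlations' squared sum
is < 1). Normal marginals reproduce latent Pearson correlations exactly;
monotone transforms preserve them to first order (age truncation
attenuates the age–index correlation by roughly 0.005, well inside the
generator's Monte-Carlo tolerance). The generator does not enforce the
algebraic identity MD = (AD + 2 RD)/3 across the drawn columns; variables
are statistically, not physically, coupled.

## Statistics layer

Continuous group comparisons use the pooled-variance Student's t-test
(Welch by config flag, with the choice recorded); categorical comparisons
use Pearson's chi-square without continuity correction (appropriate at
these group sizes; expected cells < 5 warn, < 1 error). Mean ± SD versus
median (IQR) presentation is routed by Shapiro–Wilk at 0.05 — the
presentation rule is standard but the routing test had to be fixed by us.
Pearson correlations report two-tailed p from the exact t transform with
n − 2 df. Bonferroni thresholds are α/m, kept raw for significance flags
and *also* truncated (floored) to three decimals for presentation —
0.05/4 → 0.012 and 0.05/9 → 0.005 — because that is how such thresholds
are printed. `build_report()` assembles the demographic table, the m = 4
DTI family, the m = 9 graph family and the per-group index correlation
table with deterministic ordering; it is a pure function of the cohort and
config.

## Numerical and design choices

* Units: tensors in 10⁻³ mm²/s, b-values in s/mm², world coordinates in mm
  from the grid origin corner, voxel indices 0-based, boxes half-open.
  The axis convention x = left–right, y = anterior–posterior,
  z = head–foot is metadata on every geometry.
* Determinism: every stochastic operation takes an explicit seed;
  identical seed + config yields bit-identical outputs, including the
  command-line stages' files (logs carry no timestamps).
* Tie-breaks are total and documented: axis ties x < y < z, voxel ties
  lexicographic, modal ties by axis order.
* Degenerate inputs have defined behaviour: FA of the zero tensor is 0,
  empty tractograms yield a zero matrix without division by zero,
  assortativity on zero-variance strengths is flagged rather than NaN.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations run at desk scale chosen
once as representative: the 24 × 24 × 12 default phantom, 100 random SPD
tensors for the fit oracle, 50 random ≤ 8-node graphs against brute-force
enumeration, 200 noisy-phantom replicates for index robustness, and 500
replicate cohorts for correlation recovery and the null family-wise error
rate. At these sizes the entire suite completes in a few minutes on one
CPU.

## Known limitations

* Phantoms are piecewise-constant diagonal tensor fields; there is no
  crossing-fiber or partial-volume structure, so tractography is only
  exercised in regimes where its contracts (length filter, angular
  threshold, straight-field fidelity) are unambiguous.
* The index's noise floor is set by its construction from four
  single-voxel tensor elements: at snr = 50 its coefficient of variation
  on the default phantom is below 5%, but single-voxel sampling means
  robustness degrades quickly below snr ≈ 30.
* ROI placement on real anatomy (atlas registration) is out of scope; ROI
  boxes are explicit voxel coordinates.
* The cohort generator reproduces marginals and pairwise correlations
  with the index, not the full joint dependence structure of real
  imaging-derived variables.
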