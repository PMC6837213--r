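---
title: "Trabecular morphometry and phylogenetic comparative methods in musteloTrab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular morphometry and phylogenetic comparative methods in musteloTrab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musteloTrab)
```

`musteloTrab` quantifies epiphyseal trabecular bone architecture in cubic
volumes of interest (VOIs) from micro-CT stacks and relates those
parameters to locomotor habit across species in a phylogenetic framework.
This vignette is the package's own account of the methods: the models and
their assumptions, the tunable parameters, the numerical choices made where
the design was genuinely open, and what the synthetic-data tests do and do
not establish about real data.

## Volume handling and VOI extraction

Volumes follow a fixed anatomical axis convention: array axis 1 runs
proximal to distal (the slice order of an oriented scan export), axis 2 is
the image vertical, and axis 3 the image horizontal with the anterior face
at low indices.  Left bones are mirrored (axis 3 reversed) to make them
comparable with right bones; the side flag prevents accidental double
mirroring.  Plain TIFF carries no spatial calibration in the writer
available here, so the voxel spacing (µm) must accompany TIFF reads; the
raw+JSON dialect is self-describing.  DICOM series are not read directly —
no DICOM reader is among the package's dependencies — and should be
converted to one of the supported formats.

VOI placement is landmark-driven and deliberately non-interactive: each
articular structure (humeral head, humeral trochlea, femoral head, femoral
lateral condyle) has a required set of named landmarks; the VOI centre is
the mid-slice between the proximal-most and distal-most landmarks and the
in-plane midpoint of the landmark bounding box, with `.5` midpoints rounded
down for determinism.  The "as large as possible without cortical bone"
rule is operationalised against an explicit trabecular-compartment mask:
the cube grows symmetrically (odd edges, exactly centred) until a face
would leave the mask.  Edges below 16 voxels are rejected as unusable —
such VOIs contain only a few trabeculae and their parameters are dominated
by sampling noise.

## Binary morphometry

**Thresholding and purification.** The default global threshold is Otsu's
between-class variance maximiser over a 256-bin histogram; the strategy is
recorded in the output, and a fixed threshold can be substituted.  The
original study's thresholding routine is a named but unpublished heuristic,
so reproducibility was preferred over fidelity to it.  Purification keeps
the largest 26-connected foreground component and fills enclosed cavities
(largest 6-connected background component kept), the standard connectivity
duality.

**BV/TV, Tb.Th, Tb.Sp.** Bone fraction is voxel counting.  Local thickness
follows the model-independent maximal-inscribed-sphere definition: the
thickness at a voxel is the diameter of the largest sphere containing it
that fits entirely in the phase, computed from the exact Euclidean distance
transform with dominance pruning of sphere centres (a centre whose sphere
lies inside a neighbour's sphere cannot contribute).  Separation is the
same computation on the background of the purified volume.  Distances are
measured between voxel centres, so both metrics carry a discretisation
uncertainty of about one voxel; VOI-boundary regions inflate the estimate
slightly because the nearest opposite-phase voxel may lie outside the
volume.  Phantom tests accordingly assert agreement within one voxel.

**Connectivity.** `Conn = 1 − χ`, with the Euler characteristic computed
exactly on the cubical complex of the purified object
(`χ = V − E + F − C`).  After purification the object has one component and
no cavities, so `1 − χ` is the first Betti number — the number of redundant
connections, roughly the number of trabeculae.  The object is treated as
free-standing; no edge correction for structures cut by the VOI boundary is
applied, which biases `Conn.D` slightly for real VOIs whose network
continues beyond the cube.  An independent integral-geometry implementation
(scikit-image) is used as the oracle in tests.

**Bone surface.** BS uses Cauchy–Crofton stereology, the classical unbiased
surface estimator of bone histomorphometry: a quasi-uniform set of
directions (Fibonacci lattice) each carries a randomly offset parallel grid
of test lines, and `S_V = 2 P_L` converts boundary intersections per unit
test-line length into surface per unit volume.  Counting intersections on
the raw binary boundary would measure the voxelised staircase (up to 1.5×
the smooth area), so the indicator is zero-padded, smoothed with a narrow
Gaussian (σ = 0.6 voxels) and intersections are counted on the trilinearly
interpolated 0.5 level set — the same surface a marching-cubes
triangulation would approximate.  σ = 0.6 keeps digitised spheres and boxes
within 3% of their closed forms while leaving struts ≥ 2 voxels intact;
thinner structures can be lost, but such structures fail the resolution
quality check anyway.

**Fabric tensor and anisotropy.** The mean intercept length
`MIL(ω) = (total test-line length)/(boundary crossings)` is measured with
the same line machinery (nearest-voxel sampling; 2000 directions, 1-voxel
line spacing and 0.5-voxel steps by default; the per-direction grid offset
is seeded).  The MIL ellipsoid is fitted by linear least squares on
`1/MIL²`; its eigenvalues (semi-axes, sorted descending) and eigenvectors
summarise the directional structure.  Directions without crossings — e.g.
in-plane directions of a plate stack — have effectively unbounded MIL; the
corresponding semi-axes are capped at the volume diagonal rather than
failing, so perfectly layered structures report `DA → 1`.
`DA = 1 − λ_min/λ_max` is bounded in [0, 1] (0 isotropic, 1 fully
oriented); this convention matches the value range reported for mammalian
epiphyses, unlike the older unbounded `λ_max/λ_min`.  The first eigenvector
is reported in anatomical components (x anterior, y vertical,
z proximodistal), normalised to the upper hemisphere (ties broken toward
positive anterior), and converted to MDT angles (θ from the proximodistal
axis, φ from the anterior axis).  For GRF phantoms no closed-form MIL
exists, so anisotropy is validated ordinally: DA increases monotonically
with the stretch of the correlation length along one axis.

**Quality control.** The relative resolution check (mean Tb.Th divided by
voxel spacing) must reach 5 pixels per trabecula; repeatability is
summarised as per-parameter coefficients of variation across repeated
acquisitions, with jittered re-extraction of a phantom keeping the mean CV
below 5%.

## Phylogenetic machinery

The Brownian covariance `C` of a timetree has entries equal to shared
root-to-ancestor path lengths.  Pagel's λ multiplies the off-diagonal
entries (equivalent to internal-branch rescaling on ultrametric trees).  λ
is estimated by profiling the multivariate-normal GLS likelihood over an
unconstrained λ ∈ [−0.5, 1.5] (golden-section/parabolic search, tolerance
1e-6; non-positive-definite covariances score −∞), then clamped to [0, 1]:
negative optima are forced to 0 and optima above 1 to 1.  ML is the default
(REML is available); ML keeps the λ criterion consistent with the
likelihood used elsewhere in the package, though the original tooling's
default is REML — at the study's sample sizes the difference is well inside
the estimator's sampling variability.  The implementation is cross-checked
against `nlme::gls` with `ape::corPagel` in the test suite.

RRPP linear models whiten the data by `C_λ^{-1/2}` (eigen square root;
eigenvalues below 1e-10 of the maximum raise an error rather than being
pseudo-inverted), compute F and R² from full vs reduced OLS fits on the
whitened data, and obtain p-values by permuting reduced-model residuals
(seeded; default 999 permutations plus the observed case, so the smallest
attainable p is 1/1000).  With `C = I` the observed F equals the classical
ANOVA F to machine precision.  Pairwise contrasts are distances between
least-squares group means (covariates held at their means) under the same
residual-permutation schedule; groups with fewer than two members are
flagged and given missing p-values.

**Species vs specimens.** Conspecific specimens are averaged to species
values before any phylogenetic fit (the tree has one tip per species);
specimen-level values are kept for descriptive tables and ratios.  This is
the conservative default where the original handling is unstated.

## The comparative chain

`BMsp`, the specimen body-mass proxy (natural log of grams), is predicted
from a λ-optimised phylogenetic regression of ln species mean mass on ln
species mean VOI total volume, evaluated at each specimen's own TV.  The
ln–ln form is used because mass and volume are expected to scale linearly
on the log scale with slope ≈ 1, and the simulation tests recover that
slope.

Each parameter is first screened for size dependence: an RRPP regression on
BMsp under the λ-rescaled covariance (λ fitted on that size model and
clamped).  If significant at α (default 0.05), the omnibus locomotor-type
test includes BMsp as a covariate (ANCOVA); otherwise a plain phylogenetic
ANOVA is used.  `α = 1` and `α = 0` force the two routes, which pins the
routing contract in tests.  Residuals of the size regression are exported
for "size-corrected" plotting only — inference always comes from the
permutation fits.

Phylogenetic PCA removes the GLS phylogenetic mean, forms the evolutionary
covariance `R = Xcᵀ C⁻¹ Xc/(n − 1)`, and eigen-decomposes its correlation
form by default (the input variables mix ln g, mm, mm⁻³ and mm² units);
`BMsp` is included as a variable.  Eigenvector signs follow a deterministic
convention (largest-magnitude loading positive).  On a star phylogeny the
result equals ordinary PCA, which the tests assert to 1e-8, and the full
computation is cross-checked against an independent implementation.

The association between locomotor types and the phylogeny itself is
measured by two-block partial least squares: block 1 is the dummy-coded
habit matrix, block 2 a phylogeny representation, by default the matrix
square root of `C` — each species described by its expected
Brownian-motion covariance profile, which is where the BM assumption
enters.  Both blocks are column-centred and the first singular pair of
their cross-covariance gives rPLS; significance comes from seeded row
permutations of the phylogeny block.  The blocks are deliberately *not*
whitened by `C^{-1/2}`: whitening an already full-rank phylogeny
representation produces an orthogonal basis of the whole tip space, and the
first singular pair is then perfectly correlated for *any* grouping
(rPLS ≡ 1), a degenerate statistic.  The exact block construction behind
the published analysis is not recoverable; this choice is recorded in the
output metadata.

## Character evolution

Ancestral states for the (unordered, four-state) locomotor habit are
reconstructed by uniform-cost Sankoff dynamic programming with an up-pass,
which yields exact most-parsimonious-reconstruction state sets per node —
equivalent to two-pass Fitch but with ambiguity reported rather than
silently resolved.  Transition counting uses one deterministic MPR: ties
resolve to the parent's state when optimal, else to the lexicographically
smallest state; a "reversal" is any branch whose child state is fossorial
with a non-fossorial parent.  The retention index is
`RI = (g − s)/(g − m)` with `m = (observed states − 1)` and
`g = tips − max state frequency`.

The equal-rates Mk model is fitted by Felsenstein pruning with a uniform
root prior (the conventional default) and a bounded 1-D ML search
(tolerance 1e-8); the pruning likelihood is verified against exhaustive
enumeration over all internal-state assignments on five-tip trees.
Stochastic maps draw node states root-down from their conditional
distributions and simulate branch histories conditional on endpoints by
rejection sampling with a bounded number of attempts (200 per branch draw;
on exhaustion the node draw is resampled and logged — this occurs on well
under 1% of branch draws at the fitted mustelid rate).  Node posteriors are
frequencies across maps; mean change counts always dominate the parsimony
minimum.

## The shipped mustelid inputs

The locomotor-type table of the 29 sampled species (7 fossorial, 9
generalized, 6 natatorial, 7 scansorial) ships with the package.  The
published timetree cannot be redistributed, so `mustelid_tree()` returns a
**synthetic stand-in**: a topology assembled from accepted musteloid
systematics — Taxidiinae basal, then Mellivorinae, Melinae, Helictidinae,
Guloninae (with *Eira* sister to *Gulo* + *Pekania* + *Martes*), and
Ictonychinae sister to Lutrinae + Mustelinae — with Grafen branch lengths
rescaled to a plausible 16.5 Ma crown age.  Quantities that depend only on
the topology are meaningful on it: the habit character maps with 6
parsimony steps (five gains of non-fossorial habits and one reversal to
fossoriality) and RI = 14/17 ≈ 0.82.  Quantities that depend on branch
lengths (the Mk rate, node posteriors, rPLS magnitude) are computed the
same way a user would on the real timetree but should be read as
illustrative.

## The synthetic study and what the tests show

`make_synthetic_study()` generates the study design: a pure-birth 29-tip
tree (unit height), locomotor types assigned as contiguous blocks of
7/9/6/7 along the cladewise tip order — emulating the strong phylogenetic
aggregation of habits in the real clade — 35 specimens (six species
sampled twice), four VOI types, a BV/TV-like focal trait simulated under
Brownian motion with λ = 0.8 and a +2 sd natatorial effect, TV from a
lognormal size axis, and species masses from
`ln mass = 2 + 1·ln TV + BM noise (sd 0.2)`.  These defaults are the study
conditions; they are not tuned per test.

On 50 replicates of that design the pipeline routes BV/TV to the ANOVA arm
(no size effect simulated) in 94% of runs, detects the natatorial effect —
a significant omnibus type effect with natatorial separated from at least
one other type in the pairwise table — with power 0.92–0.94, and recovers
λ with mean ≈ 0.68.  Two properties of clade-aligned effects are worth
stating plainly: the phylogenetic correction absorbs part of a group
effect that coincides with a clade, so *full* three-way separation of the
natatorial group is much rarer (≈ 0.5) than detection; and ML λ̂ at n = 29
has large sampling variance (quartiles roughly 0.5–0.85 under a true 0.8),
so only its average is a meaningful recovery check.  RRPP type-I error on
null data with the correct covariance is 0.046 over 500 datasets × 999
permutations.

The synthetic volumes and trait tables validate correctness of the
algorithms, not biological realism: phantoms have ideal geometry and no
scan noise, partial-volume blur, or segmentation error; the trait generator
draws from the exact model class the estimators assume.  Passing tests
therefore demonstrate that the implementations compute their definitions
correctly and are calibrated under their assumptions — not that those
assumptions hold for any particular scan or clade.

## Problem sizes and determinism

Test and acceptance computations use phantom edges of 120–130 voxels for
the closed-form morphometry, 200–300 fabric directions with 2-voxel line
spacing and 1-voxel steps (the defaults — 2000 directions, 1-voxel spacing,
0.5-voxel steps — are for production analyses), 500 null datasets for the
type-I calibration, and 50 replicates for recovery checks.  Every
stochastic component (line-grid offsets, permutation schedules, simulation
draws) is seeded, and identical inputs plus seed give bit-identical
outputs.

## Known limitations

* No DICOM reader; no automatic cortical/trabecular segmentation — the
  compartment mask is an explicit input, replacing a visual stopping rule
  that is not recoverable from the published description.
* No Euler-characteristic edge correction for boundary-cut networks.
* The surface estimator's pre-smoothing can erase structures thinner than
  about two voxels (below the resolution QC threshold in any case).
* Mk is equal-rates only; no all-rates-different or ordered models, no
  Bayesian rate integration, no OU or multivariate-λ trait models.
* The shipped tree is a synthetic stand-in; analyses of real data should
  supply the appropriate published timetree.
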