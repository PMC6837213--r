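# musteloTrab

Trabecular bone architecture of long-bone epiphyses, and its relation to
locomotor habit across species, in one tested R pipeline.

Epiphyseal trabecular (spongy) bone remodels in response to mechanical
load, so its architecture is a candidate signal of locomotor specialisation
— digging, swimming, climbing — in clades such as mustelids where those
habits evolved repeatedly.  `musteloTrab` covers the whole chain from
micro-CT image stacks to phylogenetic inference:

* **Volumes** — read oriented TIFF stacks / raw+JSON volumes, mirror left
  bones, and extract the largest cubic volume of interest (VOI) centred in
  an articular structure from landmark files, growing the cube until it
  would leave the trabecular compartment mask.
* **Morphometry** on a binary VOI (foreground = bone, spacing in µm):
  - bone fraction `BV/TV`, total volume `TV` (mm³);
  - trabecular thickness `Tb.Th` and separation `Tb.Sp` (mm) by the
    model-independent maximal-inscribed-sphere definition
    (per-voxel thickness = diameter of the largest sphere containing the
    voxel that fits in the phase);
  - connectivity `Conn = 1 − χ` from the Euler characteristic of the
    purified network and connectivity density `Conn.D` (mm⁻³);
  - bone surface `BS` (mm²) by Cauchy–Crofton stereology,
    `S_V = 2 P_L` with intersections counted on a seeded quasi-uniform
    grid of test lines against the smoothed 0.5 level set;
  - the mean-intercept-length (MIL) fabric tensor: `MIL(ω)` over ≥ 2000
    directions, ellipsoid fitted by least squares on `1/MIL²`, giving the
    degree of anisotropy `DA = 1 − λ_min/λ_max ∈ [0, 1]`, the main
    trabecular direction (MDT, as the first eigenvector and as angles), and
    the quality check "relative resolution ≥ 5 pixels/trabecula".
* **Phylogenetic machinery** — Brownian covariance `C` from a timetree,
  Pagel's λ transform (off-diagonals × λ), ML/REML λ estimation by profile
  GLS likelihood with the clamping rule (λ̂ < 0 → 0, λ̂ > 1 → 1), and
  residual-randomisation permutation (RRPP) linear models: data whitened by
  `C_λ^{-1/2}`, F from full vs reduced OLS fits, p from permuting
  reduced-model residuals, plus pairwise least-squares-mean contrasts.
* **Comparative pipeline** — specimen body-mass estimation `BMsp` (ln g)
  from a phylogenetic ln-mass ~ ln-TV regression; per-parameter size screen
  routing to ANCOVA (size-correlated) or ANOVA; inter-limb ratios
  (humeral/femoral head; trochlea/lateral condyle); descriptive group
  summaries; phylogenetic PCA on the evolutionary correlation matrix; and
  two-block PLS between locomotor types and a phylogeny block.
* **Character evolution** — exact parsimony ancestral states (uniform-cost
  Sankoff with up-pass, equivalent to Fitch) with transition counts and the
  retention index `RI = (g − s)/(g − m)`; equal-rates Mk ML fitting by
  Felsenstein pruning; stochastic character mapping with node posterior
  probabilities.
* **Synthetic data** — binary phantoms with analytic ground truth (plate
  stacks, rod lattices, balls, wireframe cubes, anisotropic Gaussian random
  fields) and a full synthetic comparative study (29 species, 4 locomotor
  types, 4 VOI types, configurable λ and group effects), so every stage is
  testable without scan data.

The package ships the locomotor-type table of the 29 sampled mustelid
species and a clearly-labelled *synthetic stand-in* topology following
accepted musteloid systematics (`mustelid_tree()`, `mustelid_habits()`);
topology-dependent results (parsimony steps, RI) are meaningful on it,
branch-length-dependent ones are illustrative only.

## Worked example

Morphometry of a three-axis rod lattice (period 10, width 3 voxels,
20 µm voxels — analytic BV/TV = 3·0.3² − 2·0.3³ = 0.216):

```r
library(musteloTrab)
ph <- make_phantom("rod_lattice", size = 60, spacing = 20, period = 10, width = 3)
m  <- trabecular_metrics(purify(ph$vol), n_directions = 300,
                         line_spacing = 2, step = 1, seed = 1)
round(m[, c("DA", "BVTV", "TbTh", "TbSp", "Conn", "ConnD", "BS", "rel_res")], 4)
#>       DA  BVTV   TbTh   TbSp Conn    ConnD      BS rel_res
#> x 0.0056 0.216 0.0945 0.2235  325 188.0787 17.9978  4.7248
```

`BVTV` reproduces the closed form exactly; `DA ≈ 0` reflects the lattice's
cubic symmetry; `Tb.Th` ≈ 0.09 mm is the rod width (3 voxels × 20 µm, plus
the node thickening where rods cross); `Conn = 325` counts the lattice's
redundant connections; `rel_res < 5` correctly flags that 3-voxel struts
are below the 5 pixels/trabecula quality threshold.

Locomotor-type history on the shipped stand-in topology:

```r
tr     <- mustelid_tree()
states <- setNames(mustelid_habits()$habit, mustelid_habits()$species)
fitch_parsimony(tr, states)
#> Parsimony reconstruction: 6 step(s), 6 transition branch(es), ambiguous MPR sets present
retention_index(tr, states)
#> [1] 0.8235294
phylo_two_block_pls(dummy_code(states), phylo_block(tr), tr, seed = 1)$rPLS
#> [1] 0.9036985
```

Six parsimony steps decompose into five gains of non-fossorial habits plus
one reversal to fossoriality, and the high RI / rPLS quantify how strongly
the habits aggregate within the phylogeny.

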