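---
title: "Models and methods behind osteoqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind osteoqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices behind
`osteoqtl`: what each stage computes, which parameters matter, what the
synthetic generators do and do not emulate, and where the design was
genuinely open. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## 1. The study design the package implements

The package implements a phenotype-to-genotype pipeline for cortical bone
microstructure: 3D morphometry of osteocyte lacunae, vascular canals and the
cortical shell from tomographic volumes, followed by QTL mapping of the
resulting phenotypes in an F2 intercross between two inbred strains. The
canonical cohort the defaults mirror is 755 genotyped F2 animals and 12 F1
animals (47% male), genotyped at 98 microsatellite markers across the 19
autosomes, with genotype probabilities on a 2 cM grid, extended Haley–Knott
scans with sex as an interactive covariate, permutation-derived thresholds
and penalties at a 5% genome-wide level, penalized stepwise model search,
and 0.1 cM position refinement. All of it runs on synthetic phantoms and
simulated crosses with known ground truth, so correctness is testable
end-to-end.

## 2. Synthetic phantoms

`generate_phantom()` rasterises a hollow circular shell (optionally with an
eccentric bore) containing solid ellipsoidal lacunae and straight Z-parallel
canal tubes, by the centre-of-voxel inclusion test; the physical coordinate
of array index `i` is `(i − 0.5) · voxel_size`. Defaults: outer radius 40 and
inner radius 30 voxels, height 60, fifty `(5, 2, 2)`-voxel lacunae with
random orientations, two canals of radius 3, bone/pore grayscale 200/20, and
a 1.4 µm voxel — a scaled-down analogue of synchrotron scans of the mouse
femur mid-diaphysis (a full field of view would be ~1000³ voxels; the phantom
keeps the same geometry at a size where whole-pipeline tests run in seconds).

Placement uses ellipsoid *support functions* (separating-slab tests), so an
elongated lacuna may sit tangentially inside a wall thinner than its long
axis: containment requires the support-adjusted distance to both shell
boundaries to clear a ~1–1.5 voxel margin (the inner margin is 1.5 voxels so
that no pore can become 26-connected to the medullary cavity), and Poisson
placement rejects candidates whose separating-slab gap to any placed lacuna
is below 2 voxels. Canals keep a 1.5-voxel clearance from both boundaries.
Lattice placement puts lacunae on a regular grid and keeps a compact cluster
of admissible sites; it exists to plant known spatial anisotropy. One master
seed drives deterministic sub-streams per purpose (canals, lacunae,
orientations, noise), so identical specifications are bit-identical.

Not emulated: X-ray physics (phase contrast, beam hardening, rings), curved
or branching canal networks, trabecular bone, non-ellipsoidal lacunae,
partial-volume blur. Segmentation results on phantoms therefore bound what
the pipeline can do on ideal data; they do not certify performance on real
scans with reconstruction artifacts.

## 3. Segmentation and labeling

`segment_phases()` thresholds the volume (fixed value or Otsu on the global
histogram, 256 levels), fills the bone mask's internal cavities slice by
slice in 2D, and calls enclosed non-bone voxels pore. A slice-wise fill
necessarily also fills the medullary bore of a closed shell, so the package
applies the standard cortical-porosity convention: any enclosed component
larger than `medullary_min_fraction` (default 5%) of the filled shell is the
medullary cavity and is assigned to background. The 2D-fill choice is
deliberate: Z-parallel canals are open at the axial faces and a 3D flood from
the border would classify them as background.

`label_components()` takes 26-connected components of the pore phase and
classifies them by volume alone: within the lacuna range → lacuna, at or
above the canal minimum → canal, otherwise speckle. Defaults (50–1000 voxels
for lacunae, ≥1500 voxels for canals, at the 1.4 µm voxel) are chosen so the
default phantom's objects fall squarely inside their classes; both are
plain parameters, and classification requires the ranges to be disjoint.
Components touching the volume border are flagged: they count toward number
densities (their existence is certain) but are excluded from shape metrics
(their shapes are clipped); `include_border = TRUE` flips the exclusion.

## 4. Morphometry

**Shape.** For each object, principal half-lengths are
`L_i = sqrt(5 λ_i)` with `λ_i` the eigenvalues of the voxel-coordinate
covariance — exact for a uniform solid ellipsoid. Each voxel contributes its
own cubic second moment (1/12 per axis), which keeps single-voxel objects at
`L = sqrt(5/12) ≈ 0.65` voxels instead of zero (such objects are flagged
degenerate and given stretch 0). Stretch `1 − L3/L1` hits the required
endpoints: 0 for a sphere, →1 both for extreme rods (`a ≫ b = c`) and
extreme plates (`a = b ≫ c`).

**Distribution oblateness.** For each lacuna centroid, displacement vectors
to its `k` nearest neighbours (default `k = 6`) are accumulated into a 3×3
second-moment tensor; all neighbours tied at the k-th distance are included,
which keeps the estimator symmetric on regular lattices (index-order
tie-breaking demonstrably biases a cubic lattice). With eigenvalues
`μ1 ≥ μ2 ≥ μ3`,

`Ob = 1 − 2 (μ2 − μ3) / (μ1 − μ3)`.

Lacunae packed closely in two orthogonal directions (prolate spacing) give a
pancake-shaped displacement tensor (`μ1 ≈ μ2 ≫ μ3`) and `Ob → −1`; lacunae
close in only one direction (oblate spacing) give a cigar-shaped tensor and
`Ob → +1`. If `(μ1 − μ3)/μ1 < 0.05` the distribution is reported isotropic
with `Ob = 0`. The anisotropy sign is meaningful only when the point set's
extent along its close direction(s) is large relative to the far spacing;
on small clusters the tensor mixes planted spacing with cluster-edge
geometry.

**Radial cortical thickness.** Per Z slice, rays are cast from the
bone-phase centroid at `n_theta_bins` equally spaced angles (default 360;
the estimate is stable from ~16 bins on a regular shell). The mask is
sampled every 0.25 voxel with bilinear interpolation and crossings taken at
the 0.5 level, refined linearly between samples; thickness is outermost
minus innermost crossing. The mean and SD pool all valid (angle, slice) bins
with equal weight — weighted by angle rather than volume, so thick sectors
are not over-represented. By default intracortical pores count as bone (the
shell envelope); `solid_thickness = TRUE` restricts the mask to calcified
bone. Bins with no crossing are skipped with a warning; if more than half
the bins are invalid the shell is declared not closed and the call errors.
Whether to pool bins across slices before or after angular averaging is not
dictated by the phenotype's definition; this implementation pools all
(angle, slice) bins, which weights every slice equally when all bins are
valid.

## 5. Cross simulation

Gametes are Markov walks along each chromosome under the Haldane map
function `r = (1 − e^(−2d/100))/2` (no crossover interference); an F2
genotype is the union of two independent gametes. The Haldane choice matches
the downstream HMM's Markov assumption exactly, so HMM correctness is
testable against enumeration. The default synthetic map is a stand-in for a
mouse microsatellite panel: 19 autosomes with lengths declining 100→50 cM,
98 markers allocated proportionally and evenly spaced. Phenotypes follow

`y = Σ_q (a_q x_q + d_q z_q) + Σ interactions + sex_effect · male + ε`,

with `x ∈ {−1, 0, +1}`, `z = 1` for heterozygotes,
`ε ~ N(0, env_sd²)`; planted QTL may sit between markers (the simulator
walks through their true positions). F1 phenotypes carry only the
environmental term. Sex is Bernoulli with a 47% male fraction; marker
missingness defaults to 2%, a typical microsatellite panel failure rate.
Not simulated: the X chromosome, crossover interference, genotyping errors
beyond missingness, segregation distortion.

## 6. Genotype probabilities

Per chromosome, a forward–backward pass over the three-state F2 chain
(prior ¼, ½, ¼; transitions from Haldane `r` applied to both gametes;
emissions `1 − e` for the observed code and `e/2` otherwise, uniform for
missing; default `e = 10⁻⁴`) yields smoothed probabilities on the union of
the marker positions and a regular grid (default 2 cM). Rows are normalised
at each step, which leaves posteriors exact. Posterior *path* draws (backward
sampling; the convention is 128 when imputation is wanted) feed the optional
imputation scan `scan_one_imp()`; they cannot improve the smoothed
probabilities themselves, so the default scan uses the probabilities
directly and the draws exist as a companion method.

## 7. Scans, thresholds, penalties, model search

**Extended Haley–Knott.** At each position the full model regresses `y` on
covariates plus the expected scores `x̂ = P(BB) − P(AA)`, `ẑ = P(AB)` — plus
`x̂·sex`, `ẑ·sex` in interactive mode — with per-individual residual variance
`σ² + v_i`, where `v_i = a_i² Var(x_i) + d_i² Var(z_i) + 2 a_i d_i Cov` is the
genotype-posterior variance of the genetic predictor. The fit iterates
weighted least squares with a fixed-point update for σ² and stops when the
relative log-likelihood change is below 10⁻⁸ (cap 50 iterations); the
likelihood is also evaluated at the null-nested point, so `LOD ≥ 0` holds by
construction. At fully typed markers `v_i = 0` and the extended fit
coincides with plain Haley–Knott, which in turn equals the three-group
ANOVA `LOD = (n/2)·log10(RSS₀/RSS₁)`. A constant sex covariate is dropped
with a warning (it is confounded with the intercept, so the documented
"additive" fallback would still be singular). Rank-deficient designs are
handled by eigen-pseudo-inverse quadratic forms and a pivoted-QR projection
fallback.

**Permutations.** Thresholds are `1 − α` type-7 quantiles of genome-wide
maximum LOD over phenotype permutations, stratified within sex (sex is a
model covariate, so exchangeability holds within, not across, strata).
Penalties come from two-locus scans of permuted phenotypes over a coarse
grid (default 10 cM): `T_main` from the single-locus maxima, `T_heavy` from
(max full − max single), `T_light` from (max full − max additive); the
ordering `T_heavy ≥ T_light ≥ 0` holds per permutation because the additive
two-locus model nests the single-locus model. Permutation scans use plain
Haley–Knott regression: under permutation the design at each position (or
pair) is fixed and only the response changes, so all permutations reduce to
one set of normal equations plus a matrix product — this is what makes
1000-permutation two-locus nulls tractable — and under the null plain and
extended HK coincide at typed markers. Desk-scale runs with fewer than 1000
permutations are flagged `scaled_down` in the penalty set.

**Penalized stepwise search.** The criterion is
`pLOD = LOD − T_main·#loci − T_heavy·#heavy − T_light·#light`, where within
each connected component of the model's interaction graph one interaction
pays the heavy penalty and the rest pay light (the standard hierarchy
convention). Forward steps add whichever candidate maximises pLOD — the best
new locus from a genome scan conditional on the current model, or the best
new interaction between current loci — up to `max_qtl` loci (default 10,
matching multi-locus architectures of 2–10 loci); at the locus cap,
interactions are added only while they improve pLOD. Backward deletion then
prunes term by term to the empty model (a deleted locus takes its
interactions with it), and the best model visited on either path is
returned; if nothing beats `pLOD = 0` the result is the empty model — "no
QTL found" is a first-class outcome. Multi-locus fits use plain HK with sex
as an additive covariate; the interactive sex scheme is the single-locus
scan's, following the study procedure.

**Refinement and summaries.** `refine_positions()` recomputes probabilities
at 0.1 cM within ±10 cM of each locus and re-optimises positions one pass in
order, always including the incumbent position, so the model LOD never
decreases and a second pass moves positions by at most one step. Per-term
variance is `100·(RSS_reduced − RSS_full)/TSS` with TSS about the phenotype
mean (so values read as percent of F2 population variance), and the dropped
LOD is the corresponding likelihood-ratio change; dropping a locus removes
its interactions too. Support intervals are 1.5-LOD drops — the conventional
approximate 95% region for an intercross — clipped to chromosome ends, with
the drop as a parameter. Argmax ties resolve to the smallest chromosome
index, then the smallest position.

Interval mapping attenuates effect estimates between markers: with ~15 cM
marker spacing, a QTL planted mid-interval yields a per-QTL variance share
several points below the planted value even at n = 2000, because the
expected genotype scores shrink toward zero away from markers. The
validation studies therefore plant QTL at marker positions when the question
is attribution accuracy rather than localisation; this is a property of the
method on sparse maps, not an implementation artifact.

**Heritability.** `H² = 100 · max(0, 1 − Var(F1)/Var(F2))` (sample
variances), with phenotypes selected when H² strictly exceeds the criterion
(default 40%); a phenotype at exactly the criterion is not selected.

## 8. Problem sizes in the shipped studies

The test-suite and acceptance-script studies run at the cohort the defaults
mirror (n = 755; n = 2000 where attribution precision is the question), with
100 permutations for thresholds and penalties, 20 × 20 trials for type-I
calibration, and 40–100 replicates for recovery studies; phantoms are
87×87×60 voxels. These sizes were chosen so that each study's Monte-Carlo
error is small relative to the tolerance it is checked against while the
whole suite stays interactive.

## 9. Known limitations

- Segmentation assumes a closed shell per slice; open or fragmented
  cortices defeat the slice-fill/medullary rule.
- Classification is by volume only; merged lacuna pairs or lacunae abutting
  canals are not split (no watershed).
- The thickness estimator assumes a star-convex shell about the per-slice
  bone centroid; strongly non-convex sections would need polyline tracing.
- The oblateness score is a global summary; spatially heterogeneous packing
  is averaged away.
- The QTL chain is autosomal F2 only: no X chromosome, no composite interval
  mapping, no Bayesian multiple-QTL; multiple imputation is provided as a
  companion scan, not the primary method.
- Effect attribution on sparse maps is attenuated between markers (Section
  7); refined positions mitigate but cannot remove this.
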