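---
title: "Chromosome-walk imaging analysis and integrative modeling of genomic regions"
author: "chromotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-walk imaging analysis and integrative modeling of genomic regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromotrace)
```

## The problem

Sequential super-resolution FISH imaging ("chromosome walking") labels a
megabase-scale genomic region in consecutive segments and images each
segment as a cloud of single-molecule localization events. `chromotrace`
implements the downstream computation for such walks on a diploid human
region imaged in nine chromosomal segments (CS1–CS9, 360 kb–1.8 Mb,
8.16 Mb in total):

1. **Localization processing** — quality filtering, repeat merging,
   axial-precision filtering, fiducial drift correction, and DBSCAN
   extraction of per-segment clusters.
2. **Density maps** — Gaussian-smoothed 3D intensity grids per segment
   with an automatic iso-contour threshold.
3. **Structural statistics** — pairwise distance (DS) and entanglement
   (ES) scores, convex-hull surface area, body volume and sphericity,
   all expressed as z-scores against power-law genomic-size expectations;
   PCA classification into two compartment-like clusters; homolog
   ellipticity with a random-pair null.
4. **IMGR** (integrative modeling of genomic regions) — rigid fitting of
   Hi-C-derived bead-chain models into the imaging density maps by
   cross-correlation search, followed by flexible simulated-annealing
   refinement under harmonic restraints.
5. **Synthetic data** — a generator producing ground-truth chains,
   localization tables and contact matrices, so that every stage is
   testable end to end without external data.

## Localization processing

Each localization event carries a position, an acquisition frame, photon
counts, an axial offset and Cramér–Rao-derived precisions. The quality
rank of an event is the geometric mean of three self-normalized metrics
(PSF-to-cutout photon ratio, cutout photons, axial offset); events with
rank below 0.8 are discarded. The self-normalization is rank-based
min–max scaling per acquisition: the functional form of the
normalization is an open design point, and rank scaling was chosen
because it is invariant to the (arbitrary) units of the three raw
metrics. Note a consequence: ranks are uniform by construction, so the
0.8 cutoff retains roughly the best fifth of all events regardless of
their absolute quality — the filter is a per-acquisition triage, not an
absolute gate.

Re-detections of a single emitter — events whose lateral position stays
within 2 pixels (~100 nm/pixel) of the run's first event over at most 7
frames with no gap larger than one frame — collapse to a single event.
The merged position is the precision-weighted mean, the photon counts
are summed (the natural reading for re-fired emitters), and the merged
precision is the inverse-variance combination. Events with axial
precision worse than 100 nm are removed (boundary convention: exactly
100 nm is kept).

Drift correction estimates the fiducial-marker centre of mass in
non-overlapping 1000-frame windows, subtracts the displacement relative
to the first window with linear interpolation between window centres,
and returns the full drift trace for audit. Clustering is DBSCAN with
`eps = 150` nm; `minPts` defaults to 10 (not fixed by the source
protocol) and counts the point itself. Border points are attached to
their nearest core point with a lowest-index tie-break, which makes the
labelling deterministic and lets a brute-force density-reachability
oracle reproduce it exactly.

## Density maps and geometric descriptors

A segment's map is built by incrementing the voxel nearest to each
localization by one and convolving with an isotropic Gaussian. The
kernel is normalized to unit mass so the total intensity equals the
localization count; the printed normalization constant in the source
formula is typographically ambiguous and the unit-mass reading is the
only one that keeps maps comparable across segments. σ defaults to the
mean of the cluster's lateral and axial precisions (proportionality
constant 1; whether the original σ tracked lateral, axial or pooled
precision is not stated). Voxel size defaults to 25 nm with 5σ padding.

The iso-contour threshold is "one sigma after shifting the background
peak to zero": the background mode is located as the tallest
Freedman–Diaconis histogram bin, intensities are shifted so the mode is
zero, and the threshold is the RMS deviation of the sub-mode population
about the mode — for symmetric background noise this estimates the
background standard deviation. Maps whose histogram is degenerate (no
background, e.g. tiny dense clusters) fall back to the limiting case:
the body is every positive voxel.

Surface area is the summed triangle area of the convex hull of
above-threshold voxel centres (an incremental beneath-beyond hull,
implemented in the package; voxel clouds are prefiltered to per-column
extreme points, which provably leaves the hull unchanged). Volume is
the voxel count at or above threshold times the voxel volume.
Sphericity is `psi = pi^(1/3) (6V)^(2/3) / A`, 1 for a perfect sphere.

DS is the Euclidean distance between intensity-weighted body centres of
mass; ES is the overlapping body voxel count divided by the smaller
body. Size correction fits `value = a * size^b` by ordinary least
squares in log–log space (the estimator is not specified in the source;
OLS is the conventional choice) and returns
`z = (observed − expected) / s_res` with `s_res` the linear-scale
residual standard deviation, pooled over the population (not
distance-binned). DS and ES use the genomic separation between segment
midpoints as abscissa; area, volume and sphericity use segment length.

## Classification and homolog comparisons

The 19 z-scored features per imaged segment (8 DS-z, 8 ES-z, area-z,
volume-z, sphericity-z) are column-standardized and decomposed by PCA;
segments are partitioned by 2-means on the first two PC scores with
deterministic k-means++ initialization (the original partition ran
along PC1 but the algorithm is unnamed; seeded 2-means on PC1–2 is the
recorded choice). Cluster 1 is relabelled as the group with larger mean
volume, matching the active-like cluster's larger, less spherical
bodies. Compartment-state profiles compare the two homologs' labels per
segment (1 both in cluster 1, −1 both in cluster 2, 0 discordant) and
are clustered with average-linkage on Euclidean distances.

Homolog ellipticity fits an ellipsoid to each homolog's localizations.
The fit is the classic algebraic least-squares quadric (solve
`x'Qx + 2b'x = 1`, axes from the eigenvalues of the centred quadric)
when the points concentrate near the fitted shell, and moment-based
axes (covariance eigenvalues) otherwise. The split follows from two
measurements: moment axes are biased ~11% on area-uniform surface
samples of a 2:1:1 ellipsoid, where the algebraic fit is exact; and on
filled clouds the algebraic quadric is near-degenerate and its axes
frame-sensitive, while moment axes are exactly rotation-invariant. A
shell criterion (coefficient of variation of the quadric form < 0.5)
selects between them. The ellipticity
score is the ratio of the two largest axes, the ellipticity ratio the
larger-over-smaller ratio of the two homologs' scores, and significance
is assessed against 1,000 random cross-nucleus pairs with a two-sided
Mann–Whitney test.

A calibration caveat, measured with this package: because the random
pairs are resampled from the same score population that yields the
within-nucleus ratios, the two Mann–Whitney samples are dependent and
the test is conservative — simulated type-I error at α = 0.05 is
~0.02–0.03 for exchangeable scores (0.0475 when the null sample is
drawn from an independent population of the same distribution). The
procedure therefore understates, never overstates, significance.

## IMGR

Bead-chain models (one bead per 10-kb bin by convention; the synthetic
walk uses 40-kb beads to stay desk-sized) are derived from normalized
contact matrices by a simplified restraint transformation: log contact
frequencies are z-scored within each genomic-distance stratum; pairs
with `z >= 0.5` receive upper-bound harmonic restraints, `z <= -0.5`
lower-bound ones, with equilibrium distances interpolating linearly in
z between `2r` and a maximum distance (default `2r sqrt(n)`), and
adjacent beads always bonded at `2r`. This generator stands in for the
full restraint-based modeling package cited by the source protocol; it
exists to exercise the fitting stages, not to reproduce that tool. An
ensemble is generated by minimizing the restraint energy from random
starts (5,000 generated, best 1,000 kept, by convention).

Rigid fitting renders the bead model as a probe map (continuous
Gaussian splat at the target's σ — continuous rather than
nearest-voxel sampling so the cross-correlation is differentiable in
the pose) and scores the Pearson-form CCC over all voxels; the printed
source formula lacks the square root in its denominator as typeset and
the standard Pearson form is used. Raw CCC can be negative and is
floored at zero for scoring. 100 random placements (uniform rotation,
translation within the map box) are each locally optimized by steepest
ascent on the analytic pose gradient, coarse-to-fine: first against the
map smoothed to 2σ on a 2× downsampled grid (coil-shaped bodies have
rugged rotation landscapes at native resolution), then at native
resolution, stopping at ΔCCC < 1e-4 or 200 iterations. The connectivity
score of a fit is `ConS = 1 − d / max(d)` over the ensemble, with `d`
the distance from the terminal bead genomically adjacent to the
neighbouring segment to the interface centre of mass (body voxels
within 50 nm of the neighbour's body); bodies farther apart than the
cutoff yield a recorded no-interface signal. Fits are ranked by
`CombScore = ConS + 2 CCC` and the top 5% (pooled over the ensemble;
per-model application would also be defensible) are flagged for
refinement.

Flexible refinement perturbs user-supplied rigid bodies (automatic
domain-border partitioning is out of scope) under the composite energy
`E = W1 E_CCC + W2 (E_HLB + E_HUB + E_C) + W3 E_EV`, with `E_CCC` the
negative sum of per-body CCCs, one-sided harmonic bounds, connectivity
bonds, and a hard-sphere excluded-volume term vanishing at `2r`.
The annealing stage runs Metropolis rigid-body moves over the
prescribed temperature schedule (at most 50 cycles, heating 0→1000 K in
≤100 steps, cooling back in ≤200) — a method substitution for literal
molecular-dynamics annealing that preserves the schedule constants, the
ΔCCC tolerance and the energy model. Each body's move is displaced
along the analytic pose gradient of the composite energy (the direction
maximizing its cross-correlation while honouring the restraints), with
backtracking on overshoot and thermal noise proportional to the
temperature. Two functional adaptations were made after measuring that
the literal reading cripples the optimizer: the per-step CCC-stall
termination (change < 0.001) is evaluated on cooling steps only —
checked during heating it fires on the first, still-cold steps and the
anneal never heats — and the cycle loop runs basin-hop cycles
(each restarts from the best state so far and re-orients the
worst-correlating body; candidate orientations include 180° flips about
the body's principal axes, the typical trapped states of elongated
bodies; on alternate stalls the two worst bodies hop jointly), stopping
after `patience` (default 10) consecutive non-improving cycles instead
of one. On the perturb-and-recover experiment these changes raise the
mean bead-RMSD recovery from ~27% to ~60%. The Metropolis criterion
uses `exp(−ΔE/(kB T))` with `kB = 1e-4` energy units per kelvin
(configurable; the energy scale is arbitrary). The SA weights default
to `W1 = W2 = W3 = 1` (the source defers to an uncited default; these
are explicit configuration here). A two-stage conjugate-gradient minimization
follows (200 steps with all weights 1, 200 with `W1 = 0`), using
analytic gradients of all terms. The returned model maximizes CCC over
the per-cycle snapshots and CG results, ties broken by minimal clash
score (`CLS` = non-adjacent pairs closer than `2r`, per 1000 beads).
Force constants default to 0.01 energy/nm² (not printed in the source).

The perturb-and-recover experiments in the test suite use harmonic
bounds placed at the planted conformation's own pair distances (±1%,
pairs within 90 nm) rather than restraints derived from a contact
matrix. The reason is informational consistency: contacts of a single
conformation are binary, so the frequency-to-distance mapping assigns
its tightest equilibrium to every contact pair and the planted truth is
then not the minimum of the energy being optimized — no refinement
could be expected to return it. With truth-consistent bounds the
planted state is the global energy level, and the experiment measures
what it should: the optimizer's ability to get there. The residual
bead RMSD after refinement (~7–15 nm in these experiments) is the
identifiability floor set by the map width and the restraint slack, not
an optimization failure; a ≥50% RMSD reduction therefore requires
perturbations at least twice that floor, which the experiments' body
rotations (sd 0.5 rad) provide.

## The synthetic generator

`synthetic_nucleus()` plants the study's qualitative geometry: nine
segments tiling chr19:7,400,000–15,560,000 with the printed sizes
(360 kb–1.8 Mb; CS7 = 840 kb), two homolog chains grown as
self-avoiding fixed-bond walks through per-bead target tubes. Segments
CS3–CS7 occupy a compact core (ring radius 80 nm, tube radius 110 nm);
CS1, CS2, CS8 and CS9 sit in one shell neighbourhood ~500 nm away with
the two walk ends proximal — the arrangement in which the walk centre
is spatially separated from the ends and the ends are closer than their
genomic separation predicts. Bead targets interpolate linearly between
segment-midpoint knots so chain growth across segment boundaries stays
feasible; transition beads therefore smear between neighbouring
centres, which is also the main respect in which the generator is
easier than real data (real compartmental intervals have no target
tube, and their variability across cells is larger and structured).
Bond length is 40 nm at 40-kb resolution; homolog 2 is displaced 3 µm
so the homologs are resolvable by clustering, emulating the selection
of nuclei with distinguishable homologs.

`simulate_localizations()` draws Poisson event counts per bead (mean
30; event totals thus grow linearly with genomic segment size),
axis-wise Gaussian displacements with the reported precisions (11 nm
lateral, 47 nm axial), 5% uniform background, 5% events with axial
precision worse than 100 nm, 15% next-frame re-detections, a linear
stage drift shared with three synthetic fiducial markers, and quality
metrics driven by a latent per-event quality so the rank filter
preferentially removes background. Not emulated: blinking kinetics and
duty cycles, anisotropic/astigmatic PSF shape, fiducial loss, and
Hi-C noise structure (ligation artifacts, coverage bias) — passing
tests therefore demonstrate the correctness of the computations under
the stated statistical model, not robustness to those artifacts.

Problem sizes used by the test-suite experiments (the package's own
choice of desk scale): 20 nuclei for planted-structure recovery, a
50-bead chain for pose recovery over 20 placement seeds, a 40-bead
chain for the refinement contract, and 1,000 replicates for the null
calibration.

## Numerical choices and degenerate inputs

* Grids are x-fastest 3D arrays; the origin is the centre of voxel
  `[1,1,1]`; MRC mode-2 I/O records voxel size and origin.
* Convolution is separable with kernels truncated at 4σ (3σ in the
  coarse fitting stage) and renormalized, so mass is conserved up to
  boundary truncation.
* The hull code rejects < 4 points and coplanar/collinear inputs with a
  degenerate-geometry error; `entanglement_score` and `interface_com`
  reject empty bodies; `connectivity_score` flags the all-zero-distance
  degenerate ensemble and returns all 1s.
* 2-means ties and k-means++ draws are fixed by the caller's seed; all
  stochastic functions take explicit seeds and restore the caller's RNG
  state.
* `merge_repeats` is idempotent because merged events keep the run's
  first frame, so re-runs cannot re-chain them.

## Known limitations

* The alpha-shape overlap of the source protocol is computed on a
  dilated occupancy grid (union of 150-nm balls sampled at 25 nm), not
  an exact alpha complex; reported fractions agree with voxel counting
  semantics but not with an exact alpha-shape surface.
* Compartment assignment of real A/B tracks, Hi-C normalization and
  eigenvector calling are consumed, not computed.
* Rigid-body partitions for refinement are user input; no domain-border
  caller is included.
* The restraint generator is intentionally simplified (see above) and
  its absolute distance scale is set by `max_dist`, not calibrated to
  Hi-C counts.
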