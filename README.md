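# chromotrace

Analysis of sequential super-resolution chromosome walks and integrative
modeling of genomic regions (IMGR).

Single-molecule localization microscopy with sequential oligonucleotide
FISH ("chromosome walking") images a megabase-scale genomic region
segment by segment, producing one 3D point cloud of localization events
per chromosomal segment per homolog. `chromotrace` is for researchers
who have such data — or who want to prototype against realistic
simulations of it — and covers the full downstream computation:

* **Localization processing** — geometric-mean quality ranking of events
  (rank `(m1·m2·m3)^(1/3)`, threshold 0.8), merging of repeated
  detections (≤ 2 pixels, ≤ 7 frames), axial-precision filtering
  (≤ 100 nm), fiducial drift correction, DBSCAN clustering
  (`eps = 150` nm).
* **Density maps** — per-segment Gaussian-smoothed intensity grids
  `ρ_i = Σ_n Z exp(−|x_i − x_n|²/2σ²)` (unit-mass kernel), iso-contour
  threshold at one background sigma after shifting the background peak
  to zero; MRC/CCP4 I/O.
* **Structural statistics** — distance score DS (centre-of-mass
  distance), entanglement score ES (shared body voxels over the smaller
  body), convex-hull area, volume, and sphericity
  `ψ = π^(1/3)(6V)^(2/3)/A`; power-law size correction
  `z = (obs − a·size^b)/s_res`; PCA + 2-means compartment
  classification; compartment-state profiles (1/0/−1); homolog
  ellipticity scores and ratios with a 1,000-pair random null and
  Mann–Whitney test.
* **IMGR** — rigid fitting of contact-derived bead models into density
  maps (100 random placements, analytic-gradient steepest ascent on the
  Pearson-form CCC, `ConS = 1 − d/max(d)` connectivity,
  `CombScore = ConS + 2·CCC`, 95th-percentile selection) and flexible
  refinement (Metropolis rigid-body annealing, ≤ 50 cycles, 0→1000 K,
  ΔCCC < 0.001 stop, two-stage conjugate-gradient finish, clash score
  per 1000 beads).
* **Synthetic data** — ground-truth chains over a 9-segment, 8.16-Mb
  walk with a planted two-block geometry, simulated localization tables
  (11 nm lateral / 47 nm axial precision) and ensemble contact
  matrices.

## Worked example

Simulate one diploid nucleus, run the processing chain, and inspect the
per-segment structure:

```r
library(chromotrace)

nuc <- synthetic_nucleus(seed = 1)        # ground-truth chains, 9 segments
sim <- simulate_nucleus(seed = 1)          # localization table + fiducials
an  <- analyze_nucleus(sim$locs, sim$fiducials, nuc$segments)

ps <- pairwise_scores(an$homologs[[1]]$maps)
round(ps$ds[1:4, 1:4])
#>     CS1 CS2 CS3 CS4
#> CS1   0 124 411 600
#> CS2 124   0 337 536
#> CS3 411 337   0 213
#> CS4 600 536 213   0
```

The distance-score matrix already shows the planted arrangement: the
peripheral walk start (CS1, CS2) forms one neighbourhood (124 nm apart)
while the central segments sit hundreds of nanometres away from it and
within ~100–250 nm of each other. Classifying all segments of a
20-nucleus population recovers the planted two-block structure:

```r
ft <- zscore_features(features_of_population, walk_segments())
pc <- pca_classify(ft[, grep("_z$", names(ft))], seed = 1)
round(pc$explained_variance[1:2], 3)
#> [1] 0.430 0.199
```

Here PC1/PC2 carry 43%/20% of the variance and the 2-means labels
separate CS3–CS7 from CS1/CS2/CS8/CS9 with 100% accuracy on this
simulation.

Fitting a 50-bead model into a density map rendered at a hidden pose:

```r
chain <- make_chain(50, bond_length = 30, confinement_radius = 200,
                    seed = 7, r = 15)
tm <- render_model(chain, grid, sigma = 25)   # target map at a known pose
rf <- rigid_fit(chain, tm, n_placements = 100, seed = 1)
rf
#> rigid_fit_ensemble: 100 placements; best CCC 1.000, ConS n/a, CombScore 2.000
#>   5 fit(s) flagged for refinement (>= 95th percentile)
```

The best fit recovers the planted pose (centre-of-mass error well below
one voxel). `flexible_refine()` then relaxes the fit under the
restraint-aware composite energy.

A unified command-line entry point is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/chromotrace", package="chromotrace"))')" \
    metrics --seed 1 --out run/
```

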