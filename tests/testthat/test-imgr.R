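test_that("CCC is 1 on self, symmetric, and invariant to affine rescaling", {
  m <- blob_map(24, voxel = 20)
  expect_equal(ccc(m, m), 1, tolerance = 1e-9)

  m2 <- blob_map(24, voxel = 20, seed = 7)
  expect_equal(ccc(m, m2), ccc(m2, m), tolerance = 1e-12)

  resc <- m2
  resc$data <- 3.7 * m2$data + 0.5
  expect_equal(ccc(m, resc), ccc(m, m2), tolerance = 1e-9)

  flat <- density_map(array(1, dim = dim(m2$data)), c(0, 0, 0), 10)
  expect_error(ccc(m2, flat), "variance")

  # two independent noise maps decorrelate
  set.seed(8)
  a <- density_map(array(runif(50^3), dim = c(50, 50, 50)), c(0, 0, 0), 10)
  b <- density_map(array(runif(50^3), dim = c(50, 50, 50)), c(0, 0, 0), 10)
  expect_lt(abs(ccc(a, b)), 0.01)
})

test_that("interface COM sits on the shared face of touching cubes", {
  cube <- function(x0, xs) {
    a <- array(0, dim = c(20, 10, 10))
    a[xs, , ] <- 1
    density_map(a, c(x0, 0, 0), 10, threshold = 1)
  }
  A <- cube(0, 1:10)       # occupies x in [0, 90]
  B <- cube(0, 11:20)      # occupies x in [100, 190]
  # one-layer cutoff: the interface is the face layer itself
  com <- interface_com(A, B, cutoff = 10)
  expect_lt(abs(com[1] - 90), 5 + 1e-9)
  # 50 nm cutoff: the slab x in {50..90}, centre of mass at 70 (by hand)
  com50 <- interface_com(A, B, cutoff = 50)
  expect_equal(com50[1], 70, tolerance = 1e-9)
  expect_equal(com50[2:3], c(45, 45), tolerance = 1e-9)

  Bfar <- cube(2000, 1:10)
  expect_null(interface_com(A, Bfar, cutoff = 50))

  # enlarging the cutoff grows the interface voxel set monotonically
  ctrA <- chromotrace:::voxel_centers(A, chromotrace:::body_mask(A))
  ctrB <- chromotrace:::voxel_centers(B, chromotrace:::body_mask(B))
  dmin <- chromotrace:::cpp_min_dist(ctrA, ctrB)
  expect_gte(sum(dmin <= 100), sum(dmin <= 50))
})

test_that("connectivity scores follow 1 - d/max(d)", {
  expect_equal(connectivity_score(c(10, 20, 50)), c(0.8, 0.6, 0))
  d <- runif(20, 0, 300)
  cs <- connectivity_score(d)
  expect_equal(cs[which.max(d)], 0)
  expect_true(all(cs >= 0 & cs <= 1))
  expect_equal(connectivity_score(42), 0)  # single member is its own max
  expect_warning(z <- connectivity_score(c(0, 0)), "degenerate")
  expect_equal(z, c(1, 1))
})

test_that("restraint construction reacts to contact enrichment", {
  n <- 20
  uni <- matrix(0.2, n, n); diag(uni) <- 1
  for (d in 1:(n - 1)) for (i in 1:(n - d))
    uni[i, i + d] <- uni[i + d, i] <- 1 / (1 + d)
  rs <- restraints_from_contacts(uni, bead_radius = 10)
  expect_true(all(rs$restraints$kind == "bond"))  # z = 0 within strata
  expect_equal(nrow(rs$restraints), n - 1)

  enr <- uni
  enr[3, 15] <- enr[15, 3] <- 0.9  # one strongly enriched long-range pair
  rs2 <- restraints_from_contacts(enr, bead_radius = 10)
  ups <- rs2$restraints[rs2$restraints$kind == "upper", ]
  expect_equal(nrow(ups), 1)
  expect_equal(c(ups$i, ups$j), c(3, 15))
  expect_gte(ups$d0_nm, 2 * 10)

  asym <- uni
  asym[1, 2] <- 5
  expect_error(restraints_from_contacts(asym), "symmetric")
})

test_that("model ensembles keep the best-energy conformations", {
  rs <- toy_restraints(8)
  ens <- model_ensemble(rs, n_models = 30, n_keep = 10, seed = 1,
                        max_iter = 60)
  expect_length(ens$models, 10)
  expect_true(all(ens$energies[1:10] <= ens$energies[11:30] + 1e-12))
  expect_error(model_ensemble(rs, n_models = 5, n_keep = 6), "<=")

  ens2 <- model_ensemble(rs, n_models = 30, n_keep = 10, seed = 1,
                         max_iter = 60)
  expect_equal(ens$models[[1]]$coords, ens2$models[[1]]$coords)
})

test_that("contact round trip recovers planted structure (50-bead toy)", {
  # planted chain -> perturbed ensemble -> contacts -> restraints ->
  # new ensemble: the generated models should reproduce both the planted
  # distance matrix and the input contact map
  truth <- make_chain(50, bond_length = 30, confinement_radius = 250,
                      seed = 3, r = 15)
  set.seed(99)
  perturbed <- lapply(1:12, function(i)
    truth$coords + matrix(rnorm(150, 0, 15), 50, 3))
  contacts <- contacts_from_ensemble(perturbed, cutoff = 90)
  rs <- restraints_from_contacts(contacts, bead_radius = 15)
  ens <- model_ensemble(rs, n_models = 60, n_keep = 10, seed = 5,
                        max_iter = 300)
  dtruth <- as.numeric(dist(truth$coords))
  dmean <- Reduce("+", lapply(ens$models, function(m)
    as.numeric(dist(m$coords)))) / 10
  expect_gt(cor(dtruth, dmean, method = "spearman"), 0.8)
  cm_out <- contacts_from_ensemble(lapply(ens$models, function(m)
    m$coords), cutoff = 90)
  ut <- which(upper.tri(contacts) & abs(row(contacts) - col(contacts)) >= 2)
  expect_gt(cor(contacts[ut], cm_out[ut], method = "spearman"), 0.6)
})

test_that("clash score counts non-adjacent close pairs per 1000 beads", {
  line <- cbind(seq(0, 990, 10) * 4, 0, 0)  # spaced 40 nm, r = 15
  expect_equal(clash_score(line, r = 15), 0)

  thousand <- cbind(seq_len(1000) * 100, 0, 0)
  thousand[500, ] <- thousand[502, ] + c(1, 0, 0)  # one clashing pair
  expect_equal(clash_score(thousand, r = 15), 1)

  # k co-located, chain-non-adjacent beads: all k(k-1)/2 pairs clash
  k <- 5; n <- 40
  co <- cbind(seq_len(n) * 100, 0, 0)
  co[c(1, 5, 9, 13, 17), ] <- 0  # spread along the chain, same position
  expected <- k * (k - 1) / 2 * 1000 / n
  expect_equal(clash_score(co, r = 15), expected)
})

test_that("flexible energy components follow the printed forms", {
  rs <- structure(list(
    restraints = data.frame(i = 1L, j = 2L, kind = "lower", d0_nm = 100,
                            k = 1),
    r = 5, k_ev = 0.01, n_beads = 2, bin_size = 1e4),
    class = "restraint_set")
  m <- blob_map(16, voxel = 20)
  coords <- rbind(c(100, 100, 100), c(180, 100, 100))  # d = 80 < d0 = 100
  e <- flex_energy(coords, m, rs, list(1:2))
  expect_equal(e$e_lb, 400)  # k (d0 - d)^2 = 1 * 20^2... (100-80)^2
  expect_equal(e$e_ub, 0)
  expect_equal(e$e_ev, 0)    # separation 80 >= 2r = 10

  # at equilibrium with L bodies of perfect CCC, E = -W1 * L
  chain <- make_chain(20, bond_length = 30, confinement_radius = 150,
                      seed = 2, r = 15)
  g <- chromotrace:::common_grid(
    data.frame(x_nm = chain$coords[, 1], y_nm = chain$coords[, 2],
               z_nm = chain$coords[, 3]), 15, pad = 100)
  tm <- render_model(chain, g, sigma = 25)
  rs2 <- structure(list(
    restraints = data.frame(i = integer(0), j = integer(0),
                            kind = character(0), d0_nm = numeric(0),
                            k = numeric(0)),
    r = 1e-6, k_ev = 0, n_beads = 20, bin_size = 1e4),
    class = "restraint_set")
  eL <- flex_energy(chain$coords, tm, rs2, list(1:20))
  expect_equal(eL$total, -1 * ccc(render_model(chain$coords, tm), tm),
               tolerance = 1e-6)
  expect_error(flex_energy(chain$coords, tm, rs2, list(1:10)), "cover")
})

test_that("rigid fitting respects counts, determinism and CombScore", {
  chain <- make_chain(20, bond_length = 30, confinement_radius = 120,
                      seed = 4, r = 15)
  g <- chromotrace:::common_grid(
    data.frame(x_nm = chain$coords[, 1], y_nm = chain$coords[, 2],
               z_nm = chain$coords[, 3]), 20, pad = 100)
  tm <- render_model(chain, g, sigma = 30)
  tm$threshold <- iso_threshold(tm)

  rf <- rigid_fit(chain, tm, n_placements = 12, seed = 2, max_iter = 60)
  expect_equal(nrow(rf$fits), 12)
  expect_equal(rf$fits$comb_score, rf$fits$cons + 2 * rf$fits$ccc)
  expect_true(all(rf$fits$cons >= 0 & rf$fits$cons <= 1))
  expect_gte(sum(rf$fits$refine), 1)

  rf2 <- rigid_fit(chain, tm, n_placements = 12, seed = 2, max_iter = 60)
  expect_identical(rf$fits, rf2$fits)

  # identity render of the model scores at least as well as the ensemble max
  self_ccc <- ccc(render_model(chain, tm), tm)
  expect_gte(self_ccc + 1e-3, max(rf$fits$ccc))
})

# Harmonic bounds at the planted conformation's pair distances: a
# restraint set whose energy optimum coincides with the planted chain, the
# self-consistent setting for perturb-and-recover refinement experiments.
truth_restraints <- function(chain, cutoff = 90, slack = 0.01, k = 0.02) {
  D <- as.matrix(dist(chain$coords))
  pairs <- which(upper.tri(D) & D < cutoff, arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= 2, , drop = FALSE]
  n <- nrow(chain$coords)
  bonds <- sqrt(rowSums(diff(chain$coords)^2))
  rows <- rbind(
    data.frame(i = pairs[, 1], j = pairs[, 2], kind = "upper",
               d0_nm = D[pairs] * (1 + slack), k = k),
    data.frame(i = pairs[, 1], j = pairs[, 2], kind = "lower",
               d0_nm = D[pairs] * (1 - slack), k = k),
    data.frame(i = seq_len(n - 1), j = 2:n, kind = "bond",
               d0_nm = bonds, k = k))
  structure(list(restraints = rows, r = chain$r, k_ev = 0.01,
                 n_beads = n, bin_size = chain$bin_size),
            class = "restraint_set")
}

test_that("refinement recovers a model perturbed by body rotations", {
  chain <- make_chain(30, bond_length = 30, confinement_radius = 150,
                      seed = 6, r = 10, min_dist = 20)
  g <- chromotrace:::common_grid(
    data.frame(x_nm = chain$coords[, 1], y_nm = chain$coords[, 2],
               z_nm = chain$coords[, 3]), 10, pad = 80)
  tm <- render_model(chain, g, sigma = 15)
  tm$threshold <- iso_threshold(tm)
  rs <- truth_restraints(chain)

  partition <- list(1:10, 11:20, 21:30)
  set.seed(6)
  perturbed <- chain$coords
  for (b in partition) {
    R <- chromotrace:::rotation_matrix(rnorm(3, sd = 0.5))
    cb <- colMeans(perturbed[b, ])
    perturbed[b, ] <- sweep(sweep(perturbed[b, ], 2, cb) %*% t(R), 2,
                            cb, "+")
  }
  cfg <- refinement_config(max_cycles = 30, heat_steps = 20,
                           cool_steps = 40, cg_steps = 100)
  ref <- flexible_refine(perturbed, tm, rs, partition, cfg, seed = 3)

  expect_gte(ref$final_ccc, ref$start_ccc)
  rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
  expect_lt(rmsd(ref$model$coords, chain$coords),
            0.5 * rmsd(perturbed, chain$coords))
  expect_lte(ref$final_clash, ref$start_clash + 1e-9)
  # schedule contract: cycles and per-cycle steps bounded
  expect_lte(max(ref$trajectory$cycle), cfg$max_cycles)
  steps <- table(ref$trajectory$cycle[ref$trajectory$cycle > 0])
  expect_true(all(steps <= cfg$heat_steps + cfg$cool_steps))
})

test_that("refinement leaves a planted optimum unchanged and stops early", {
  chain <- make_chain(20, bond_length = 30, confinement_radius = 120,
                      seed = 8, r = 10, min_dist = 20)
  g <- chromotrace:::common_grid(
    data.frame(x_nm = chain$coords[, 1], y_nm = chain$coords[, 2],
               z_nm = chain$coords[, 3]), 15, pad = 80)
  tm <- render_model(chain, g, sigma = 20)
  tm$threshold <- iso_threshold(tm)
  rs <- truth_restraints(chain)
  cfg <- refinement_config(max_cycles = 50, heat_steps = 10,
                           cool_steps = 20, cg_steps = 40,
                           trans_step = 2, rot_step = 0.02, patience = 2)
  ref <- flexible_refine(chain, tm, rs, list(1:10, 11:20), cfg, seed = 4)
  # hop cycles fail to improve the optimum: stop within 1 + patience
  expect_lte(max(ref$trajectory$cycle), 1 + cfg$patience)
  expect_gte(ref$final_ccc, ref$start_ccc)
  rmsd <- sqrt(mean(rowSums((ref$model$coords - chain$coords)^2)))
  expect_lt(rmsd, tm$voxel)
})
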