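test_that("distance score is the COM distance and matches brute force", {
  m <- blob_map(32, voxel = 15)
  expect_equal(distance_score(m, m), 0)

  shifted <- m
  shifted$origin <- m$origin + c(120, 0, 0)
  expect_equal(distance_score(m, shifted), 120, tolerance = 1e-9)

  # independent voxel-weighted COM summation
  m2 <- blob_map(32, voxel = 15, seed = 9)
  brute_com <- function(map) {
    mask <- map$data >= map$threshold
    idx <- which(mask, arr.ind = TRUE)
    w <- map$data[mask]
    colSums(sweep((idx - 1) * map$voxel, 2, map$origin, "+") * w) / sum(w)
  }
  expect_equal(distance_score(m, m2),
               sqrt(sum((brute_com(m) - brute_com(m2))^2)),
               tolerance = 1e-9)
})

test_that("entanglement score counts overlap against the smaller body", {
  m <- blob_map(32, voxel = 15)
  expect_equal(entanglement_score(m, m), 1)

  far <- m
  far$origin <- m$origin + c(5000, 0, 0)
  expect_equal(entanglement_score(m, far), 0)

  # constructed voxel sets: B 40 voxels inside A's 100; then half overlap
  a <- array(0, dim = c(10, 10, 10)); a[1:10, 1:10, 1] <- 1  # 100 voxels
  b <- array(0, dim = c(10, 10, 10)); b[1:10, 1:4, 1] <- 1   # 40 voxels
  A <- density_map(a, c(0, 0, 0), 10, threshold = 1)
  B <- density_map(b, c(0, 0, 0), 10, threshold = 1)
  expect_equal(entanglement_score(A, B), 1)
  Bs <- B
  # shift 8 voxels: B occupies world y 80..110, A ends at 90 -> 20 of 40
  Bs$origin <- B$origin + c(0, 80, 0)
  expect_equal(entanglement_score(A, Bs), 0.5)
  empty <- density_map(array(0, dim = c(4, 4, 4)), c(0, 0, 0), 10,
                       threshold = 0)
  empty$threshold <- 1
  expect_error(entanglement_score(A, empty), "non-empty")
})

test_that("power-law z-scores are exact on-curve and recover exponents", {
  sizes <- seq(1e5, 2e6, length.out = 50)
  vals <- 2 * sizes^0.5
  z <- size_corrected_zscore(vals, sizes)
  expect_true(all(abs(z) < 1e-6))

  set.seed(1)
  n <- 300
  sz <- exp(runif(n, log(1e5), log(2e6)))
  noisy <- 2 * sz^0.5 * rlnorm(n, 0, 0.2)
  fit <- power_law_fit(noisy, sz)
  expect_lt(abs(fit$b - 0.5) / 0.5, 0.05)

  expect_error(power_law_fit(c(1, 2), c(10, 20)), ">= 3")
  expect_error(size_corrected_zscore(c(1, 2, 3), c(-1, 2, 3)), "> 0")
})

test_that("sphericity follows the closed form", {
  R <- runif(1, 10, 1000)
  expect_equal(sphericity(4 / 3 * pi * R^3, 4 * pi * R^2), 1,
               tolerance = 1e-12)
  expect_equal(sphericity(1, 6), 0.80600, tolerance = 1e-5)
  expect_equal(sphericity(1, 3), 2 * sphericity(1, 6))
  expect_error(sphericity(0, 1), "> 0")
})

test_that("spatial overlap averages the two directed fractions", {
  set.seed(2)
  a <- as.data.frame(blob(200, sd = 60))
  names(a) <- c("x_nm", "y_nm", "z_nm")
  expect_equal(spatial_overlap(a, a), 1)
  expect_equal(spatial_overlap(a, a, align = TRUE), 1)

  b <- a
  b$x_nm <- b$x_nm + 5000
  expect_equal(spatial_overlap(a, b), 0)
  expect_equal(spatial_overlap(a, b, align = TRUE), 1)  # COM pre-alignment

  # constructed directed overlaps: slabs of different extent
  slab <- function(x0, x1) {
    g <- expand.grid(x = seq(x0, x1, by = 25), y = seq(0, 300, 25),
                     z = seq(0, 300, 25))
    data.frame(x_nm = g$x, y_nm = g$y, z_nm = g$z)
  }
  A <- slab(0, 500)
  B <- slab(300, 800)
  ov <- spatial_overlap(A, B, alpha = 50, voxel = 25)
  dirA <- sum(A$x_nm >= 250) / nrow(A)  # rough directed expectations
  expect_gt(ov, 0.1)
  expect_lt(ov, 0.9)
})

test_that("ellipsoid fits recover planted axis ratios", {
  set.seed(3)
  dirs <- matrix(rnorm(3e4), 1e4, 3)
  sphere <- 300 * dirs / sqrt(rowSums(dirs^2))
  expect_equal(ellipticity_score(sphere), 1, tolerance = 0.05)

  # area-uniform sample on a 2:1:1 ellipsoid via rejection
  a <- c(2, 1, 1) * 200
  u <- matrix(rnorm(9e4), 3e4, 3)
  u <- u / sqrt(rowSums(u^2))
  w <- sqrt((u[, 1] * a[2] * a[3])^2 + (u[, 2] * a[1] * a[3])^2 +
              (u[, 3] * a[1] * a[2])^2)
  keep <- runif(3e4) < w / max(w)
  ell <- sweep(u[keep, ][1:1e4, ], 2, a, "*")
  expect_lt(abs(ellipticity_score(ell) - 2) / 2, 0.05)

  expect_error(ellipticity_score(matrix(rnorm(9), 3, 3)), ">= 10")
  expect_error(ellipsoid_fit(cbind(1:20, 1:20, 1:20)), "rank")
})

test_that("ellipticity ratio is the symmetric larger-over-smaller ratio", {
  expect_equal(ellipticity_ratio(1.7, 1.7), 1)
  expect_equal(ellipticity_ratio(2, 1), 2)
  expect_equal(ellipticity_ratio(1.2, 3.1), ellipticity_ratio(3.1, 1.2))
  expect_error(ellipticity_ratio(0.9, 2), ">= 1")
})

test_that("random-pair null is deterministic and degenerate on ties", {
  sc <- data.frame(nucleus = rep(1:5, each = 2), score = 1.5)
  rp <- random_pair_null(sc, n_pairs = 200, seed = 11)
  expect_true(all(rp$null_ratios == 1))
  rp2 <- random_pair_null(sc, n_pairs = 200, seed = 11)
  expect_identical(rp$null_ratios, rp2$null_ratios)
  expect_error(random_pair_null(c(1.2, 1.3), 10), ">= 4")
})

test_that("the rank test detects 2x inflated within-nucleus ratios", {
  # power under a planted effect: within ratios stochastically 2x the null
  set.seed(12)
  hits <- 0
  for (i in 1:20) {
    base <- 1 + rlnorm(38, -1, 0.3)
    sc <- data.frame(nucleus = rep(1:19, each = 2), score = base)
    infl <- sc
    infl$score[seq(1, 37, 2)] <- infl$score[seq(2, 38, 2)] *
      (1 + 2 * (rlnorm(19, -1, 0.3)))
    rp <- random_pair_null(infl, n_pairs = 1000, seed = i)
    hits <- hits + (rp$test$p.value < 0.01)
  }
  expect_gte(hits / 20, 0.9)
})

test_that("PCA classification recovers well-separated planted clusters", {
  set.seed(13)
  n <- 150
  X <- matrix(rnorm(2 * n * 19), 2 * n, 19)
  # 6-sigma multivariate separation spread over 9 features (2 sigma each),
  # which survives the per-column standardization of the classifier
  X[1:n, 1:9] <- X[1:n, 1:9] + 2
  vol <- c(rep(10, n), rep(1, n))      # group 1 has larger volume
  res <- pca_classify(X, volume = vol, seed = 1)
  acc <- mean(res$labels[1:n] == 1) * 0.5 + mean(res$labels[(n + 1):(2 * n)] == 2) * 0.5
  expect_gte(acc, 0.95)
  expect_equal(sum(res$explained_variance), 1, tolerance = 1e-9)

  # duplicating rows leaves the PC directions unchanged
  res2 <- pca_classify(rbind(X, X), volume = c(vol, vol), seed = 1)
  r1 <- res$pca$rotation[, 1]
  r2 <- res2$pca$rotation[, 1]
  expect_lt(min(sum((r1 - r2)^2), sum((r1 + r2)^2)), 1e-9)

  Xc <- cbind(X, 1)
  colnames(Xc) <- c(paste0("f", 1:19), "const")
  expect_warning(pca_classify(Xc, volume = vol, seed = 1), "constant")
  expect_error(pca_classify(rbind(X, NA)), "missing")
})

test_that("compartment profiles encode the three comparison cases", {
  expect_equal(compartment_profile(rep(1, 9), rep(1, 9)), rep(1L, 9))
  expect_equal(compartment_profile(rep(1, 9), rep(2, 9)), rep(0L, 9))
  expect_equal(compartment_profile(rep(2, 9), rep(2, 9)), rep(-1L, 9))
  mixed <- compartment_profile(c(1, 1, 2, 2, 1, 2, 1, 2, 1),
                               c(1, 2, 2, 1, 1, 2, 2, 2, 1))
  expect_equal(mixed, c(1L, 0L, -1L, 0L, 1L, -1L, 0L, -1L, 1L))
  expect_error(compartment_profile(rep(1, 8), rep(1, 9)), "length 9")
  expect_error(compartment_profile(rep(3, 9), rep(1, 9)), "1 or 2")
})

test_that("DS/ES matrices are symmetric with the right diagonal", {
  maps <- lapply(1:4, function(i) blob_map(24, voxel = 20, seed = i))
  names(maps) <- paste0("CS", 1:4)
  ps <- pairwise_scores(maps)
  expect_equal(ps$ds, t(ps$ds))
  expect_equal(ps$es, t(ps$es))
  expect_true(all(diag(ps$ds) == 0))
  expect_true(all(diag(ps$es) == 1))
  expect_true(all(ps$es >= 0 & ps$es <= 1))
})
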