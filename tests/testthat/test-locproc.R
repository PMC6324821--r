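test_that("quality rank is the cube-root product with hard [0,1] domain", {
  expect_equal(score_quality(1, 1, 1), 1)
  expect_equal(score_quality(1, 1, 0.512), 0.8)      # exactly at threshold
  expect_equal(score_quality(0, 0.9, 0.9), 0)
  expect_error(score_quality(1.2, 0.5, 0.5), "0, 1")
  expect_error(score_quality(-0.1, 0.5, 0.5), "0, 1")
  # symmetry and monotonicity over random triples
  set.seed(1)
  for (i in 1:20) {
    m <- runif(3)
    perms <- list(m, m[c(2, 1, 3)], m[c(3, 2, 1)], m[c(2, 3, 1)])
    vals <- vapply(perms, function(p) score_quality(p[1], p[2], p[3]),
                   numeric(1))
    expect_true(max(vals) - min(vals) < 1e-12)
    bumped <- pmin(m + runif(3, 0, 1 - max(m)), 1)
    expect_gte(score_quality(bumped[1], bumped[2], bumped[3]),
               score_quality(m[1], m[2], m[3]))
  }
})

test_that("quality filter keeps events at or above rank 0.8", {
  set.seed(2)
  n <- 500
  locs <- localizations(rnorm(n), rnorm(n), rnorm(n), frame = seq_len(n),
                        psf_photons = runif(n, 100, 5000),
                        cutout_photons = runif(n, 5000, 9000),
                        z_offset_nm = rnorm(n, 0, 100),
                        lat_prec_nm = 11, ax_prec_nm = 47)
  kept <- filter_quality(locs, 0.8)
  m <- normalize_metrics(locs)
  q <- score_quality(m[, 1], m[, 2], m[, 3])
  expect_equal(nrow(kept), sum(q >= 0.8))
  expect_true(all(attr(kept, "quality_rank") >= 0.8))
})

test_that("axial filter keeps precisions up to and including 100 nm", {
  locs <- locs_from_points(matrix(0, 4, 3), ax = c(40, 99, 100, 101))
  expect_equal(nrow(filter_axial(locs)), 3)
  expect_equal(nrow(filter_axial(locs_from_points(matrix(0, 3, 3), ax = 47))), 3)
  empty <- locs[0, ]
  expect_equal(nrow(filter_axial(empty)), 0)
})

test_that("repeat merging follows the 2-pixel / 7-frame rule", {
  two <- function(frames, dx = 0) {
    locs_from_points(rbind(c(0, 0, 0), c(dx, 0, 0)), frame = frames)
  }
  expect_equal(nrow(merge_repeats(two(c(10, 11)))), 1)        # merge
  expect_equal(nrow(merge_repeats(two(c(10, 18)))), 2)        # span 8 > 7
  expect_equal(nrow(merge_repeats(two(c(10, 11), dx = 300))), 2)  # 3 px apart
  expect_error(merge_repeats(two(c(11, 10))), "sorted")
})

test_that("merging never increases counts, is idempotent, and pools photons", {
  set.seed(3)
  n <- 200
  pts <- matrix(rnorm(3 * n, sd = 30), n, 3)
  locs <- locs_from_points(pts, frame = sort(sample.int(80, n, TRUE)))
  m1 <- merge_repeats(locs)
  m2 <- merge_repeats(m1)
  expect_lte(nrow(m1), nrow(locs))
  expect_equal(m1, m2)
  expect_equal(sum(m1$psf_photons), sum(locs$psf_photons))
})

test_that("drift correction recovers an injected linear drift", {
  set.seed(4)
  n <- 2000
  v <- c(50, -30, 20)  # total drift over the recording, nm
  frames <- sort(sample.int(10000, n, TRUE)) - 1L
  base <- matrix(rnorm(3 * n, sd = 40), n, 3)
  drifted <- base + outer(frames / 9999, v)
  locs <- locs_from_points(drifted, frame = frames)
  fid <- do.call(rbind, lapply(1:3, function(m) {
    ff <- seq(0, 9999, by = 10)
    data.frame(marker_id = m, frame = ff,
               x_nm = m * 100 + v[1] * ff / 9999,
               y_nm = -m * 50 + v[2] * ff / 9999,
               z_nm = m * 20 + v[3] * ff / 9999)
  }))
  dc <- drift_correct(locs, fid, window = 1000)
  resid <- as.matrix(dc$locs[, c("x_nm", "y_nm", "z_nm")]) - base
  expect_lt(sqrt(mean(resid^2)), 2)
  # drift trace tracks v * t at the window centres
  expected <- outer((dc$drift$frame_center - dc$drift$frame_center[1]) / 9999, v)
  expect_lt(max(abs(as.matrix(dc$drift[, c("dx", "dy", "dz")]) - expected)), 3)
})

test_that("static fiducials give a null drift trace and identity correction", {
  locs <- locs_from_points(matrix(rnorm(30), 10, 3), frame = 1:10)
  fid <- data.frame(marker_id = 1, frame = c(1, 500, 1500),
                    x_nm = 100, y_nm = 200, z_nm = 300)
  dc <- drift_correct(locs, fid, window = 1000)
  expect_equal(dc$locs$x_nm, locs$x_nm)
  expect_true(all(abs(as.matrix(dc$drift[, c("dx", "dy", "dz")])) < 1e-12))
  expect_error(drift_correct(locs, NULL), "fiducial")
})

test_that("drift correction inverts exactly when the drift is re-injected", {
  set.seed(5)
  locs <- locs_from_points(matrix(rnorm(300, sd = 50), 100, 3),
                           frame = sort(sample.int(5000, 100)))
  fid <- data.frame(marker_id = 1, frame = seq(0, 4999, 50),
                    x_nm = seq(0, 40, length.out = 100),
                    y_nm = 0, z_nm = seq(0, -25, length.out = 100))
  dc <- drift_correct(locs, fid, window = 1000)
  d <- dc$drift_at(locs$frame)
  expect_lt(max(abs(dc$locs$x_nm + d[, 1] - locs$x_nm)), 1e-6)
  expect_lt(max(abs(dc$locs$z_nm + d[, 3] - locs$z_nm)), 1e-6)
})

test_that("DBSCAN separates blobs, flags sparse noise, matches the oracle", {
  set.seed(6)
  two <- rbind(blob(100, c(0, 0, 0), 40), blob(80, c(1000, 0, 0), 40))
  res <- extract_clusters(locs_from_points(two, frame = seq_len(180)))
  expect_equal(length(res$clusters), 2)
  expect_equal(sort(vapply(res$clusters, length, integer(1)),
                    decreasing = TRUE), c(100, 80))

  sparse <- locs_from_points(matrix(seq(0, 3000, length.out = 30), 10, 3),
                             frame = 1:10)
  res2 <- extract_clusters(sparse, max_distance = 150, min_points = 2)
  expect_equal(length(res2$clusters), 0)
  expect_true(all(res2$labels == 0))

  one <- extract_clusters(locs_from_points(blob(60, sd = 30), frame = 1:60))
  expect_equal(length(one$clusters), 1)

  # label-exact agreement with the brute-force density-reachability oracle
  for (i in 1:5) {
    set.seed(100 + i)
    pts <- rbind(blob(150, c(0, 0, 0), 60), blob(150, c(400, 100, 0), 80),
                 matrix(runif(300, -500, 900), 100, 3))
    res3 <- extract_clusters(locs_from_points(pts, frame = seq_len(400)),
                             max_distance = 100, min_points = 8)
    expect_identical(res3$labels, dbscan_oracle(pts, 100, 8))
  }
})
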