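test_that("rasterization counts localizations into nearest voxels", {
  one <- data.frame(x_nm = 10, y_nm = 20, z_nm = 30)
  m <- rasterize(one, voxel_size = 25)
  expect_equal(sum(m$data), 1)
  expect_equal(max(m$data), 1)

  k <- data.frame(x_nm = rep(10, 7), y_nm = 20, z_nm = 30)
  expect_equal(max(rasterize(k, 25)$data), 7)

  set.seed(1)
  cloud <- as.data.frame(blob(500, sd = 80))
  names(cloud) <- c("x_nm", "y_nm", "z_nm")
  expect_equal(sum(rasterize(cloud, 25, padding = 50)$data), 500)
  expect_error(rasterize(cloud[0, ], 25), "empty")
})

test_that("Gaussian convolution conserves mass and decays monotonically", {
  z <- density_map(array(0, dim = c(8, 8, 8)), c(0, 0, 0), 10)
  expect_true(all(convolve_gaussian(z, 15)$data == 0))
  expect_error(convolve_gaussian(z, -1), "sigma")

  # single count in the centre: max there, monotone decay along the axis
  a <- array(0, dim = c(21, 21, 21)); a[11, 11, 11] <- 1
  sm <- convolve_gaussian(density_map(a, c(0, 0, 0), 10), 20)
  expect_equal(which.max(sm$data), which(seq_len(21^3) ==
    (10 * 21 * 21 + 10 * 21 + 11)))
  axis_profile <- sm$data[11:18, 11, 11]  # within the 4-sigma support
  expect_true(all(diff(axis_profile) < 0))

  # mass conservation within 1% when the cloud is >= 5 sigma from edges
  set.seed(2)
  cloud <- as.data.frame(blob(400, sd = 40))
  names(cloud) <- c("x_nm", "y_nm", "z_nm")
  counts <- rasterize(cloud, 20, padding = 5 * 25)
  sm2 <- convolve_gaussian(counts, 25)
  expect_lt(abs(sum(sm2$data) - 400) / 400, 0.01)
})

test_that("convolution is linear over disjoint clusters on a shared grid", {
  g <- density_map(array(0, dim = c(30, 30, 30)), c(0, 0, 0), 20)
  a <- data.frame(x_nm = runif(50, 50, 150), y_nm = runif(50, 50, 150),
                  z_nm = runif(50, 50, 150))
  b <- data.frame(x_nm = runif(50, 400, 500), y_nm = runif(50, 400, 500),
                  z_nm = runif(50, 400, 500))
  ra <- chromotrace:::rasterize_on_grid(a, g)
  rb <- chromotrace:::rasterize_on_grid(b, g)
  rab <- chromotrace:::rasterize_on_grid(rbind(a, b), g)
  expect_equal(convolve_gaussian(rab, 30)$data,
               convolve_gaussian(ra, 30)$data +
                 convolve_gaussian(rb, 30)$data,
               tolerance = 1e-12)
})

test_that("iso threshold matches the background sigma and is shift-invariant", {
  set.seed(3)
  s <- 0.4
  noise <- pmax(rnorm(50^3, 5, s), 0)  # background well above clip
  m <- density_map(array(noise, dim = c(50, 50, 50)), c(0, 0, 0), 10)
  thr <- iso_threshold(m)
  expect_lt(abs(as.numeric(thr) - s) / s, 0.1)

  shifted <- density_map(m$data + 2, c(0, 0, 0), 10)
  expect_equal(as.numeric(iso_threshold(shifted)), as.numeric(thr),
               tolerance = 1e-9)

  expect_error(iso_threshold(density_map(array(1, dim = c(4, 4, 4)),
                                         c(0, 0, 0), 10)),
               "degenerate|constant")
})

test_that("zero-background maps threshold to essentially all signal", {
  a <- array(0, dim = c(20, 20, 20))
  a[9:12, 9:12, 9:12] <- 10
  m <- build_density_map(data.frame(x_nm = runif(50, 90, 110),
                                    y_nm = runif(50, 90, 110),
                                    z_nm = runif(50, 90, 110)),
                         voxel_size = 10, sigma = 15)
  expect_gte(sum(chromotrace:::body_mask(m)), 1)
  bg <- m$data[m$data < m$threshold]
  expect_lt(sum(bg), 0.2 * sum(m$data))  # body holds nearly all intensity
})

test_that("hull area is exact on cubes and close on spheres", {
  L <- 70
  cube <- as.matrix(expand.grid(c(0, L), c(0, L), c(0, L)))
  expect_equal(convex_hull_area(cube), 6 * L^2, tolerance = 1e-12)

  set.seed(4)
  R <- 400
  dirs <- matrix(rnorm(6000), 2000, 3)
  sph <- R * dirs / sqrt(rowSums(dirs^2))
  expect_lt(abs(convex_hull_area(sph) - 4 * pi * R^2) / (4 * pi * R^2), 0.02)

  line <- cbind(1:10, 1:10, 1:10)
  expect_error(convex_hull_area(line), "collinear|degenerate")
})

test_that("body volume counts thresholded voxels exactly", {
  a <- array(0, dim = c(10, 10, 10))
  a[1:3, 1, 1] <- 5
  m <- density_map(a, c(0, 0, 0), 25, threshold = 4)
  expect_equal(body_volume(m), 3 * 25^3)
  m$threshold <- 5
  expect_equal(body_volume(m), 3 * 25^3)
  a2 <- array(1, dim = c(5, 5, 5))
  expect_equal(body_volume(density_map(a2, c(0, 0, 0), 10, threshold = 1)),
               125 * 1000)
})

test_that("voxelized ball volume matches the analytic ball within 3%", {
  R <- 500; v <- 25
  g <- seq(-R - 2 * v, R + 2 * v, by = v)
  inside <- outer(outer(g^2, g^2, "+"), g^2, "+") <= R^2
  m <- density_map(array(as.numeric(inside), dim = rep(length(g), 3)),
                   rep(g[1], 3), v, threshold = 0.5)
  expect_lt(abs(body_volume(m) - 4 / 3 * pi * R^3) / (4 / 3 * pi * R^3), 0.03)
})

test_that("raising the threshold never grows the body", {
  m <- blob_map(32, voxel = 15)
  vols <- vapply(quantile(m$data, c(0.5, 0.7, 0.9, 0.99)), function(t) {
    m$threshold <- t
    body_volume(m)
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("area and volume are rotation-invariant within tolerance", {
  set.seed(5)
  pts <- blob(800, sd = c(120))
  build <- function(P) {
    cl <- data.frame(x_nm = P[, 1], y_nm = P[, 2], z_nm = P[, 3])
    m <- build_density_map(cl, voxel_size = 20, sigma = 25)
    c(surface_area(m), body_volume(m))
  }
  base <- build(pts)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- build(pts %*% Rz)
  expect_lt(abs(rot[1] - base[1]) / base[1], 0.03)
  expect_lt(abs(rot[2] - base[2]) / base[2], 0.03)
})

test_that("MRC round trip preserves the map", {
  m <- blob_map(24, voxel = 20)
  f <- tempfile(fileext = ".mrc")
  write_mrc(m, f)
  m2 <- read_mrc(f)
  expect_equal(dim(m2$data), dim(m$data))
  expect_equal(m2$voxel, m$voxel)
  expect_equal(m2$origin, m$origin, tolerance = 1e-5)
  expect_equal(m2$data, m$data, tolerance = 1e-6)  # float32 storage
  expect_equal(m2$sigma, m$sigma, tolerance = 1e-6)
  unlink(f)
})
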