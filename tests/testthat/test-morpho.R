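test_that("connected components split and merge with connectivity", {
  arr <- array(0L, c(10, 10, 10))
  arr[2:3, 2:3, 2:3] <- 1L
  arr[6:7, 6:7, 6:7] <- 1L
  c26 <- label_components(arr, 1L, 26L)
  expect_identical(attr(c26, "n_components"), 2L)
  ## cubes touching at a single corner merge only under 26-connectivity
  corner <- array(0L, c(6, 6, 6))
  corner[1:3, 1:3, 1:3] <- 1L
  corner[4:6, 4:6, 4:6] <- 1L
  expect_identical(attr(label_components(corner, 1L, 26L), "n_components"), 1L)
  expect_identical(attr(label_components(corner, 1L, 6L), "n_components"), 2L)
  empty <- label_components(array(0L, c(4, 4, 4)), 1L)
  expect_identical(attr(empty, "n_components"), 0L)
  expect_error(label_components(arr, 1L, 18L), "connectivity")
  ## deterministic scan-order ids: first cube (lower indices) is component 1
  expect_identical(unique(as.vector(c26[2:3, 2:3, 2:3])), 1L)
})

test_that("digital ball morphometry approaches the sphere closed forms", {
  ball <- digital_ellipsoid(c(20, 20, 20))
  comp <- label_components(ball, 1L)
  ss <- shape_stats(comp, c(1, 1, 1))
  r_eq <- (3 * ss$n_voxels / (4 * pi))^(1 / 3)   # volume-equivalent radius
  expect_gt(ss$sphericity, 0.95)
  expect_lte(ss$sphericity, 1.0)
  expect_lt(abs(ss$sa_to_v - 3 / r_eq) / (3 / r_eq), 0.05)
  expect_lt(ss$elongation, 1.05)
  expect_gte(ss$elongation, 1 - 1e-6)
  expect_lt(ss$flatness, 1.05)
  expect_lt(abs(ss$spareness - 1), 0.05)
  ## voxel-face surface of a ball is biased high by about 1.5x
  sf <- shape_stats(comp, c(1, 1, 1), surface_estimator = "voxel_faces")
  expect_gt(sf$surface_um2 / (4 * pi * r_eq^2), 1.4)
  expect_lt(sf$surface_um2 / (4 * pi * r_eq^2), 1.6)
})

test_that("digital cube compactness matches pi/6 under exact face counting", {
  cube <- array(0L, c(30, 30, 30))
  cube[6:25, 6:25, 6:25] <- 1L   # a = 20: V = a^3 and S = 6 a^2 are exact
  ss <- shape_stats(label_components(cube, 1L), c(1, 1, 1),
                    surface_estimator = "voxel_faces")
  expect_equal(ss$volume_um3, 8000)
  expect_equal(ss$surface_um2, 6 * 400)
  expect_equal(ss$compactness, pi / 6, tolerance = 1e-12)
  expect_equal(ss$sphericity, (pi / 6)^(1 / 3), tolerance = 1e-12)
})

test_that("ellipsoid second moments recover the semi-axis ratios", {
  ell <- digital_ellipsoid(c(40, 20, 10))
  ss <- shape_stats(label_components(ell, 1L), c(1, 1, 1))
  ## covariance of a solid ellipsoid is diag(a^2, b^2, c^2) / 5
  expect_lt(abs(ss$elongation - 2) / 2, 0.05)
  expect_lt(abs(ss$flatness - 2) / 2, 0.05)
  expect_lt(abs(ss$spareness - 1), 0.05)
})

test_that("the ball is the most compact of equal-volume shapes and SA:V scales as 1/s", {
  ball <- digital_ellipsoid(c(12, 12, 12))
  vol_target <- sum(ball)
  a <- round(vol_target^(1 / 3))
  cube <- array(0L, c(a + 8, a + 8, a + 8))
  cube[5:(4 + a), 5:(4 + a), 5:(4 + a)] <- 1L
  ell <- digital_ellipsoid(c(24, 12, 6))
  stats_of <- function(m) shape_stats(label_components(m, 1L), c(1, 1, 1))
  sb <- stats_of(ball)
  sc <- stats_of(cube)
  se <- stats_of(ell)
  expect_gt(sb$sphericity, sc$sphericity)
  expect_gt(sb$sphericity, se$sphericity)
  expect_lt(sb$sa_to_v, sc$sa_to_v)
  expect_lt(sb$sa_to_v, se$sa_to_v)
  ## doubling the radius halves SA:V (within discretization error)
  small <- stats_of(digital_ellipsoid(c(10, 10, 10)))
  big <- stats_of(digital_ellipsoid(c(20, 20, 20)))
  expect_lt(abs(small$sa_to_v / big$sa_to_v - 2) / 2, 0.05)
  ## tiny components are flagged, not dropped
  dot <- array(0L, c(5, 5, 5))
  dot[3, 3, 3] <- 1L
  sd <- shape_stats(label_components(dot, 1L), c(1, 1, 1))
  expect_true(sd$unreliable)
  expect_identical(nrow(sd), 1L)
})

test_that("density maps equal a brute-force window recount", {
  ## uniform 1:2 interleave -> every window ratio is exactly 0.5
  lab <- array(2L, c(12, 12, 12))
  lab[, , seq(1, 12, 3)] <- 1L
  dm <- density_map(lab, kernel_um = 6, stride_um = 3, voxel_size_um = 1)
  expect_true(all(dm$map == 0.5))
  expect_identical(dm$n_undefined, 0L)
  ## no mitochondria -> all defined cells are 0
  lab0 <- array(2L, c(8, 8, 8))
  dm0 <- density_map(lab0, kernel_um = 4, stride_um = 2, voxel_size_um = 1)
  expect_true(all(dm0$map == 0))
  ## random labels: exact agreement with a naive double-loop recount
  set.seed(9)
  lab_r <- array(sample(0:3, 14^3, TRUE), c(14, 14, 14))
  dm_r <- density_map(lab_r, kernel_um = 5, stride_um = 2, voxel_size_um = 1)
  kv <- dm_r$kernel_vox
  for (iz in seq_along(dm_r$origins[[1]]))
    for (iy in seq_along(dm_r$origins[[2]]))
      for (ix in seq_along(dm_r$origins[[3]])) {
        oz <- dm_r$origins[[1]][iz]
        oy <- dm_r$origins[[2]][iy]
        ox <- dm_r$origins[[3]][ix]
        win <- lab_r[oz:(oz + kv[1] - 1), oy:(oy + kv[2] - 1),
                     ox:(ox + kv[3] - 1)]
        n1 <- sum(win == 1L)
        n2 <- sum(win == 2L)
        want <- if (n2 == 0) NA_real_ else n1 / n2
        expect_identical(dm_r$map[iz, iy, ix], want)
      }
  expect_error(density_map(lab0, kernel_um = 20, voxel_size_um = 1), "larger")
})

test_that("distribution comparison reproduces the hand-computed ANOVA table", {
  x <- c(1, 2, 3)
  y <- c(2, 3, 4)
  ## by hand: group means 2 and 3, grand mean 2.5, SSB = 1.5, SSW = 4,
  ## F = (1.5/1) / (4/4) = 1.5
  res <- compare_distributions(x, y)
  expect_equal(res$f, 1.5)
  expect_equal(res$p, stats::pf(1.5, 1, 4, lower.tail = FALSE))
  expect_equal(res$eta_sq, 1.5 / 5.5)
  ## identical samples: F = 0, p = 1
  a <- rnorm(20)
  same <- compare_distributions(a, a)
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)
  ## a large shift is detected decisively
  shifted <- compare_distributions(a, a + 10)
  expect_lt(shifted$p, 1e-3)
  ## constant samples flag degeneracy instead of erroring
  dg <- compare_distributions(rep(2, 5), rep(2, 5))
  expect_true(dg$degenerate)
  expect_equal(dg$p, 1)
})

test_that("mutual volume Jaccard matrices are symmetric and consistent", {
  ph <- generate_phantom(training_phantom_config(41, c(6L, 64L, 64L), mito_count = 0L))
  v1 <- ph$labels
  v2 <- degrade_labels(v1, 0.2, seed = 1)
  v3 <- degrade_labels(v1, 0.5, seed = 2)
  M <- mutual_volume_jaccard(list(v1, v2, v3))
  expect_equal(diag(M), rep(0, 3))
  expect_equal(M, t(M))
  expect_equal(M[1, 2], jaccard_distance(v1, v2))
  expect_equal(M[2, 3], jaccard_distance(v2, v3))
  ## identical copies give the zero matrix; disjoint foregrounds distance 1
  expect_true(all(mutual_volume_jaccard(list(v1, v1, v1)) == 0))
  da <- array(0L, c(2, 4, 4)); da[1, , ] <- 1L
  db <- array(0L, c(2, 4, 4)); db[2, , ] <- 1L
  expect_equal(mutual_volume_jaccard(list(da, db), "foreground")[1, 2], 1)
})
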