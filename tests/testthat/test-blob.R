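gauss2d <- function(n, ctr, t, A = 1) {
  x <- outer((1:n - ctr[1])^2, (1:n - ctr[2])^2, "+")
  A * exp(-x / (2 * t))
}

test_that("scale space: impulse variance, semigroup, identity limit", {
  n <- 41
  imp <- matrix(0, n, n); imp[21, 21] <- 1
  t <- 4
  L <- scale_space_slice(imp, t)
  # second moment of the response equals the scale index
  w <- L / sum(L)
  i <- row(L) - 21
  expect_equal(sum(w * i^2), t, tolerance = 0.02)

  # semigroup: smoothing by t1 then t2 equals smoothing by t1 + t2
  L12 <- scale_space_slice(scale_space_slice(imp, 3), 2)
  L3 <- scale_space_slice(imp, 5)
  expect_lt(max(abs(L12 - L3)), 1e-4)

  # t -> 0 approaches the identity
  expect_equal(scale_space_slice(imp, 1e-4), imp, tolerance = 1e-6)
})

test_that("DoH response: constants and ramps vanish, blob scale is optimal", {
  expect_true(all(doh_response(matrix(3, 15, 15), 2) == 0))
  ramp <- outer(1:15, 1:15, function(i, j) 2 * i + 3 * j - 4)
  expect_true(all(abs(doh_response(ramp, 2)) < 1e-9))

  # analytic Gaussian blob of variance t0: centre response maximal at t = t0
  t0 <- 8
  blob <- gauss2d(81, c(41, 41), t0)
  ts <- seq(2, 20, by = 0.5)
  resp <- vapply(ts, function(t)
    doh_response(scale_space_slice(blob, t), t)[41, 41], numeric(1))
  expect_lt(abs(ts[which.max(resp)] - t0), 1)
})

test_that("moment descriptor: solid sphere trace, intensity invariance, rod", {
  s <- 0.6
  R <- 3.5
  n <- 31
  v <- as_volume(array(0, c(n, n, n)), spacing = rep(s, 3))
  ctr <- (n - 1) * s / 2 + c(0, 0, 0)
  v <- voxelize_sphere(v, rep(ctr[1], 3), R, 1)
  d <- moment_descriptor(v, rep(ctr[1], 3), R)
  expect_false(d$degenerate)
  expect_lt(abs(d$size - 3 * R^2 / 5) / (3 * R^2 / 5), 0.10)
  # near-isotropic moment matrix
  expect_lt(max(abs(d$moments - diag(rep(d$size / 3, 3)))), 0.15)

  v2 <- as_volume(2 * v$data, spacing = v$spacing)
  d2 <- moment_descriptor(v2, rep(ctr[1], 3), R)
  expect_equal(d2$components, d$components, tolerance = 1e-12)

  # anisotropic rod: distinct eigenvalues, different trace
  vr <- as_volume(array(0, c(n, n, n)), spacing = rep(s, 3))
  vr$data[10:22, 15, 15] <- 1
  ctr_r <- voxel_to_world(vr, c(16, 15, 15))
  dr <- moment_descriptor(vr, as.numeric(ctr_r), R)
  ev <- eigen(dr$moments, symmetric = TRUE)$values
  expect_gt(ev[1] / max(ev[3], 1e-9), 10)
  expect_gt(abs(dr$size - d$size), 0.5)

  dz <- moment_descriptor(as_volume(array(0, c(9, 9, 9))), c(4, 4, 4), 3)
  expect_true(dz$degenerate)
})

test_that("cluster selection recovers a labelled sphere group among clutter", {
  set.seed(21)
  sph <- cbind(xx = stats::rnorm(20, 2.45, 0.03),
               yy = stats::rnorm(20, 2.45, 0.03),
               zz = stats::rnorm(20, 2.45, 0.03),
               xy = stats::rnorm(20, 0, 0.02),
               xz = stats::rnorm(20, 0, 0.02),
               yz = stats::rnorm(20, 0, 0.02))
  clut <- cbind(xx = stats::runif(200, 4, 9), yy = stats::runif(200, 4, 9),
                zz = stats::runif(200, 4, 9), xy = stats::rnorm(200, 0, 1),
                xz = stats::rnorm(200, 0, 1), yz = stats::rnorm(200, 0, 1))
  X <- rbind(sph, clut)
  sel <- cluster_select(X, characteristic_size = 3 * 3.5^2 / 5, seed = 1)
  expect_true(all(1:20 %in% sel))
  purity <- mean(sel <= 20)
  expect_gte(purity, 0.95)

  # a single tight group is returned whole
  expect_equal(cluster_select(sph[1:5, ], 7.35, seed = 1), 1:5)
  # determinism
  expect_identical(cluster_select(X, 7.35, seed = 3),
                   cluster_select(X, 7.35, seed = 3))
})

test_that("blob candidates cover all true spheres and are permissive", {
  ph <- small_phantom(s = 1.0)
  bc <- blob_candidates(ph$volume, 3.5)
  for (i in 1:10) {
    dd <- sqrt((bc$x - ph$truth$sphere_centers[i, 1])^2 +
                 (bc$y - ph$truth$sphere_centers[i, 2])^2 +
                 (bc$z - ph$truth$sphere_centers[i, 3])^2)
    expect_lt(min(dd), 1.0)  # within one voxel of a candidate
  }
  expect_gt(nrow(bc), 10)  # deliberately permissive

  # a noisy (textured) phantom produces far more raw candidates
  phn <- small_phantom(s = 1.0, noise_sd = 0.05)
  expect_gt(nrow(blob_candidates(phn$volume, 3.5)), 50)

  expect_equal(nrow(blob_candidates(as_volume(array(0, c(20, 20, 20))), 3.5)),
               0L)
})

test_that("blob detection keeps all spheres and is deterministic", {
  ph <- small_phantom(s = 1.0)
  c1 <- detect_spheres_blob(ph$volume, seed = 0)
  c2 <- detect_spheres_blob(ph$volume, seed = 0)
  expect_identical(c1, c2)
  ev <- evaluate_detections(c1, ph$truth)
  expect_equal(ev$recall, 1.0)
  # clustering reduces the raw candidate count
  expect_lt(nrow(c1), nrow(blob_candidates(ph$volume, 3.5)))
})
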