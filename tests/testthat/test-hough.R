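# anti-aliased disk (5x5 subsampled inside fraction), so edge normals are
# meaningfully comparable with the analytic circle normal
disk_image <- function(n, ctr, r) {
  aa <- matrix(0, n, n)
  for (oi in seq(-0.4, 0.4, 0.2)) for (oj in seq(-0.4, 0.4, 0.2))
    aa <- aa + (outer((1:n - ctr[1] + oi)^2, (1:n - ctr[2] + oj)^2,
                      "+") <= r^2)
  aa / 25
}

# ring of ideal edge pixels with exact radial gradient directions
ideal_circle_edges <- function(n, ctr, r) {
  mag <- matrix(0, n, n)
  dir <- matrix(0, n, n)
  for (th in seq(0, 2 * pi, length.out = 720)) {
    i <- round(ctr[1] + r * cos(th)); j <- round(ctr[2] + r * sin(th))
    if (i >= 1 && i <= n && j >= 1 && j <= n) {
      mag[i, j] <- 1
      dir[i, j] <- atan2(j - ctr[2], i - ctr[1])
    }
  }
  list(magnitude = mag, direction = dir)
}

test_that("Gaussian gradient: constants, step edges and disk normals", {
  g0 <- gaussian_gradient(matrix(5, 20, 20), sigma = 1)
  expect_true(all(abs(g0$magnitude) < 1e-12))

  step <- matrix(0, 20, 20); step[11:20, ] <- 1  # edge across rows
  gs <- gaussian_gradient(step, sigma = 1)
  edge <- which(gs$magnitude > 0.5 * max(gs$magnitude), arr.ind = TRUE)
  ang <- gs$direction[edge]
  expect_true(all(abs(sin(ang)) < 1e-8))  # gradient along rows: angle 0 or pi

  d <- disk_image(41, c(21, 21), 10)
  gd <- gaussian_gradient(d, sigma = 1)
  edge <- which(gd$magnitude > 0.6 * max(gd$magnitude), arr.ind = TRUE)
  for (row in seq_len(nrow(edge))) {
    i <- edge[row, 1]; j <- edge[row, 2]
    radial <- atan2(j - 21, i - 21)
    delta <- abs(((gd$direction[i, j] - radial + pi / 2) %% pi) - pi / 2)
    expect_lt(delta, 5 * pi / 180)
  }
})

test_that("slice CHT peaks at the circle centre; radius mismatch weakens it", {
  e <- ideal_circle_edges(41, c(21, 21), 10)
  acc <- cht_slice(e$magnitude, e$direction, radii = 10)
  pk <- which(acc == max(acc), arr.ind = TRUE)
  expect_equal(as.numeric(pk[1, ]), c(21, 21))

  acc_wrong <- cht_slice(e$magnitude, e$direction, radii = 13)
  expect_lt(acc_wrong[21, 21], acc[21, 21])

  expect_true(all(cht_slice(matrix(0, 16, 16), matrix(0, 16, 16),
                            radii = 5) == 0))
})

test_that("gradient-limited CHT finds the same centre as the full-arc CHT", {
  e <- ideal_circle_edges(41, c(19, 23), 9)
  a1 <- cht_slice(e$magnitude, e$direction, radii = 9, arc_halfwidth = 0.35)
  a2 <- cht_slice(e$magnitude, e$direction, radii = 9, arc_halfwidth = pi)
  p1 <- which(a1 == max(a1), arr.ind = TRUE)[1, ]
  p2 <- which(a2 == max(a2), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(p1), c(19, 23))
  expect_equal(as.numeric(p1), as.numeric(p2))
})

test_that("accumulator peak translates with whole-pixel circle shifts", {
  e1 <- ideal_circle_edges(49, c(22, 24), 8)
  e2 <- ideal_circle_edges(49, c(27, 29), 8)  # shifted by (5, 5)
  a1 <- cht_slice(e1$magnitude, e1$direction, radii = 8)
  a2 <- cht_slice(e2$magnitude, e2$direction, radii = 8)
  p1 <- which(a1 == max(a1), arr.ind = TRUE)[1, ]
  p2 <- which(a2 == max(a2), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(p2 - p1), c(5, 5))
})

test_that("bidirectional blending favours spheres over cylinders", {
  n <- 40
  vs <- voxelize_sphere(as_volume(array(0, c(n, n, n))), c(19.6, 20.2, 19.8),
                        3.5, 1)
  acc_s <- cht_bidirectional(vs, 3.5)
  pk <- find_local_maxima(acc_s, 7, 0.5 * max(acc_s$data))
  expect_equal(nrow(pk), 1L)
  expect_lt(sqrt(sum((as.numeric(pk[1, 1:3]) - c(19.6, 20.2, 19.8))^2)),
            sqrt(3))  # within one voxel

  # cylinder along axis 1 with the same radius and contrast, rendered with
  # the same partial-volume subsampling, placed in the same volume so both
  # objects share the accumulator normalization
  m <- 64
  vb <- voxelize_sphere(as_volume(array(0, c(m, m, m))),
                        c(18.6, 20.2, 19.8), 3.5, 1)
  aa <- matrix(0, m, m)
  for (oj in c(-1, 0, 1) / 3) for (ok in c(-1, 0, 1) / 3)
    aa <- aa + (outer((0:(m - 1) + oj - 44.2)^2,
                      (0:(m - 1) + ok - 43.8)^2, "+") <= 3.5^2)
  aa <- aa / 9
  both <- vb$data
  for (i in 20:44) both[i, , ] <- pmax(both[i, , ], aa)
  acc_b <- cht_bidirectional(as_volume(both), 3.5)
  sphere_peak <- max(acc_b$data[15:25, 16:26, 15:25])
  cyl_peak <- max(acc_b$data[20:45, 40:49, 39:48])
  expect_lt(cyl_peak, sphere_peak)

  # empty volume: all-zero accumulator
  acc_0 <- cht_bidirectional(as_volume(array(0, c(20, 20, 20))), 3.5)
  expect_true(all(acc_0$data == 0))

  expect_error(cht_bidirectional(as_volume(array(0, c(10, 10, 10)),
                                           spacing = c(1, 1, 2)), 3.5),
               "resample")
})

test_that("hough detection is deterministic and respects the threshold", {
  ph <- small_phantom(s = 1.2)
  c1 <- detect_spheres_hough(ph$volume)
  c2 <- detect_spheres_hough(ph$volume)
  expect_identical(c1, c2)
  expect_gt(nrow(c1), 0)
  # a threshold at the maximum excludes everything (strict inequality)
  expect_equal(nrow(detect_spheres_hough(ph$volume, threshold_rel = 1)), 0L)
  expect_error(detect_spheres_hough(ph$volume, threshold_rel = 0), "threshold_rel")
})
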