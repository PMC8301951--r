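test_that("unsharp mask: constants, zero amount, step overshoot", {
  vc <- as_volume(array(4.2, c(10, 10, 10)))
  expect_equal(unsharp_mask(vc, 1, 1)$data, vc$data, tolerance = 1e-10)

  set.seed(4)
  v <- as_volume(array(stats::rnorm(10^3), c(10, 10, 10)))
  expect_equal(unsharp_mask(v, 1, 0)$data, v$data, tolerance = 1e-12)

  stepv <- as_volume(array(rep(c(0, 1), each = 10 * 16 * 16 / 2),
                           c(16, 16, 10)) * 0)
  stepv$data[, , 6:10] <- 1
  u <- unsharp_mask(stepv, 1, 1)
  expect_gt(max(u$data), 1)   # overshoot above the high level
  expect_lt(min(u$data), 0)   # undershoot below the low level
})

test_that("two-class Otsu separates two delta peaks", {
  counts <- rep(0, 64)
  counts[10] <- 500; counts[50] <- 300
  th <- multi_otsu_thresholds(counts, n_classes = 2)
  expect_gt(th, 10); expect_lt(th, 50)
})

test_that("four-class Otsu equals the exhaustive between-class-variance search", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- c(stats::rnorm(400, 10, 2), stats::rnorm(300, 30, 3),
           stats::rnorm(200, 45, 2), stats::rnorm(100, 58, 1.5))
    counts <- tabulate(findInterval(x, seq(0, 64, length.out = 65),
                                    all.inside = TRUE), nbins = 64)
    got <- multi_otsu_thresholds(counts, 4)
    ref_idx <- brute_otsu4(counts)
    ref <- (ref_idx + (ref_idx + 1)) / 2  # same midpoint convention
    expect_equal(got, ref)
  }
  expect_error(multi_otsu_thresholds(c(5, 0, 9, 0), 4), "degenerate")
  # appending empty bins does not move the thresholds
  set.seed(9)
  counts <- tabulate(findInterval(stats::rnorm(500, 20, 6), 0:40,
                                  all.inside = TRUE), nbins = 40)
  expect_equal(multi_otsu_thresholds(counts, 3),
               multi_otsu_thresholds(c(counts, rep(0, 10)), 3))
})

test_that("6-connected labelling: adjacency rules and block", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE  # share only an edge
  lc <- label_components(m)
  expect_equal(lc$n_components, 2L)

  blk <- array(FALSE, c(5, 5, 5)); blk[2:4, 2:4, 2:4] <- TRUE
  lcb <- label_components(blk)
  expect_equal(lcb$n_components, 1L)
  expect_equal(sum(lcb$label_map == 1), 27L)
  expect_error(label_components(array(2, c(3, 3, 3))), "binary")
})

test_that("labelling partitions equal the igraph flood-fill oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    m <- array(stats::runif(16^3) < 0.35, c(16, 16, 16))
    lc <- label_components(m)
    expect_true(same_partition(partition_sets(lc$label_map),
                               oracle_partition6(m)))
    # labels are 1..n with no gaps
    expect_setequal(unique(as.vector(lc$label_map[lc$label_map > 0])),
                    seq_len(lc$n_components))
  }
})

test_that("component features: radius identity, cube/sphere/rod roundness", {
  # axis-aligned cube: face counting is exact, roundness = (36 pi)^(1/3)/6
  cube <- array(FALSE, c(16, 16, 16)); cube[4:13, 4:13, 4:13] <- TRUE
  f <- component_features(label_components(cube))
  expect_equal(f$volume_mm3, 1000)
  expect_equal(f$equivalent_radius, (3 * 1000 / (4 * pi))^(1 / 3))
  expect_equal(f$roundness, (36 * pi)^(1 / 3) / 6, tolerance = 1e-9)
  expect_equal(as.numeric(f[1, c("x", "y", "z")]), c(7.5, 7.5, 7.5))

  # digitized spheres: stable plateau below 1, above the 0.6 filter default
  for (r in c(2.2, 3.5, 5, 5.8)) {
    fs <- component_features(label_components(ball_mask(r)))
    expect_lte(fs$roundness, 1)
    expect_gt(fs$roundness, 0.6)
    expect_lt(fs$roundness, 0.8)
  }

  # a thin rod scores far below both, and below the roundness filter
  rod <- array(FALSE, c(5, 5, 16)); rod[3, 3, 3:14] <- TRUE
  fr <- component_features(label_components(rod))
  expect_lt(fr$roundness, f$roundness)
  expect_lt(fr$roundness, 0.6)
})

test_that("anisotropic spacing is honoured by volume, area and centroid", {
  m <- array(FALSE, c(8, 8, 8)); m[3:4, 3:4, 3:4] <- TRUE
  v <- as_volume(m * 1.0, spacing = c(1, 2, 0.5), origin = c(10, 0, -5))
  f <- component_features(label_components(v))
  expect_equal(f$volume_mm3, 8 * 1 * 2 * 0.5)
  # 2x2x2 voxel box: physical edges 2 x 4 x 1 mm
  expect_equal(f$surface_area_mm2, 2 * (2 * 4 + 2 * 1 + 4 * 1))
  expect_equal(as.numeric(f[1, c("x", "y", "z")]),
               c(10 + 2.5 * 1, 0 + 2.5 * 2, -5 + 2.5 * 0.5))
})

test_that("CCA detection: phantom spheres found, bright rod rejected", {
  ph <- small_phantom(s = 1.6)
  v <- ph$volume
  # embed a bright 1x1x13-voxel rod whose equivalent radius passes the radius
  # filter at this voxel size; only the roundness filter can reject it
  rod_vox <- 13
  expect_lt(abs((3 * rod_vox * 1.6^3 / (4 * pi))^(1 / 3) - 3.5), 0.35 * 3.5)
  v$data[5, 5, 10:(9 + rod_vox)] <- 1
  rod_mm <- voxel_to_world(v, c(5, 5, 15))
  cand <- detect_spheres_cca(v)
  expect_gt(nrow(cand), 0)
  dd_rod <- sqrt((cand$x - rod_mm[1])^2 + (cand$y - rod_mm[2])^2 +
                   (cand$z - rod_mm[3])^2)
  expect_gt(min(dd_rod), 5)  # nothing detected at the rod

  # all-background volume: empty candidate list, not an error
  expect_equal(nrow(detect_spheres_cca(as_volume(array(0, c(12, 12, 12))))),
               0L)
})

test_that("CCA centroid error shrinks with the voxel size", {
  med <- vapply(c(0.8, 1.6), function(s) {
    ph <- small_phantom(s = s)
    ev <- evaluate_detections(detect_spheres_cca(ph$volume), ph$truth)
    stats::median(ev$ep_mm)
  }, numeric(1))
  expect_lt(med[1], med[2])
})
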