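test_that("volume construction enforces geometric invariants", {
  expect_error(as_volume(array(0, c(4, 4, 4)), spacing = c(1, 0, 1)),
               "spacing")
  expect_error(as_volume(array(0, c(4, 4, 4)), spacing = c(1, -1, 1)),
               "spacing")
  expect_error(as_volume(matrix(0, 4, 4)), "3 axes")
  v <- as_volume(array(0, c(2, 3, 4)), spacing = c(0.5, 1, 2),
                 origin = c(-1, 0, 3))
  expect_s3_class(v, "volume")
  expect_equal(dim(v), c(2L, 3L, 4L))
})

test_that("voxel/world conversion round-trips exactly for all indices", {
  set.seed(7)
  for (rep in 1:3) {
    sp <- stats::runif(3, 0.3, 2.5)
    or <- stats::rnorm(3, sd = 10)
    v <- as_volume(array(0, c(4, 5, 6)), spacing = sp, origin = or)
    idx <- as.matrix(expand.grid(1:4, 1:5, 1:6))
    back <- world_to_voxel(v, voxel_to_world(v, idx))
    expect_equal(unname(back), unname(idx), tolerance = 1e-12)
  }
  # first voxel centre sits at the origin
  v <- as_volume(array(0, c(3, 3, 3)), spacing = c(1, 1, 1),
                 origin = c(5, 6, 7))
  expect_equal(as.numeric(voxel_to_world(v, c(1, 1, 1))), c(5, 6, 7))
})

test_that("NIfTI and JSON volume I/O round-trips data and spacing", {
  set.seed(1)
  v <- as_volume(array(stats::rnorm(4 * 5 * 6), c(4, 5, 6)),
                 spacing = c(1, 1, 1))
  f <- tempfile(fileext = ".nii.gz")
  save_volume(v, f)
  v2 <- load_volume(f)
  expect_equal(v2$spacing, c(1, 1, 1))
  expect_equal(v2$data, v$data, tolerance = 1e-6)

  v3 <- as_volume(array(1:24, c(2, 3, 4)), spacing = c(0.6, 0.8, 1.0))
  f3 <- tempfile(fileext = ".nii.gz")
  save_volume(v3, f3)
  expect_equal(load_volume(f3)$spacing, c(0.6, 0.8, 1.0), tolerance = 1e-5)

  # JSON fixture with a zero spacing axis must fail naming the field
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(dim = c(2, 2, 2), spacing_mm = c(1, 0, 1),
                            data = rep(0, 8)), fj, auto_unbox = FALSE)
  expect_error(load_volume(fj), "spacing_mm")
  expect_error(load_volume("no/such/file.nii"), "no such file")
})

test_that("isotropic resampling preserves constants, identity and centroids", {
  set.seed(2)
  v <- as_volume(array(stats::rnorm(6^3), c(6, 6, 6)), spacing = c(1, 1, 1))
  same <- resample_isotropic(v, 1)
  expect_equal(same$data, v$data)

  vc <- as_volume(array(3.7, c(5, 7, 6)), spacing = c(1, 1.5, 0.7))
  rc <- resample_isotropic(vc, 0.9)
  expect_equal(rc$spacing, c(0.9, 0.9, 0.9))
  expect_true(all(abs(rc$data - 3.7) < 1e-12))
  # span of voxel centres preserved to within one voxel
  expect_lte(abs((dim(rc)[2] - 1) * 0.9 - (7 - 1) * 1.5), 0.9)

  # anisotropic sphere: intensity centroid preserved within half a voxel
  va <- as_volume(array(0, c(32, 32, 16)), spacing = c(1, 1, 2))
  ctr <- c(15.2, 16.1, 14.7)
  va <- voxelize_sphere(va, ctr, 5, 1)
  cen_w <- function(v) {
    idx <- which(v$data > 0)
    pos <- voxel_to_world(v, arrayInd(idx, dim(v$data)))
    colSums(pos * v$data[idx]) / sum(v$data[idx])
  }
  vi <- resample_isotropic(va, 1)
  expect_lt(sqrt(sum((cen_w(vi) - cen_w(va))^2)), 0.5 * 1)
})

test_that("intensity normalization: definition, idempotence, affine invariance", {
  set.seed(3)
  v <- as_volume(array(stats::rnorm(10^3, mean = 4, sd = 9), c(10, 10, 10)))
  n1 <- normalize_intensity(v)
  expect_lt(abs(mean(n1$data)), 1e-6)
  expect_lt(abs(stats::sd(n1$data) - 1), 1e-6)
  n2 <- normalize_intensity(n1)
  expect_equal(n2$data, n1$data, tolerance = 1e-6)
  vr <- as_volume(5 * v$data - 13, spacing = v$spacing)
  expect_equal(normalize_intensity(vr)$data, n1$data, tolerance = 1e-6)
  expect_error(normalize_intensity(as_volume(array(2, c(3, 3, 3)))),
               "constant")
})

test_that("local maxima: impulses, ties and the empty volume", {
  a <- array(0, c(11, 11, 11))
  a[6, 6, 6] <- 5
  v <- as_volume(a)
  m <- find_local_maxima(v, min_distance = 2, threshold = 1)
  expect_equal(nrow(m), 1L)
  expect_equal(as.numeric(m[1, 1:3]), c(5, 5, 5))  # mm of voxel (6,6,6)

  # two equal impulses closer than min_distance: lowest linear index wins
  a2 <- array(0, c(11, 11, 11))
  a2[4, 6, 6] <- 3; a2[6, 6, 6] <- 3
  m2 <- find_local_maxima(as_volume(a2), min_distance = 3, threshold = 0)
  expect_equal(nrow(m2), 1L)
  expect_equal(as.numeric(m2[1, 1:3]), c(3, 5, 5))

  # two unequal impulses closer than min_distance: the larger wins
  a2[4, 6, 6] <- 9
  m3 <- find_local_maxima(as_volume(a2), min_distance = 3, threshold = 0)
  expect_equal(as.numeric(m3[1, 1:3]), c(3, 5, 5))
  expect_equal(m3$value, 9)

  expect_equal(nrow(find_local_maxima(as_volume(array(0, c(8, 8, 8))),
                                      min_distance = 2, threshold = 0)), 0L)
})

test_that("local maxima agree with the exhaustive brute-force scan", {
  for (seed in 1:3) {
    set.seed(seed)
    a <- array(stats::rnorm(12^3), c(12, 12, 12))
    sp <- c(1, 1.3, 0.7)
    v <- as_volume(a, spacing = sp)
    thr <- stats::quantile(a, 0.85)
    got <- find_local_maxima(v, min_distance = 2.4, threshold = thr)
    ref <- brute_local_maxima(a, sp, 2.4, thr)
    expect_equal(nrow(got), nrow(ref))
    got_idx <- world_to_voxel(v, as.matrix(got[, 1:3]))
    expect_equal(unname(got_idx[order(got$value), , drop = FALSE]),
                 unname(ref[order(ref[, 4]), 1:3, drop = FALSE]),
                 tolerance = 1e-9)
  }
})
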