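#' Scale-space representation of a 2D slice
#'
#' Gaussian smoothing of the slice at scale index `t`, i.e. convolution with
#' the Gaussian of variance `sigma^2 = t` (pixels^2).
#'
#' @param slice numeric matrix.
#' @param t scale index (> 0), the Gaussian variance in pixel units.
#' @return smoothed matrix.
#' @export
scale_space_slice <- function(slice, t) {
  if (t <= 0) stop("scale index t must be > 0")
  slice <- as.matrix(slice)
  d <- c(dim(slice), 1L)
  g <- gaussian_kernel_1d(sqrt(t))
  matrix(cpp_conv_axis(cpp_conv_axis(slice, d, g, 1L), d, g, 2L),
         dim(slice)[1])
}

#' Scale-normalized determinant-of-Hessian response
#'
#' `t^2 * (Lxx * Lyy - Lxy^2)` with second derivatives of the scale-space
#' slice `L` taken by central differences. The `t^2` factor normalizes the
#' decreasing derivative magnitude across scales; bright blobs of radius
#' matched to the scale produce maxima at their centres.
#'
#' @param L scale-space slice from [scale_space_slice()].
#' @param t the scale index `L` was computed at.
#' @return response matrix of the same size. Central differences are
#'   undefined on the outermost row/column, which is set to zero, so
#'   constants and linear ramps give exactly zero response everywhere.
#' @export
doh_response <- function(L, t) {
  L <- as.matrix(L)
  n1 <- nrow(L); n2 <- ncol(L)
  if (n1 < 3 || n2 < 3) stop("slice too small for central differences")
  i <- 2:(n1 - 1); j <- 2:(n2 - 1)
  out <- matrix(0, n1, n2)
  Lxx <- L[i + 1, j] - 2 * L[i, j] + L[i - 1, j]
  Lyy <- L[i, j + 1] - 2 * L[i, j] + L[i, j - 1]
  Lxy <- (L[i + 1, j + 1] - L[i + 1, j - 1] - L[i - 1, j + 1] +
            L[i - 1, j - 1]) / 4
  out[i, j] <- t^2 * (Lxx * Lyy - Lxy^2)
  out
}

# single characteristic scale for a blob radius in voxels: r = sigma*sqrt(2)
blob_scale_index <- function(radius_vox) radius_vox^2 / 2

#' Slice-wise determinant-of-Hessian blob candidates
#'
#' Computes the 2D determinant-of-Hessian response at the single
#' characteristic scale index `t = (r/s)^2 / 2` on every slice perpendicular
#' to `slice_axis`, stacks the responses into 3D, and returns *all* local
#' maxima with positive response within a marker-radius-sized neighbourhood.
#' The step is deliberately permissive — candidate counts in the hundreds or
#' thousands are expected — and is followed by moment-descriptor filtering.
#'
#' @param v an isotropic [volume][as_volume].
#' @param radius_mm blob (sphere) radius in mm.
#' @param slice_axis axis perpendicular to the processed slices.
#' @param scale_index optional override of the scale index `t`.
#' @return data.frame with candidate positions (`x`, `y`, `z`, mm) and the
#'   DoH `value`.
#' @export
blob_candidates <- function(v, radius_mm, slice_axis = 1,
                            scale_index = NULL) {
  stopifnot_volume(v)
  if (!is_isotropic(v))
    stop("volume is anisotropic; resample_isotropic() it first")
  s <- v$spacing[1]
  r_vox <- radius_mm / s
  t <- if (is.null(scale_index)) blob_scale_index(r_vox) else scale_index
  if (t <= 0) stop("scale index must be > 0")
  inplane <- setdiff(1:3, slice_axis)
  d <- dim(v$data)
  g <- gaussian_kernel_1d(sqrt(t))
  L <- cpp_conv_axis(cpp_conv_axis(v$data, d, g, inplane[1]), d, g,
                     inplane[2])
  L <- array(L, dim = d)
  resp <- array(0, dim = d)
  for (sl in seq_len(d[slice_axis])) {
    resp <- slice_set(resp, slice_axis, sl,
                      doh_response(slice_get(L, slice_axis, sl), t))
  }
  # suppress padding artifacts: blank an in-plane border of ~sigma voxels
  mrg <- min(max(2L, ceiling(sqrt(t))), floor((min(d[inplane]) - 1) / 2))
  for (ax in inplane) {
    n <- d[ax]
    edge <- c(seq_len(mrg), seq(n - mrg + 1L, n))
    resp <- slice_set_many(resp, ax, edge, 0)
  }
  rv <- as_volume(resp, spacing = v$spacing, origin = v$origin)
  find_local_maxima(rv, min_distance = radius_mm, threshold = 0)
}

#' Normalized second-order central moment descriptor
#'
#' Intensity-weighted covariance of position about the intensity centroid,
#' computed over the cubic neighbourhood of half-size `radius_mm` around
#' `center` (clipped at the volume border) and normalized by the total
#' intensity. For a uniform solid sphere of radius R the matrix tends to
#' `(R^2/5) I`, so the trace tends to `3 R^2 / 5`; the descriptor is invariant
#' to scaling of the intensities.
#'
#' @param v a [volume][as_volume] (raw intensities; negative values are
#'   clamped to zero for the weighting).
#' @param center mm position of the neighbourhood centre.
#' @param radius_mm neighbourhood half-size in mm.
#' @return list with `moments` (symmetric 3x3, mm^2), `components` (named
#'   6-vector: xx, yy, zz, xy, xz, yz), `size` (trace) and `degenerate`
#'   (TRUE when the window has no intensity mass).
#' @export
moment_descriptor <- function(v, center, radius_mm) {
  stopifnot_volume(v)
  d <- dim(v$data)
  lo <- pmax(ceiling(world_to_voxel(v, center - radius_mm)), 1)
  hi <- pmin(floor(world_to_voxel(v, center + radius_mm)), d)
  if (any(lo > hi)) stop("neighbourhood does not intersect the volume")
  ii <- seq(lo[1], hi[1]); jj <- seq(lo[2], hi[2]); kk <- seq(lo[3], hi[3])
  wgt <- pmax(v$data[ii, jj, kk, drop = FALSE], 0)
  tot <- sum(wgt)
  if (tot <= 0) {
    return(list(moments = matrix(NA_real_, 3, 3),
                components = stats::setNames(rep(NA_real_, 6),
                                             c("xx", "yy", "zz", "xy", "xz", "yz")),
                size = NA_real_, degenerate = TRUE))
  }
  px <- v$origin[1] + (ii - 1) * v$spacing[1]
  py <- v$origin[2] + (jj - 1) * v$spacing[2]
  pz <- v$origin[3] + (kk - 1) * v$spacing[3]
  wx <- apply(wgt, 1, sum); wy <- apply(wgt, 2, sum); wz <- apply(wgt, 3, sum)
  mx <- sum(wx * px) / tot; my <- sum(wy * py) / tot; mz <- sum(wz * pz) / tot
  dx <- px - mx; dy <- py - my; dz <- pz - mz
  m_xx <- sum(wx * dx^2) / tot
  m_yy <- sum(wy * dy^2) / tot
  m_zz <- sum(wz * dz^2) / tot
  # cross terms: marginalize the third axis, then weight the outer product
  wxy <- apply(wgt, c(1, 2), sum)
  wxz <- apply(wgt, c(1, 3), sum)
  wyz <- apply(wgt, c(2, 3), sum)
  m_xy <- sum(wxy * outer(dx, dy)) / tot
  m_xz <- sum(wxz * outer(dx, dz)) / tot
  m_yz <- sum(wyz * outer(dy, dz)) / tot
  M <- matrix(c(m_xx, m_xy, m_xz,
                m_xy, m_yy, m_yz,
                m_xz, m_yz, m_zz), 3, 3)
  list(moments = M,
       components = c(xx = m_xx, yy = m_yy, zz = m_zz, xy = m_xy, xz = m_xz,
                      yz = m_yz),
       size = m_xx + m_yy + m_zz, degenerate = FALSE)
}

#' Select the marker cluster among moment descriptors
#'
#' Classifies the descriptors by k-means according to their *size* (the
#' moment trace) for k = 1..`k_max`, picks k at the knee of the
#' total-within-inertia curve (the point of maximum distance to the chord
#' between the curve's endpoints), and returns the indices of the cluster
#' whose mean size is closest to `characteristic_size`. True marker spheres
#' share one size and shape, so they form an extremely tight size cluster.
#' Deterministic under a fixed `seed`. `features = "components"` clusters in
#' the full 6-dimensional moment space instead.
#'
#' @param descriptors numeric matrix (n x 6) of descriptor components (as
#'   from [moment_descriptor()]`$components`), or a list of
#'   [moment_descriptor()] results.
#' @param characteristic_size expected moment trace of a true marker sphere
#'   (`3 * radius_mm^2 / 5` for a solid sphere).
#' @param k_max largest cluster count probed.
#' @param seed RNG seed for the k-means restarts.
#' @param features cluster on the scalar `"size"` (default) or on the 6
#'   moment `"components"`.
#' @return integer indices of the selected descriptors.
#' @export
cluster_select <- function(descriptors, characteristic_size, k_max = 8,
                           seed = 0, features = c("size", "components")) {
  features <- match.arg(features)
  if (is.list(descriptors) && !is.matrix(descriptors))
    descriptors <- do.call(rbind, lapply(descriptors, `[[`, "components"))
  X <- as.matrix(descriptors)
  n <- nrow(X)
  if (n < 2) return(seq_len(n))
  sizes <- X[, "xx"] + X[, "yy"] + X[, "zz"]
  F <- if (features == "size") matrix(sizes, ncol = 1) else X
  n_distinct <- nrow(unique(F))
  kmax <- max(1L, min(k_max, n_distinct, n - 1L))
  if (kmax == 1L) return(seq_len(n))
  # a single tight group: rms spread negligible against the marker size
  if (sqrt(sum(scale(F, scale = FALSE)^2) / n) < 0.05 * characteristic_size)
    return(seq_len(n))
  withr::with_seed(seed, {
    fits <- lapply(seq_len(kmax), function(k) {
      stats::kmeans(F, centers = k, nstart = 10, iter.max = 100)
    })
    inertia <- vapply(fits, function(f) f$tot.withinss, numeric(1))
    k_best <- knee_point(inertia)
    fit <- fits[[k_best]]
    size_per_cluster <- vapply(seq_len(k_best), function(c) {
      mean(sizes[fit$cluster == c])
    }, numeric(1))
    winner <- which.min(abs(size_per_cluster - characteristic_size))
    which(fit$cluster == winner)
  })
}

# knee of a decreasing curve: maximum distance to the chord between endpoints
knee_point <- function(y) {
  n <- length(y)
  if (n <= 2) return(n)
  x <- seq_len(n)
  x0 <- c(x[1], y[1]); x1 <- c(x[n], y[n])
  chord <- x1 - x0
  cn <- sqrt(sum(chord^2))
  if (cn == 0) return(1L)
  dist <- abs(chord[2] * (x - x0[1]) - chord[1] * (y - x0[2])) / cn
  which.max(dist)
}

#' Detect spheres with the determinant-of-Hessian blob pipeline
#'
#' [blob_candidates()] (permissive, slice-wise DoH at one characteristic
#' scale) -> [moment_descriptor()] in a marker-radius-sized neighbourhood of
#' every candidate -> [cluster_select()] against the analytic solid-sphere
#' trace `3 * radius_mm^2 / 5`. Residual false positives are expected to be
#' removed downstream by the marker pairing model, as for all detectors.
#'
#' @param v an isotropic [volume][as_volume].
#' @param radius_mm sphere radius in mm.
#' @param k_max,seed clustering controls, see [cluster_select()].
#' @param scale_index,slice_axis DoH controls, see [blob_candidates()].
#' @return data.frame of candidates with `score` = DoH response.
#' @export
detect_spheres_blob <- function(v, radius_mm = 3.5, k_max = 8, seed = 0,
                                scale_index = NULL, slice_axis = 1) {
  cand <- blob_candidates(v, radius_mm, slice_axis = slice_axis,
                          scale_index = scale_index)
  if (nrow(cand) == 0) return(empty_candidates("blob"))
  desc <- lapply(seq_len(nrow(cand)), function(i) {
    moment_descriptor(v, c(cand$x[i], cand$y[i], cand$z[i]), radius_mm)
  })
  valid <- !vapply(desc, `[[`, logical(1), "degenerate")
  cand <- cand[valid, , drop = FALSE]
  desc <- desc[valid]
  if (nrow(cand) == 0) return(empty_candidates("blob"))
  sel <- cluster_select(desc, characteristic_size = 3 * radius_mm^2 / 5,
                        k_max = k_max, seed = seed)
  cand <- cand[sel, , drop = FALSE]
  candidates_df(cand, "blob")
}
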