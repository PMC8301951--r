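#' Gaussian gradient of a 2D slice
#'
#' First-order derivative-of-Gaussian edge detection: the slice is correlated
#' with a Gaussian derivative along each in-plane axis (and smoothed with a
#' Gaussian along the other), giving the gradient magnitude and per-pixel
#' gradient angle.
#'
#' @param slice numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return list with `magnitude` and `direction` matrices; `direction` is the
#'   gradient angle `atan2(gy, gx)` in radians.
#' @export
gaussian_gradient <- function(slice, sigma = 1) {
  if (sigma <= 0) stop("sigma must be > 0")
  slice <- as.matrix(slice)
  d <- c(dim(slice), 1L)
  g <- gaussian_kernel_1d(sigma)
  dg <- gaussian_deriv_1d(sigma)
  gx <- cpp_conv_axis(cpp_conv_axis(slice, d, dg, 1L), d, g, 2L)
  gy <- cpp_conv_axis(cpp_conv_axis(slice, d, g, 1L), d, dg, 2L)
  gx <- matrix(gx, dim(slice)[1])
  gy <- matrix(gy, dim(slice)[1])
  list(magnitude = sqrt(gx^2 + gy^2), direction = atan2(gy, gx))
}

#' Gradient-limited circular Hough transform of one slice
#'
#' Every edge pixel with gradient magnitude above `threshold` casts votes
#' along its gradient direction +/- `arc_halfwidth`, both inward and outward,
#' at every probed radius. Votes for all radii are collected in a single 2D
#' accumulator.
#'
#' @param magnitude,direction gradient maps from [gaussian_gradient()].
#' @param radii circle radii in pixels (all >= 1).
#' @param arc_halfwidth half-width of the voting arc in radians. `pi` gives
#'   the classical full-circle (gradient-free) transform.
#' @param threshold gradient magnitude a pixel must exceed to vote.
#' @return accumulator matrix of the same size as the slice.
#' @export
cht_slice <- function(magnitude, direction, radii, arc_halfwidth = 0.35,
                      threshold = 0) {
  if (length(radii) == 0 || any(radii < 1))
    stop("radii must be a non-empty set of pixel radii >= 1")
  cpp_cht_votes(as.matrix(magnitude), as.matrix(direction),
                as.numeric(radii), arc_halfwidth, threshold)
}

# radii probed for a physical radius on an isotropic grid: nominal +/- 1 voxel
cht_radii_vox <- function(radius_mm, s) {
  r <- round(radius_mm / s)
  unique(pmax(1, c(r - 1, r, r + 1)))
}

#' Bidirectional slice-wise circular Hough transform
#'
#' Runs the gradient-limited 2D circular Hough transform independently over
#' slice stacks perpendicular to two (or more) orthogonal axes of an isotropic
#' volume, reassembles the per-slice accumulators into 3D vote volumes,
#' normalizes each stack to `[0, 1]` and blends the stacks by elementwise
#' multiplication. Multiplicative blending reinforces objects that appear
#' circular in *every* slicing direction (spheres) over objects circular in
#' only one (for example cylinders).
#'
#' @param v an isotropic [volume][as_volume] (resample first if needed).
#' @param radius_mm sphere radius in mm; must exceed the voxel size.
#' @param axes which slice stacks to use (default the first two axes).
#' @param arc_halfwidth voting arc half-width in radians.
#' @param edge_quantile per-stack quantile of the nonzero gradient magnitudes
#'   above which pixels vote.
#' @param sigma gradient smoothing in pixels.
#' @return a [volume][as_volume] whose data are the blended votes.
#' @export
cht_bidirectional <- function(v, radius_mm, axes = c(1, 2),
                              arc_halfwidth = 0.35, edge_quantile = 0.95,
                              sigma = 1) {
  stopifnot_volume(v)
  if (!is_isotropic(v))
    stop("volume is anisotropic; resample_isotropic() it first")
  s <- v$spacing[1]
  if (radius_mm <= s) stop("radius_mm must exceed the voxel size")
  if (length(axes) < 1 || any(!axes %in% 1:3)) stop("axes must be within 1:3")
  radii <- cht_radii_vox(radius_mm, s)
  d <- dim(v$data)
  blended <- NULL
  for (ax in axes) {
    inplane <- setdiff(1:3, ax)
    g <- gaussian_kernel_1d(sigma)
    dg <- gaussian_deriv_1d(sigma)
    gx <- cpp_conv_axis(cpp_conv_axis(v$data, d, dg, inplane[1]), d, g,
                        inplane[2])
    gy <- cpp_conv_axis(cpp_conv_axis(v$data, d, g, inplane[1]), d, dg,
                        inplane[2])
    mag <- array(sqrt(gx^2 + gy^2), dim = d)
    dir <- array(atan2(gy, gx), dim = d)
    nz <- mag[mag > 0]
    thr <- if (length(nz)) stats::quantile(nz, edge_quantile, names = FALSE)
           else Inf
    acc <- array(0, dim = d)
    for (sl in seq_len(d[ax])) {
      msl <- slice_get(mag, ax, sl)
      if (!any(msl > thr)) next
      a2 <- cpp_cht_votes(msl, slice_get(dir, ax, sl), radii, arc_halfwidth,
                          thr)
      acc <- slice_set(acc, ax, sl, a2)
    }
    mx <- max(acc)
    if (mx > 0) acc <- acc / mx
    blended <- if (is.null(blended)) acc else blended * acc
  }
  as_volume(blended, spacing = v$spacing, origin = v$origin)
}

slice_get <- function(a, ax, i) {
  switch(ax, a[i, , ], a[, i, ], a[, , i])
}

slice_set <- function(a, ax, i, val) {
  switch(ax,
         { a[i, , ] <- val; a },
         { a[, i, ] <- val; a },
         { a[, , i] <- val; a })
}

slice_set_many <- function(a, ax, idx, val) {
  switch(ax,
         { a[idx, , ] <- val; a },
         { a[, idx, ] <- val; a },
         { a[, , idx] <- val; a })
}

#' Detect spheres with the bidirectional circular Hough transform
#'
#' @param v an isotropic [volume][as_volume].
#' @param radius_mm sphere radius in mm.
#' @param threshold_rel fraction of the accumulator maximum a local maximum
#'   must exceed, in (0, 1].
#' @param acc_smooth_vox Gaussian smoothing (in voxels) applied to the
#'   blended accumulator before peak picking. Votes are drawn on a discrete
#'   grid, so the raw peak voxel can sit one voxel off the circle centre;
#'   mild smoothing regularizes the vote counts (0 disables it). Candidate
#'   positions are still voxel centres.
#' @param ... further arguments passed to [cht_bidirectional()].
#' @return data.frame of candidates with columns `x`, `y`, `z` (mm), `score`
#'   and `method = "hough"`.
#' @export
detect_spheres_hough <- function(v, radius_mm = 3.5, threshold_rel = 0.3,
                                 acc_smooth_vox = 0.6, ...) {
  if (threshold_rel <= 0 || threshold_rel > 1)
    stop("threshold_rel must be in (0, 1]")
  acc <- cht_bidirectional(v, radius_mm, ...)
  if (acc_smooth_vox > 0)
    acc <- gaussian_blur(acc, acc_smooth_vox * acc$spacing[1])
  mx <- max(acc$data)
  if (mx <= 0) return(empty_candidates("hough"))
  peaks <- find_local_maxima(acc, min_distance = 2 * radius_mm,
                             threshold = threshold_rel * mx)
  candidates_df(peaks, "hough")
}

empty_candidates <- function(method) {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             score = numeric(0), method = character(0))
}

candidates_df <- function(peaks, method) {
  if (nrow(peaks) == 0) return(empty_candidates(method))
  data.frame(x = peaks$x, y = peaks$y, z = peaks$z, score = peaks$value,
             method = method)
}
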