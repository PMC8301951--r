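#' Outside weight of the spherical matching kernel
#'
#' The kernel's outside elements take a voxel-size-dependent negative weight
#' `kout = -0.5 - 1 / (1 + exp(-c * (1 - sv)))`, a logistic in the voxel size
#' `sv` with steepness `c = 3`. The value increases monotonically with `sv`
#' and stays strictly within `(-1.5, -0.5)`; at `sv = 1` mm it equals `-1`.
#' Coarser grids (larger `sv`) thus penalize the sphere surroundings less,
#' compensating for the stronger partial-volume mixing at the sphere border.
#'
#' @param sv voxel size in mm (> 0); vectorized.
#' @param c logistic steepness (default 3).
#' @return outside weight(s) in (-1.5, -0.5).
#' @export
kout_value <- function(sv, c = 3) {
  if (any(sv <= 0)) stop("sv must be > 0")
  -0.5 - 1 / (1 + exp(-c * (1 - sv)))
}

#' Build a two-valued spherical matching kernel
#'
#' The kernel is a cuboid of odd size per axis with half-size
#' `floor(radius_mm / spacing)` voxels, so a 3.5 mm sphere at 1 mm isotropic
#' spacing gives the typical 7x7x7 kernel. Elements whose centre lies within
#' `radius_mm` of the kernel centre get the inside weight `kin = 1` (the
#' matched inside ball), all others [kout_value()] of the smallest voxel
#' size. Anisotropic spacings yield cuboidal kernels.
#'
#' @param radius_mm sphere radius in mm; must exceed half the largest voxel
#'   size.
#' @param spacing voxel size in mm (scalar or per axis).
#' @return object of class `sphere_kernel`: list with `weights` (3D array),
#'   `kin`, `kout`, `spacing`, `halfsize`.
#' @export
build_sphere_kernel <- function(radius_mm, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (radius_mm <= max(spacing) / 2)
    stop("radius_mm must exceed half the voxel size")
  h <- pmax(1L, floor(radius_mm / spacing))
  kin <- 1.0
  kout <- kout_value(min(spacing))
  ax <- lapply(1:3, function(a) (seq(-h[a], h[a]) * spacing[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  w <- array(kout, dim = 2 * h + 1)
  w[d2 <= radius_mm^2] <- kin
  structure(list(weights = w, kin = kin, kout = kout, spacing = spacing,
                 halfsize = h),
            class = "sphere_kernel")
}

#' @export
print.sphere_kernel <- function(x, ...) {
  cat(sprintf("<sphere_kernel> %s, kin = %g, kout = %.4f (%d inside elements)\n",
              paste(dim(x$weights), collapse = "x"), x$kin, x$kout,
              sum(x$weights == x$kin)))
  invisible(x)
}

#' Valid-region 3D convolution of a volume with a sphere kernel
#'
#' Discrete convolution `I*(i,j,k) = sum F(u,v,w) I(i-u, j-v, k-w)`; regions
#' whose computation would involve values outside the volume are cropped, so
#' the output shrinks by the kernel half-size on every face (the origin is
#' shifted accordingly, keeping physical coordinates aligned with the input).
#' The kernel is symmetric, so this equals cross-correlation. With
#' `rescale = TRUE` the result is mapped affinely onto `[0, 1]`.
#'
#' @param v a [volume][as_volume].
#' @param k a [build_sphere_kernel()] kernel (or any odd-sized 3D array).
#' @param rescale min-max rescale the response to `[0, 1]`.
#' @return the response [volume][as_volume] (cropped).
#' @export
convolve3d <- function(v, k, rescale = TRUE) {
  stopifnot_volume(v)
  w <- if (inherits(k, "sphere_kernel")) k$weights else as.array(k)
  if (any(dim(w) %% 2 == 0)) stop("kernel must be odd-sized on every axis")
  if (any(dim(w) >= dim(v$data)))
    stop("kernel must be smaller than the volume on every axis")
  out <- cpp_conv3d_valid(as.numeric(v$data), dim(v$data), as.numeric(w),
                          dim(w))
  h <- (dim(w) - 1) / 2
  if (rescale) {
    rng <- range(out)
    out <- if (diff(rng) > 0) (out - rng[1]) / diff(rng) else out * 0
  }
  as_volume(array(out, dim = dim(v$data) - dim(w) + 1),
            spacing = v$spacing, origin = v$origin + h * v$spacing)
}

#' Detect spheres by matched spherical-kernel convolution
#'
#' Normalizes the volume intensities to zero mean and unit variance, convolves
#' with the two-valued spherical kernel adapted to the voxel size, and takes
#' local maxima of the `[0, 1]`-rescaled response. Because of the intensity
#' normalization, detection is invariant to affine rescaling of the input
#' intensities.
#'
#' @param v a [volume][as_volume].
#' @param radius_mm sphere radius in mm.
#' @param threshold_rel fraction of the maximum response a local maximum must
#'   exceed, in (0, 1].
#' @return data.frame of candidates (`x`, `y`, `z` in the *original* frame,
#'   `score`, `method = "kernel"`).
#' @export
detect_spheres_kernel <- function(v, radius_mm = 3.5, threshold_rel = 0.5) {
  if (threshold_rel <= 0 || threshold_rel > 1)
    stop("threshold_rel must be in (0, 1]")
  vn <- normalize_intensity(v)
  k <- build_sphere_kernel(radius_mm, vn$spacing)
  resp <- convolve3d(vn, k, rescale = TRUE)
  mx <- max(resp$data)
  if (mx <= 0) return(empty_candidates("kernel"))
  peaks <- find_local_maxima(resp, min_distance = 2 * radius_mm,
                             threshold = threshold_rel * mx)
  candidates_df(peaks, "kernel")
}
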