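#' Construct a volume object
#'
#' A `volume` is a 3D scalar grid together with its physical geometry: the
#' per-axis voxel size in mm and the physical position (mm) of the *centre* of
#' voxel `(1,1,1)`. Voxel `(i,j,k)` (1-based) is centred at
#' `origin + (i-1, j-1, k-1) * spacing`, so voxel and world coordinates are
#' exactly interconvertible for voxel centres.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, mm position of the centre of voxel (1,1,1).
#' @return An object of class `volume` (a list with `data`, `spacing`,
#'   `origin`).
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must have exactly 3 axes")
  if (any(dim(data) < 1L))
    stop("every volume axis must have length >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive voxel sizes in mm")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite length-3 mm coordinate")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = ", "),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "volume")

stopifnot_volume <- function(v) {
  if (!is_volume(v)) stop("expected a 'volume' object; see as_volume()")
  invisible(v)
}

#' Convert voxel indices to world (mm) coordinates
#'
#' @param v a [volume][as_volume].
#' @param idx integer matrix (n x 3) or length-3 vector of 1-based voxel
#'   indices.
#' @return n x 3 matrix of mm positions of the voxel centres.
#' @export
voxel_to_world <- function(v, idx) {
  stopifnot_volume(v)
  idx <- rbind_coords(idx)
  sweep(sweep(idx - 1, 2, v$spacing, "*"), 2, v$origin, "+")
}

#' Convert world (mm) coordinates to (fractional) voxel indices
#'
#' Exact inverse of [voxel_to_world()] for voxel centres.
#'
#' @param v a [volume][as_volume].
#' @param pts numeric matrix (n x 3) or length-3 vector of mm positions.
#' @return n x 3 matrix of 1-based (fractional) voxel indices.
#' @export
world_to_voxel <- function(v, pts) {
  stopifnot_volume(v)
  pts <- rbind_coords(pts)
  sweep(sweep(pts, 2, v$origin, "-"), 2, v$spacing, "/") + 1
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  as.matrix(x)
}

#' Read a volume from disk
#'
#' Reads NIfTI-1 files (`.nii`, `.nii.gz`) via RNifti, taking the voxel size
#' from the header `pixdim` and the origin from the stored transform; or a
#' plain-text JSON fixture with fields `dim`, `spacing_mm`, optional
#' `origin_mm` and flattened `data` (column-major).
#'
#' @param path file path.
#' @return a [volume][as_volume].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(js$spacing_mm)) stop("fixture is missing field 'spacing_mm'")
    if (any(!is.finite(js$spacing_mm)) || any(js$spacing_mm <= 0))
      stop("fixture field 'spacing_mm' must be positive")
    origin <- if (is.null(js$origin_mm)) c(0, 0, 0) else js$origin_mm
    return(as_volume(array(as.numeric(js$data), dim = js$dim),
                     spacing = js$spacing_mm, origin = origin))
  }
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(img)), " axes")
  spacing <- attr(img, "pixdim")[seq_len(3)]
  if (is.null(spacing) || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI header field 'pixdim' is missing or non-positive")
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  as_volume(array(as.numeric(img), dim = dim(img)), spacing = spacing,
            origin = origin)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param v a [volume][as_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(v, path) {
  stopifnot_volume(v)
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  xf <- diag(4)
  diag(xf)[1:3] <- v$spacing
  xf[1:3, 4] <- v$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume to an isotropic voxel size
#'
#' Trilinear (separable linear) interpolation onto a grid with the requested
#' isotropic spacing. The first output voxel centre coincides with the first
#' input voxel centre and the span of voxel centres is preserved to within one
#' voxel, so physical coordinates are directly comparable before and after.
#'
#' @param v a [volume][as_volume].
#' @param target isotropic voxel size in mm (> 0).
#' @return resampled [volume][as_volume] with `spacing = c(target, target,
#'   target)`.
#' @export
resample_isotropic <- function(v, target) {
  stopifnot_volume(v)
  if (!is.numeric(target) || length(target) != 1L || target <= 0)
    stop("target spacing must be a single positive mm value")
  d <- dim(v$data)
  out <- v$data
  for (ax in 1:3) {
    n_new <- max(1L, floor((d[ax] - 1L) * v$spacing[ax] / target) + 1L)
    if (n_new == d[ax] && isTRUE(all.equal(v$spacing[ax], target))) next
    pos <- (seq_len(n_new) - 1) * target / v$spacing[ax]  # 0-based frac index
    i0 <- pmin(pmax(floor(pos), 0), d[ax] - 1L)
    i1 <- pmin(i0 + 1, d[ax] - 1L)
    w <- pos - i0
    out <- interp_axis(out, ax, i0 + 1L, i1 + 1L, w)
    d <- dim(out)
  }
  as_volume(out, spacing = rep(target, 3), origin = v$origin)
}

# linear interpolation of an array along one axis given index pairs + weights
interp_axis <- function(a, ax, i0, i1, w) {
  idx0 <- switch(ax,
                 a[i0, , , drop = FALSE],
                 a[, i0, , drop = FALSE],
                 a[, , i0, drop = FALSE])
  idx1 <- switch(ax,
                 a[i1, , , drop = FALSE],
                 a[, i1, , drop = FALSE],
                 a[, , i1, drop = FALSE])
  d <- dim(idx0)
  warr <- switch(ax,
                 array(w, dim = d),
                 array(rep(w, each = d[1]), dim = d),
                 array(rep(w, each = d[1] * d[2]), dim = d))
  idx0 * (1 - warr) + idx1 * warr
}

#' Normalize volume intensities to zero mean, unit standard deviation
#'
#' @param v a [volume][as_volume] with non-constant intensities.
#' @return normalized [volume][as_volume].
#' @export
normalize_intensity <- function(v) {
  stopifnot_volume(v)
  s <- stats::sd(v$data)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: constant intensity volume cannot be normalized")
  as_volume((v$data - mean(v$data)) / s, spacing = v$spacing,
            origin = v$origin)
}

#' Find local maxima of a volume under a physical-distance constraint
#'
#' A voxel is reported when its value exceeds `threshold`, it is >= every
#' voxel within a Euclidean `min_distance` (mm) neighbourhood, and no two
#' reported maxima are closer than `min_distance`. Plateau ties are broken
#' toward the smallest linear voxel index; suppression is greedy in order of
#' decreasing value. Positions are the mm coordinates of the voxel centres.
#'
#' @param v a [volume][as_volume].
#' @param min_distance minimum separation in mm (> 0).
#' @param threshold strict lower bound on reported values.
#' @return data.frame with columns `x`, `y`, `z` (mm) and `value`.
#' @export
find_local_maxima <- function(v, min_distance, threshold) {
  stopifnot_volume(v)
  if (!is.numeric(min_distance) || min_distance <= 0)
    stop("min_distance must be > 0")
  m <- cpp_local_maxima(as.numeric(v$data), dim(v$data), v$spacing,
                        min_distance, threshold)
  if (nrow(m) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      value = numeric(0)))
  pos <- voxel_to_world(v, m[, 1:3, drop = FALSE])
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], value = m[, 4])
}

is_isotropic <- function(v, tol = 1e-6) {
  diff(range(v$spacing)) <= tol * mean(v$spacing)
}

# 1D Gaussian kernel (unit sum), sigma in voxels
gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D Gaussian first-derivative kernel, sigma in voxels.
# Normalized so that correlation with a unit ramp gives slope 1.
gaussian_deriv_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- x * g
  k / sum(x * k)
}

# separable Gaussian smoothing of a 3D array; sigma in voxels per axis,
# sigma[i] = 0 skips axis i
gauss_smooth3 <- function(a, sigma) {
  d <- dim(a)
  for (ax in 1:3) {
    if (sigma[ax] > 0 && d[ax] > 1)
      a <- cpp_conv_axis(a, d, gaussian_kernel_1d(sigma[ax]), ax)
  }
  array(a, dim = d)
}

#' Gaussian blur of a volume
#'
#' Separable Gaussian smoothing with a physically specified width.
#'
#' @param v a [volume][as_volume].
#' @param sigma_mm Gaussian standard deviation in mm (scalar or per axis).
#' @return blurred [volume][as_volume].
#' @export
gaussian_blur <- function(v, sigma_mm) {
  stopifnot_volume(v)
  if (length(sigma_mm) == 1L) sigma_mm <- rep(sigma_mm, 3)
  if (any(sigma_mm < 0)) stop("sigma_mm must be >= 0")
  as_volume(gauss_smooth3(v$data, sigma_mm / v$spacing),
            spacing = v$spacing, origin = v$origin)
}
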