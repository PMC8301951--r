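#' Phantom specification
#'
#' Describes a synthetic head-and-marker acquisition: a bright ellipsoidal
#' "head" inside a dark background, and `n_markers` two-sphere fiducial
#' markers mounted just off the head surface. Each marker consists of two
#' bright spheres of radius `sphere_radius` whose centres are exactly
#' `pair_spacing` apart, each embedded in a dark concentric spherical shell
#' that emulates the marker housing. Marker axes are drawn uniformly on the
#' sphere so detection is exercised in arbitrary orientation; ground-truth
#' sphere centres are continuous positions, never snapped to the voxel grid.
#'
#' @param voxel_size isotropic voxel size in mm.
#' @param n_markers number of two-sphere markers.
#' @param sphere_radius sphere radius in mm.
#' @param pair_spacing centre-to-centre distance of the two spheres of one
#'   marker, mm. Must exceed `2 * sphere_radius`.
#' @param sphere_intensity,shell_intensity,head_intensity,background_intensity
#'   intensities (arbitrary units, pre-normalization). The housing shell
#'   defaults to the background intensity: the marker housing gives no MRI
#'   signal, so in a realistic acquisition it is as dark as air. (A shell
#'   distinctly brighter than the background would form its own histogram
#'   class, which no real acquisition shows and which defeats
#'   background/foreground thresholding.)
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed controlling placement and noise.
#' @param volume_mm physical edge lengths of the volume (length 3), mm.
#' @param head_semiaxes semi-axes of the head ellipsoid, mm.
#' @param shell_thickness radial thickness of the dark housing shell, mm.
#' @param standoff_mm distance from the head surface to the marker midpoint,
#'   along the outward surface direction, mm.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_size = 1.0, n_markers = 5L,
                         sphere_radius = 3.5, pair_spacing = 11.0,
                         sphere_intensity = 1.0, shell_intensity = 0.0,
                         head_intensity = 0.5, background_intensity = 0.0,
                         noise_sd = 0.02, seed = 1L,
                         volume_mm = c(80, 80, 80),
                         head_semiaxes = c(18, 20, 22),
                         shell_thickness = 2.5,
                         standoff_mm = 12.5) {
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  if (sphere_radius <= 0) stop("sphere_radius must be > 0")
  if (pair_spacing <= 2 * sphere_radius)
    stop("pair_spacing must exceed the sphere diameter (spheres must not overlap)")
  if (n_markers < 1) stop("n_markers must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(voxel_size = voxel_size, n_markers = as.integer(n_markers),
                 sphere_radius = sphere_radius, pair_spacing = pair_spacing,
                 sphere_intensity = sphere_intensity,
                 shell_intensity = shell_intensity,
                 head_intensity = head_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 volume_mm = volume_mm, head_semiaxes = head_semiaxes,
                 shell_thickness = shell_thickness,
                 standoff_mm = standoff_mm),
            class = "phantom_spec")
}

#' Render a sphere into a volume
#'
#' Sets voxels inside the sphere to `value`. With `partial_volume = TRUE`
#' (default), boundary voxels are blended between their current value and
#' `value` according to the inside fraction estimated by 3^3 subsampling,
#' which emulates the smooth sphere edges seen at coarse voxel sizes. With
#' `partial_volume = FALSE`, a voxel is set iff its centre lies within
#' `radius` of `center`.
#'
#' @param v a [volume][as_volume].
#' @param center sphere centre in mm (length 3).
#' @param radius sphere radius in mm.
#' @param value intensity assigned to the sphere interior.
#' @param partial_volume blend boundary voxels by subsampled inside fraction.
#' @return the modified [volume][as_volume]. If the sphere does not intersect
#'   the voxel grid the volume is returned unchanged, with a warning.
#' @export
voxelize_sphere <- function(v, center, radius, value, partial_volume = TRUE) {
  stopifnot_volume(v)
  if (radius <= 0) stop("radius must be > 0")
  d <- dim(v$data)
  lo <- world_to_voxel(v, center - radius)
  hi <- world_to_voxel(v, center + radius)
  ilo <- pmax(floor(lo), 1)
  ihi <- pmin(ceiling(hi), d)
  if (any(ilo > d) || any(ihi < 1)) {
    warning("sphere lies entirely outside the volume; data unchanged")
    return(v)
  }
  ii <- seq(ilo[1], ihi[1]); jj <- seq(ilo[2], ihi[2]); kk <- seq(ilo[3], ihi[3])
  cx <- v$origin[1] + (ii - 1) * v$spacing[1] - center[1]
  cy <- v$origin[2] + (jj - 1) * v$spacing[2] - center[2]
  cz <- v$origin[3] + (kk - 1) * v$spacing[3] - center[3]
  if (!partial_volume) {
    d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
    sub <- v$data[ii, jj, kk, drop = FALSE]
    sub[d2 <= radius^2] <- value
    v$data[ii, jj, kk] <- sub
    return(v)
  }
  off <- (c(-1, 0, 1) / 3)
  frac <- array(0, dim = c(length(ii), length(jj), length(kk)))
  for (ox in off) for (oy in off) for (oz in off) {
    d2 <- outer(outer((cx + ox * v$spacing[1])^2,
                      (cy + oy * v$spacing[2])^2, "+"),
                (cz + oz * v$spacing[3])^2, "+")
    frac <- frac + (d2 <= radius^2)
  }
  frac <- frac / 27
  sub <- v$data[ii, jj, kk, drop = FALSE]
  v$data[ii, jj, kk] <- sub * (1 - frac) + value * frac
  v
}

# partial-volume ellipsoid rendering (used for the head)
voxelize_ellipsoid <- function(v, center, semiaxes, value) {
  d <- dim(v$data)
  ii <- seq_len(d[1]); jj <- seq_len(d[2]); kk <- seq_len(d[3])
  cx <- (v$origin[1] + (ii - 1) * v$spacing[1] - center[1]) / semiaxes[1]
  cy <- (v$origin[2] + (jj - 1) * v$spacing[2] - center[2]) / semiaxes[2]
  cz <- (v$origin[3] + (kk - 1) * v$spacing[3] - center[3]) / semiaxes[3]
  off <- (c(-1, 0, 1) / 3)
  frac <- array(0, dim = d)
  for (ox in off) for (oy in off) for (oz in off) {
    d2 <- outer(outer((cx + ox * v$spacing[1] / semiaxes[1])^2,
                      (cy + oy * v$spacing[2] / semiaxes[2])^2, "+"),
                (cz + oz * v$spacing[3] / semiaxes[3])^2, "+")
    frac <- frac + (d2 <= 1)
  }
  frac <- frac / 27
  v$data <- v$data * (1 - frac) + value * frac
  v
}

runif_sphere <- function() {
  repeat {
    u <- stats::rnorm(3)
    n <- sqrt(sum(u^2))
    if (n > 1e-8) return(u / n)
  }
}

#' Generate a synthetic head-and-marker phantom
#'
#' Builds the volume described by a [phantom_spec()] and returns it together
#' with the exact ground truth. Marker placement and noise are fully
#' determined by `spec$seed`: the same spec yields bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a [volume][as_volume]) and `truth`,
#'   where `truth` is a list with `sphere_centers` (2*n_markers x 3 mm
#'   matrix of continuous centres), `pairs` (n_markers x 2 index matrix) and
#'   `directions` (n_markers x 3 unit vectors).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("expected a phantom_spec")
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  s <- spec$voxel_size
  d <- pmax(ceiling(spec$volume_mm / s), 8)
  v <- as_volume(array(spec$background_intensity, dim = d),
                 spacing = rep(s, 3), origin = c(0, 0, 0))
  ctr <- (d - 1) * s / 2
  half <- spec$pair_spacing / 2
  r_shell <- spec$sphere_radius + spec$shell_thickness
  margin <- r_shell + s  # keep whole housing inside the grid
  lo_ok <- rep(margin, 3)
  hi_ok <- (d - 1) * s - margin
  min_cross <- spec$pair_spacing + 1.5  # unambiguous pairing across markers

  centers <- matrix(NA_real_, nrow = 2 * spec$n_markers, ncol = 3)
  pairs <- matrix(NA_integer_, nrow = spec$n_markers, ncol = 2)
  dirs <- matrix(NA_real_, nrow = spec$n_markers, ncol = 3)
  placed <- 0L
  for (m in seq_len(spec$n_markers)) {
    ok <- FALSE
    for (try in seq_len(5000L)) {
      u <- runif_sphere()
      k <- 1 / sqrt(sum((u / spec$head_semiaxes)^2))  # head surface distance
      mid <- ctr + u * (k + spec$standoff_mm)
      axis <- runif_sphere()
      a <- mid - axis * half
      b <- mid + axis * half
      cand <- rbind(a, b)
      if (any(cand < matrix(lo_ok, 2, 3, byrow = TRUE)) ||
          any(cand > matrix(hi_ok, 2, 3, byrow = TRUE))) next
      # housing must clear the head surface
      rad_dist <- function(p) {
        w <- p - ctr
        nv <- sqrt(sum((w / spec$head_semiaxes)^2))
        (nv - 1) / nv * sqrt(sum(w^2))  # approx. Euclidean clearance
      }
      if (rad_dist(a) < r_shell + 0.5 || rad_dist(b) < r_shell + 0.5) next
      if (placed > 0L) {
        prev <- centers[seq_len(2L * placed), , drop = FALSE]
        dd <- sqrt(rowSums(sweep(prev, 2, a)^2))
        dd <- c(dd, sqrt(rowSums(sweep(prev, 2, b)^2)))
        if (min(dd) < min_cross) next
      }
      centers[2 * m - 1, ] <- a
      centers[2 * m, ] <- b
      pairs[m, ] <- c(2L * m - 1L, 2L * m)
      dirs[m, ] <- axis
      placed <- placed + 1L
      ok <- TRUE
      break
    }
    if (!ok)
      stop("placement error: cannot place ", spec$n_markers,
           " markers with the required separation in this volume")
  }

  v <- voxelize_ellipsoid(v, ctr, spec$head_semiaxes, spec$head_intensity)
  for (i in seq_len(nrow(centers)))
    v <- voxelize_sphere(v, centers[i, ], r_shell, spec$shell_intensity)
  for (i in seq_len(nrow(centers)))
    v <- voxelize_sphere(v, centers[i, ], spec$sphere_radius,
                         spec$sphere_intensity)
  if (spec$noise_sd > 0)
    v$data <- v$data + array(stats::rnorm(length(v$data), sd = spec$noise_sd),
                             dim = dim(v$data))
  list(volume = v,
       truth = list(sphere_centers = centers, pairs = pairs,
                    directions = dirs))
}
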