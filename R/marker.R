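#' Pair sphere candidates into two-sphere markers
#'
#' Greedy pairing under the marker distance constraint: candidates are taken
#' in descending score order; each unpaired candidate is matched to the
#' remaining unpaired candidate whose distance is within
#' `spacing +/- tol` mm and closest to `spacing`. Paired candidates are
#' removed from the pool; candidates without a partner are returned unpaired
#' (these are the solitary false positives the marker model discards).
#'
#' @param candidates data.frame with columns `x`, `y`, `z` (mm) and optional
#'   `score` (defaults to 0, keeping input order).
#' @param spacing constructive sphere-to-sphere distance of a marker, mm.
#' @param tol half-width of the accepted distance corridor, mm (>= 0).
#' @return list with `markers` (data.frame: sphere centres `ax..bz`, midpoint
#'   `px, py, pz`, unit `dx, dy, dz`, `spacing_mm`, `score`) and `unpaired`
#'   (the leftover candidate rows).
#' @export
pair_spheres <- function(candidates, spacing = 11.0, tol = 1.0) {
  if (tol < 0) stop("tol must be >= 0")
  n <- nrow(candidates)
  empty <- data.frame(ax = numeric(0), ay = numeric(0), az = numeric(0),
                      bx = numeric(0), by = numeric(0), bz = numeric(0),
                      px = numeric(0), py = numeric(0), pz = numeric(0),
                      dx = numeric(0), dy = numeric(0), dz = numeric(0),
                      spacing_mm = numeric(0), score = numeric(0))
  if (is.null(n) || n == 0) return(list(markers = empty,
                                        unpaired = candidates))
  score <- if ("score" %in% names(candidates)) candidates$score else rep(0, n)
  ord <- order(-score, seq_len(n))
  pos <- as.matrix(candidates[, c("x", "y", "z")])
  paired <- rep(FALSE, n)
  rows <- list()
  for (i in ord) {
    if (paired[i]) next
    free <- which(!paired & seq_len(n) != i)
    if (!length(free)) break
    dd <- sqrt(colSums((t(pos[free, , drop = FALSE]) - pos[i, ])^2))
    ok <- abs(dd - spacing) <= tol
    if (!any(ok)) next
    j <- free[ok][which.min(abs(dd[ok] - spacing))]
    paired[c(i, j)] <- TRUE
    pose <- marker_pose(pos[i, ], pos[j, ])
    rows[[length(rows) + 1]] <-
      data.frame(ax = pos[i, 1], ay = pos[i, 2], az = pos[i, 3],
                 bx = pos[j, 1], by = pos[j, 2], bz = pos[j, 3],
                 px = pose$position[1], py = pose$position[2],
                 pz = pose$position[3],
                 dx = pose$direction[1], dy = pose$direction[2],
                 dz = pose$direction[3],
                 spacing_mm = sqrt(sum((pos[j, ] - pos[i, ])^2)),
                 score = (score[i] + score[j]) / 2)
  }
  markers <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(markers) <- NULL
  list(markers = markers,
       unpaired = candidates[!paired, , drop = FALSE])
}

#' Marker pose from its two sphere centres
#'
#' The marker position is the midpoint of the two sphere centroids; the
#' direction is the unit vector from `a` to `b`. The two spheres of the
#' physical marker are constructively identical, so the direction is defined
#' up to sign; swapping `a` and `b` flips it. [canonical_direction()] gives a
#' sign-fixed representative for reporting.
#'
#' @param a,b mm positions of the two sphere centroids.
#' @return list with `position` (mm) and unit `direction`.
#' @export
marker_pose <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  d <- b - a
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) stop("coincident sphere centres: direction undefined")
  list(position = (a + b) / 2, direction = d / nd)
}

#' Canonical sign representative of a marker direction
#'
#' Returns `u` or `-u` such that the largest-magnitude component is positive.
#'
#' @param u unit vector.
#' @return sign-fixed unit vector.
#' @export
canonical_direction <- function(u) {
  u <- as.numeric(u)
  i <- which.max(abs(u))
  if (u[i] < 0) -u else u
}

# the sphere centres of paired markers, as a candidates-like data.frame
marker_spheres <- function(markers) {
  if (nrow(markers) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)))
  data.frame(x = c(markers$ax, markers$bx),
             y = c(markers$ay, markers$by),
             z = c(markers$az, markers$bz))
}
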