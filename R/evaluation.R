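#' Match detections to ground-truth sphere centres
#'
#' One-to-one greedy matching by ascending Euclidean distance: candidate and
#' truth pairs are matched closest-first while both are still free and their
#' distance is within `threshold` mm. Matched candidates count as true
#' positives, unmatched candidates as false positives, unmatched truths as
#' false negatives.
#'
#' @param candidates data.frame with `x`, `y`, `z` (mm) or an n x 3 matrix.
#' @param truth m x 3 matrix of ground-truth centres (mm).
#' @param threshold maximum match distance in mm (> 0).
#' @return list with `tp`, `fp`, `fn` and `matches` (data.frame `candidate`,
#'   `truth`, `distance`).
#' @export
match_to_ground_truth <- function(candidates, truth, threshold = 14) {
  if (threshold <= 0) stop("threshold must be > 0")
  pos <- if (is.data.frame(candidates))
    as.matrix(candidates[, c("x", "y", "z")]) else rbind_coords(candidates)
  truth <- rbind_coords(truth)
  nc <- nrow(pos); nt <- nrow(truth)
  matches <- data.frame(candidate = integer(0), truth = integer(0),
                        distance = numeric(0))
  if (nc > 0 && nt > 0) {
    dd <- outer(seq_len(nc), seq_len(nt),
                Vectorize(function(i, j) sqrt(sum((pos[i, ] - truth[j, ])^2))))
    ord <- order(dd)
    free_c <- rep(TRUE, nc); free_t <- rep(TRUE, nt)
    for (lin in ord) {
      if (dd[lin] > threshold) break
      i <- (lin - 1) %% nc + 1
      j <- (lin - 1) %/% nc + 1
      if (free_c[i] && free_t[j]) {
        free_c[i] <- FALSE; free_t[j] <- FALSE
        matches <- rbind(matches,
                         data.frame(candidate = i, truth = j,
                                    distance = dd[lin]))
      }
    }
  }
  list(tp = nrow(matches), fp = nc - nrow(matches), fn = nt - nrow(matches),
       matches = matches)
}

#' F1 score from detection counts
#'
#' Harmonic mean of precision and recall:
#' `F1 = tp / (tp + (fp + fn) / 2)`. Equals the Dice coefficient on Boolean
#' data, and is symmetric in `fp` and `fn`.
#'
#' @param tp,fp,fn true positive, false positive and false negative counts.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  if (tp + fp + fn == 0) stop("F1 undefined for all-zero counts")
  tp / (tp + (fp + fn) / 2)
}

#' Positioning errors of matched detections
#'
#' @param matches result of [match_to_ground_truth()] (or its `matches`
#'   data.frame).
#' @return numeric vector of Euclidean distances (mm), one per matched pair.
#' @export
positioning_error <- function(matches) {
  if (is.list(matches) && !is.data.frame(matches)) matches <- matches$matches
  as.numeric(matches$distance)
}

#' Spacing errors of detected markers
#'
#' Absolute deviation of each detected marker's sphere-to-sphere distance from
#' the constructive spacing. Only computable for complete markers (both
#' spheres recognized), so it yields one value per marker.
#'
#' @param markers markers data.frame from [pair_spheres()].
#' @param nominal constructive spacing in mm.
#' @return numeric vector of `|spacing_mm - nominal|`, mm.
#' @export
spacing_error <- function(markers, nominal = 11.0) {
  abs(markers$spacing_mm - nominal)
}

#' Centroid resolution limit of a voxel grid
#'
#' Worst-case distance of a continuous point to the nearest voxel centre:
#' half a voxel in every translatory degree of freedom, i.e.
#' `|(s/2, s/2, s/2)| = sqrt(3)/2 * s ~ 0.86 s`.
#'
#' @param s isotropic voxel size in mm.
#' @return resolution limit in mm.
#' @export
resolution_limit <- function(s) {
  if (any(s <= 0)) stop("s must be > 0")
  sqrt(3) / 2 * s
}

#' Worst-case orientation error induced by positioning error
#'
#' Assumes the positioning error `ep` acts orthogonally to the marker's true
#' axis, the worst case for the estimated orientation. With both endpoints
#' displaced by `ep` in opposite senses the axis tilts by
#' `atan(2 ep / spacing)`; with a single displaced endpoint by
#' `atan(ep / spacing)`.
#'
#' @param ep positioning error in mm (>= 0).
#' @param spacing marker sphere spacing in mm.
#' @param both_endpoints use the two-endpoint worst case (default) or the
#'   single-endpoint variant.
#' @return angle in degrees.
#' @export
orientation_error_bound <- function(ep, spacing = 11.0,
                                    both_endpoints = TRUE) {
  if (any(ep < 0)) stop("ep must be >= 0")
  if (spacing <= 0) stop("spacing must be > 0")
  k <- if (both_endpoints) 2 else 1
  atan(k * ep / spacing) * 180 / pi
}

#' Full detection metrics against ground truth
#'
#' Computes the classification counts and F1 both before the marker model
#' (on the raw candidates) and after it (on the spheres surviving
#' [pair_spheres()]), plus the positioning errors of the matched raw
#' candidates and the spacing errors of the paired markers.
#'
#' @param candidates raw detector candidates.
#' @param truth ground-truth list (needs `sphere_centers`), or an n x 3
#'   matrix of centres.
#' @param spacing,tol marker-model corridor passed to [pair_spheres()].
#' @param match_threshold ground-truth matching threshold in mm.
#' @return list with `tp`, `fp`, `fn`, `f1_bm`, `f1_am`, `ep_mm`, `es_mm`,
#'   `n_markers`, `recall` and the `markers` data.frame.
#' @export
evaluate_detections <- function(candidates, truth, spacing = 11.0, tol = 1.0,
                                match_threshold = 14) {
  centers <- if (is.list(truth) && !is.null(truth$sphere_centers))
    truth$sphere_centers else rbind_coords(truth)
  bm <- match_to_ground_truth(candidates, centers, match_threshold)
  paired <- pair_spheres(candidates, spacing = spacing, tol = tol)
  am <- match_to_ground_truth(marker_spheres(paired$markers), centers,
                              match_threshold)
  list(tp = bm$tp, fp = bm$fp, fn = bm$fn,
       f1_bm = f1_score(bm$tp, bm$fp, bm$fn),
       f1_am = f1_score(am$tp, am$fp, am$fn),
       ep_mm = positioning_error(bm),
       es_mm = spacing_error(paired$markers, nominal = spacing),
       n_markers = nrow(paired$markers),
       recall = bm$tp / nrow(centers),
       markers = paired$markers)
}
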