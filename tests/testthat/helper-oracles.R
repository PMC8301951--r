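# Independent brute-force oracles used by the test-suite. These deliberately
# re-derive results from first principles (plain R loops, igraph, combn) and
# never call the package's compiled paths.

# exhaustive local-maxima scan with the same contract as find_local_maxima:
# value > threshold, >= all voxels within Euclidean min_dist (mm), plateau
# ties broken toward the smallest linear index, then greedy suppression.
brute_local_maxima <- function(a, spacing, min_dist, threshold) {
  d <- dim(a)
  lin <- function(i, j, k) i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  cand <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    v <- a[i, j, k]
    if (!(v > threshold)) next
    keep <- TRUE
    for (kk in seq_len(d[3])) for (jj in seq_len(d[2])) for (ii in seq_len(d[1])) {
      if (ii == i && jj == j && kk == k) next
      dd <- sqrt(sum((((c(ii, jj, kk) - c(i, j, k)) * spacing))^2))
      if (dd <= min_dist) {
        w <- a[ii, jj, kk]
        if (w > v || (w == v && lin(ii, jj, kk) < lin(i, j, k))) {
          keep <- FALSE
          break
        }
      }
    }
    if (keep) cand <- rbind(cand, c(i, j, k, v, lin(i, j, k)))
  }
  if (is.null(cand)) return(matrix(numeric(0), ncol = 4))
  ord <- order(-cand[, 4], cand[, 5])
  cand <- cand[ord, , drop = FALSE]
  kept <- NULL
  for (r in seq_len(nrow(cand))) {
    p <- cand[r, 1:3]
    ok <- TRUE
    if (!is.null(kept)) {
      for (q in seq_len(nrow(kept))) {
        if (sqrt(sum(((p - kept[q, 1:3]) * spacing)^2)) < min_dist) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) kept <- rbind(kept, cand[r, 1:4])
  }
  kept[, 1:4, drop = FALSE]
}

# sextuple-loop evaluation of the valid-region discrete convolution
brute_conv3d <- function(a, f) {
  da <- dim(a); df_ <- dim(f)
  p <- (df_ - 1) / 2
  o <- da - df_ + 1
  out <- array(0, dim = o)
  for (z in seq_len(o[3])) for (y in seq_len(o[2])) for (x in seq_len(o[1])) {
    cx <- x + p[1]; cy <- y + p[2]; cz <- z + p[3]  # centre in input coords
    s <- 0
    for (w in -p[3]:p[3]) for (v in -p[2]:p[2]) for (u in -p[1]:p[1]) {
      s <- s + f[u + p[1] + 1, v + p[2] + 1, w + p[3] + 1] *
        a[cx - u, cy - v, cz - w]
    }
    out[x, y, z] <- s
  }
  out
}

# 6-connected component partition via an igraph lattice, as label sets
oracle_partition6 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  pos <- arrayInd(idx, d)
  key <- function(m) m[, 1] + (m[, 2] - 1) * d[1] + (m[, 3] - 1) * d[1] * d[2]
  lookup <- match(seq_len(prod(d)), idx)  # voxel lin -> node id or NA
  edges <- NULL
  for (ax in 1:3) {
    shift <- pos
    shift[, ax] <- shift[, ax] + 1
    ok <- shift[, ax] <= d[ax]
    nb <- lookup[key(shift[ok, , drop = FALSE])]
    here <- seq_along(idx)[ok]
    good <- !is.na(nb)
    edges <- rbind(edges, cbind(here[good], nb[good]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  split(idx, comp)
}

# normalize a labelling into a canonical set-of-sets representation
partition_sets <- function(label_map) {
  labs <- label_map[label_map > 0]
  idx <- which(label_map > 0)
  unname(lapply(split(idx, labs), sort))
}

same_partition <- function(p1, p2) {
  keyset <- function(p) sort(unname(vapply(p, function(s)
    paste(sort(unname(s)), collapse = ","), character(1))))
  identical(keyset(p1), keyset(p2))
}

# exhaustive multi-Otsu oracle: maximize the textbook between-class variance
# over all threshold triples using combn
brute_otsu4 <- function(counts, mids = seq_along(counts)) {
  nb <- length(counts)
  W <- sum(counts)
  mu <- sum(counts * mids) / W
  best <- -Inf; best_t <- NULL
  splits <- utils::combn(nb - 1, 3)
  for (c in seq_len(ncol(splits))) {
    t <- splits[, c]
    cls <- list(1:t[1], (t[1] + 1):t[2], (t[2] + 1):t[3], (t[3] + 1):nb)
    v <- 0
    for (cl in cls) {
      w <- sum(counts[cl])
      if (w > 0) {
        m <- sum(counts[cl] * mids[cl]) / w
        v <- v + w * (m - mu)^2
      }
    }
    if (v > best) { best <- v; best_t <- t }
  }
  best_t  # 1-based index of the last bin of classes 1..3
}

# small deterministic phantom shared across detector tests
small_phantom <- function(s = 1.0, noise_sd = 0, seed = 42) {
  generate_phantom(phantom_spec(voxel_size = s, noise_sd = noise_sd,
                                seed = seed))
}

# binary ball mask (voxel centres within radius of the grid centre)
ball_mask <- function(r_vox, n = 2 * ceiling(r_vox) + 5) {
  ctr <- (n + 1) / 2
  idx <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  m <- with(idx, (i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= r_vox^2)
  array(m, dim = c(n, n, n))
}
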