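#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // scipy-style 'reflect' boundary: (d c b a | a b c d | d c b a)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Cross-correlation of a 3D array with a centred 1D kernel along one axis,
// reflect boundary handling. `axis` is 1-based (1, 2 or 3).
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector a, IntegerVector dim,
                            NumericVector kern, int axis) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int kl = kern.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  const int h = kl / 2;
  NumericVector out(a.size());
  const int ax = axis - 1;
  const int nax = dim[ax];
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i) {
        double s = 0.0;
        for (int t = -h; t <= h; ++t) {
          int ii = i, jj = j, kk = k;
          if (ax == 0) ii = reflect_idx(i + t, nax);
          else if (ax == 1) jj = reflect_idx(j + t, nax);
          else kk = reflect_idx(k + t, nax);
          s += kern[t + h] * a[ii + (size_t)n1 * (jj + (size_t)n2 * kk)];
        }
        out[i + (size_t)n1 * (j + (size_t)n2 * k)] = s;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Valid-region true 3D convolution (kernel flipped), as in the discrete
// convolution sum I*(i,j,k) = sum_{u,v,w} F(u,v,w) I(i-u, j-v, k-w).
// Output dims are dim(a) - dim(k) + 1.
// [[Rcpp::export]]
NumericVector cpp_conv3d_valid(NumericVector a, IntegerVector da,
                               NumericVector k, IntegerVector dk) {
  const int a1 = da[0], a2 = da[1], a3 = da[2];
  const int k1 = dk[0], k2 = dk[1], k3 = dk[2];
  if (k1 > a1 || k2 > a2 || k3 > a3) stop("kernel larger than volume");
  const int o1 = a1 - k1 + 1, o2 = a2 - k2 + 1, o3 = a3 - k3 + 1;
  NumericVector out((size_t)o1 * o2 * o3);
  for (int z = 0; z < o3; ++z) {
    for (int y = 0; y < o2; ++y) {
      for (int x = 0; x < o1; ++x) {
        double s = 0.0;
        for (int w = 0; w < k3; ++w) {
          for (int v = 0; v < k2; ++v) {
            const double *ka = &k[0] + (size_t)k1 * (v + (size_t)k2 * w);
            // flipped kernel: input index = x + (k1-1-u), etc.
            const double *aa = &a[0] + (x + k1 - 1) +
              (size_t)a1 * ((y + k2 - 1 - v) + (size_t)a2 * (z + k3 - 1 - w));
            for (int u = 0; u < k1; ++u) s += ka[u] * aa[-u];
          }
        }
        out[x + (size_t)o1 * (y + (size_t)o2 * z)] = s;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(o1, o2, o3);
  return out;
}

// 6-connected component labelling of a binary 3D mask (BFS flood fill).
// [[Rcpp::export]]
List cpp_label6(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const size_t n = (size_t)n1 * n2 * n3;
  IntegerVector labels(n, 0);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++cur;
    stack.push_back(start);
    labels[start] = cur;
    while (!stack.empty()) {
      size_t p = stack.back();
      stack.pop_back();
      int i = p % n1, j = (p / n1) % n2, k = p / ((size_t)n1 * n2);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        size_t pn = ii + (size_t)n1 * (jj + (size_t)n2 * kk);
        if (mask[pn] && labels[pn] == 0) {
          labels[pn] = cur;
          stack.push_back(pn);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return List::create(_["labels"] = labels, _["n"] = cur);
}

// Local maxima of a 3D array under a Euclidean (mm) neighbourhood, followed
// by greedy non-maximum suppression so that no two returned maxima are closer
// than min_dist. Plateau ties are broken toward the smallest linear index.
// Returns a matrix with columns (i, j, k, value), 1-based voxel indices.
// [[Rcpp::export]]
NumericMatrix cpp_local_maxima(NumericVector a, IntegerVector dim,
                               NumericVector spacing, double min_dist,
                               double threshold) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const int r1 = (int)std::floor(min_dist / sx);
  const int r2 = (int)std::floor(min_dist / sy);
  const int r3 = (int)std::floor(min_dist / sz);
  // neighbourhood offsets within Euclidean min_dist (excluding self)
  std::vector<int> od1, od2, od3;
  for (int dk = -r3; dk <= r3; ++dk)
    for (int dj = -r2; dj <= r2; ++dj)
      for (int di = -r1; di <= r1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        double d2 = di * sx * di * sx + dj * sy * dj * sy + dk * sz * dk * sz;
        if (d2 <= min_dist * min_dist) {
          od1.push_back(di); od2.push_back(dj); od3.push_back(dk);
        }
      }
  const int noff = od1.size();
  std::vector<size_t> cand;
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i) {
        size_t p = i + (size_t)n1 * (j + (size_t)n2 * k);
        double v = a[p];
        if (!(v > threshold)) continue;
        bool keep = true;
        for (int q = 0; q < noff; ++q) {
          int ii = i + od1[q], jj = j + od2[q], kk = k + od3[q];
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
            continue;
          size_t pn = ii + (size_t)n1 * (jj + (size_t)n2 * kk);
          double w = a[pn];
          if (w > v || (w == v && pn < p)) { keep = false; break; }
        }
        if (keep) cand.push_back(p);
      }
    }
  }
  // order by value descending, linear index ascending
  std::sort(cand.begin(), cand.end(), [&](size_t x, size_t y) {
    if (a[x] != a[y]) return a[x] > a[y];
    return x < y;
  });
  std::vector<size_t> kept;
  for (size_t c = 0; c < cand.size(); ++c) {
    size_t p = cand[c];
    int i = p % n1, j = (p / n1) % n2, k = p / ((size_t)n1 * n2);
    bool ok = true;
    for (size_t m = 0; m < kept.size(); ++m) {
      size_t q = kept[m];
      int qi = q % n1, qj = (q / n1) % n2, qk = q / ((size_t)n1 * n2);
      double dx = (i - qi) * sx, dy = (j - qj) * sy, dz = (k - qk) * sz;
      if (dx * dx + dy * dy + dz * dz < min_dist * min_dist) { ok = false; break; }
    }
    if (ok) kept.push_back(p);
  }
  NumericMatrix out(kept.size(), 4);
  for (size_t m = 0; m < kept.size(); ++m) {
    size_t p = kept[m];
    out(m, 0) = (int)(p % n1) + 1;
    out(m, 1) = (int)((p / n1) % n2) + 1;
    out(m, 2) = (int)(p / ((size_t)n1 * n2)) + 1;
    out(m, 3) = a[p];
  }
  return out;
}

// Gradient-limited circular Hough vote accumulation for one 2D slice.
// Each pixel with gradient magnitude above `thresh` votes, for every radius,
// along its gradient direction +/- arc_halfwidth, both inward and outward.
// All radii share one 2D accumulator.
// [[Rcpp::export]]
NumericMatrix cpp_cht_votes(NumericMatrix mag, NumericMatrix dir,
                            NumericVector radii, double arc_halfwidth,
                            double thresh) {
  const int n1 = mag.nrow(), n2 = mag.ncol();
  NumericMatrix acc(n1, n2);
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      if (!(mag(i, j) > thresh)) continue;
      const double th0 = dir(i, j);
      for (int rr = 0; rr < radii.size(); ++rr) {
        const double r = radii[rr];
        const double dphi = std::min(arc_halfwidth > 0 ? arc_halfwidth : 1.0,
                                     0.5 / r);
        const int ns = std::max(1, (int)std::ceil(arc_halfwidth / dphi));
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          int last = -1;
          for (int s = -ns; s <= ns; ++s) {
            double phi = th0 + s * arc_halfwidth / ns;
            int vi = (int)std::lround(i + sgn * r * std::cos(phi));
            int vj = (int)std::lround(j + sgn * r * std::sin(phi));
            if (vi < 0 || vi >= n1 || vj < 0 || vj >= n2) continue;
            int lin = vi + n1 * vj;
            if (lin == last) continue;  // skip duplicate consecutive cells
            acc(vi, vj) += 1.0;
            last = lin;
          }
        }
      }
    }
  }
  return acc;
}

// Exposed boundary-face area per label (a face is exposed when its 6-neighbour
// has a different label or lies outside the array). Face areas use the
// physical voxel spacing, so anisotropic grids are handled.
// [[Rcpp::export]]
NumericVector cpp_face_area(IntegerVector labels, IntegerVector dim, int nlab,
                            NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double fa[3] = {spacing[1] * spacing[2], spacing[0] * spacing[2],
                        spacing[0] * spacing[1]};
  NumericVector area(nlab, 0.0);
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  const int axq[6] = {0, 0, 1, 1, 2, 2};
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int lab = labels[i + (size_t)n1 * (j + (size_t)n2 * k)];
        if (lab == 0) continue;
        for (int q = 0; q < 6; ++q) {
          int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
          int other = 0;
          if (ii >= 0 && ii < n1 && jj >= 0 && jj < n2 && kk >= 0 && kk < n3)
            other = labels[ii + (size_t)n1 * (jj + (size_t)n2 * kk)];
          if (other != lab) area[lab - 1] += fa[axq[q]];
        }
      }
  return area;
}

// Exhaustive multi-level Otsu thresholding on a histogram: maximizes the
// between-class variance over all threshold placements. Returns the 0-based
// index of the last bin of each class but the final one.
// [[Rcpp::export]]
IntegerVector cpp_multi_otsu(NumericVector counts, NumericVector mids,
                             int nclasses) {
  const int nb = counts.size();
  if (nclasses < 2 || nclasses > 4) stop("nclasses must be 2, 3 or 4");
  std::vector<double> cw(nb + 1, 0.0), cm(nb + 1, 0.0);
  for (int b = 0; b < nb; ++b) {
    cw[b + 1] = cw[b] + counts[b];
    cm[b + 1] = cm[b] + counts[b] * mids[b];
  }
  const double W = cw[nb];
  if (W <= 0) stop("empty histogram");
  // between-class variance is (up to a constant) sum_c w_c mu_c^2
  auto crit = [&](int lo, int hi) {  // class covering bins [lo, hi]
    double w = cw[hi + 1] - cw[lo];
    if (w <= 0) return 0.0;
    double m = cm[hi + 1] - cm[lo];
    return m * m / w;
  };
  double best = -1.0;
  IntegerVector th(nclasses - 1);
  if (nclasses == 2) {
    for (int t1 = 0; t1 < nb - 1; ++t1) {
      double v = crit(0, t1) + crit(t1 + 1, nb - 1);
      if (v > best) { best = v; th[0] = t1; }
    }
  } else if (nclasses == 3) {
    for (int t1 = 0; t1 < nb - 2; ++t1)
      for (int t2 = t1 + 1; t2 < nb - 1; ++t2) {
        double v = crit(0, t1) + crit(t1 + 1, t2) + crit(t2 + 1, nb - 1);
        if (v > best) { best = v; th[0] = t1; th[1] = t2; }
      }
  } else {
    for (int t1 = 0; t1 < nb - 3; ++t1) {
      double c1 = crit(0, t1);
      for (int t2 = t1 + 1; t2 < nb - 2; ++t2) {
        double c2 = c1 + crit(t1 + 1, t2);
        for (int t3 = t2 + 1; t3 < nb - 1; ++t3) {
          double v = c2 + crit(t2 + 1, t3) + crit(t3 + 1, nb - 1);
          if (v > best) { best = v; th[0] = t1; th[1] = t2; th[2] = t3; }
        }
      }
    }
  }
  return th;
}

// Per-label voxel counts and centroid sums (in voxel indices, 1-based).
// [[Rcpp::export]]
List cpp_component_stats(IntegerVector labels, IntegerVector dim, int nlab) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  NumericVector cnt(nlab, 0.0);
  NumericMatrix csum(nlab, 3);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int lab = labels[i + (size_t)n1 * (j + (size_t)n2 * k)];
        if (lab == 0) continue;
        cnt[lab - 1] += 1;
        csum(lab - 1, 0) += i + 1;
        csum(lab - 1, 1) += j + 1;
        csum(lab - 1, 2) += k + 1;
      }
  return List::create(_["count"] = cnt, _["sum"] = csum);
}
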