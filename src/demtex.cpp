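#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Diffusion-limited aggregation on a square lattice.  A walker is launched
// on a circle just outside the current cluster radius, performs a 4-connected
// random walk, and freezes with probability `stickiness` when 8-connected to
// the aggregate.  Walkers escaping the kill radius are relaunched.  Growth
// stops when the aggregate touches the image border; the actual particle
// count is returned in attr "particles".  Uses R's RNG (set.seed applies).
// [[Rcpp::export]]
IntegerMatrix cpp_dla_grow(int size, int n_particles, double stickiness) {
  IntegerMatrix grid(size, size);
  const int c = size / 2;
  grid(c, c) = 1;
  int count = 1;
  double rcluster = 0.0;
  bool hit_border = false;
  static const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int si[4] = {-1, 1, 0, 0};
  static const int sj[4] = {0, 0, -1, 1};
  const long step_budget = 400000000L;
  long steps = 0;

  // Walkers live on an unbounded lattice (positions outside the grid are
  // simply empty); when far from the cluster they take circle jumps of the
  // largest safe length, which leaves the harmonic hitting measure intact
  // while keeping the walk fast.
  while (count < n_particles && !hit_border && steps < step_budget) {
    double rbirth = rcluster + 5.0;
    double rkill = 3.0 * rbirth + 100.0;
    double ang = 2.0 * M_PI * R::unif_rand();
    double x = c + rbirth * std::cos(ang);
    double y = c + rbirth * std::sin(ang);
    int i = (int)std::lround(x), j = (int)std::lround(y);
    bool stuck = false;
    while (!stuck && steps < step_budget) {
      ++steps;
      double dd = std::sqrt((double)((i - c) * (i - c) + (j - c) * (j - c)));
      if (dd > rkill) {  // escaped: relaunch on the birth circle
        ang = 2.0 * M_PI * R::unif_rand();
        i = (int)std::lround(c + rbirth * std::cos(ang));
        j = (int)std::lround(c + rbirth * std::sin(ang));
        continue;
      }
      if (dd > rbirth + 2.0) {  // circle jump toward the cluster zone
        double L = dd - rbirth - 1.0;
        ang = 2.0 * M_PI * R::unif_rand();
        i = (int)std::lround(i + L * std::cos(ang));
        j = (int)std::lround(j + L * std::sin(ang));
        continue;
      }
      int dir = (int)(4.0 * R::unif_rand());
      if (dir > 3) dir = 3;
      int ni = i + si[dir], nj = j + sj[dir];
      bool inside = ni >= 0 && nj >= 0 && ni < size && nj < size;
      if (inside && grid(ni, nj)) continue;  // cannot step onto the aggregate
      i = ni; j = nj;
      if (!inside) continue;  // off-grid positions are empty space
      bool adjacent = false;
      for (int k = 0; k < 8; ++k) {
        int ii = i + di8[k], jj = j + dj8[k];
        if (ii >= 0 && jj >= 0 && ii < size && jj < size && grid(ii, jj)) {
          adjacent = true;
          break;
        }
      }
      if (adjacent && R::unif_rand() <= stickiness) {
        grid(i, j) = 1;
        ++count;
        stuck = true;
        double r = std::sqrt((double)((i - c) * (i - c) + (j - c) * (j - c)));
        if (r > rcluster) rcluster = r;
        if (i == 0 || j == 0 || i == size - 1 || j == size - 1) hit_border = true;
      }
    }
  }
  grid.attr("particles") = count;
  return grid;
}

// Grayscale erosion/dilation by a nonflat structuring element given as
// offset lists (dy, dx) with heights h (<= 0, 0 at the centre).  Offsets
// falling outside the image are skipped, i.e. the image is treated as +Inf
// (erosion) / -Inf (dilation) outside its domain, which preserves the
// erosion/dilation adjunction and hence idempotence of the opening.
// [[Rcpp::export]]
NumericMatrix cpp_gray_morph_nf(NumericMatrix img, IntegerVector dy,
                                IntegerVector dx, NumericVector h,
                                bool erode) {
  int nr = img.nrow(), nc = img.ncol(), K = dy.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = erode ? R_PosInf : R_NegInf;
      for (int k = 0; k < K; ++k) {
        int ii = erode ? i + dy[k] : i - dy[k];
        int jj = erode ? j + dx[k] : j - dx[k];
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        double v = erode ? img(ii, jj) - h[k] : img(ii, jj) + h[k];
        if (erode ? (v < best) : (v > best)) best = v;
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Local connected fractal dimension map.  For each foreground pixel the
// connected mass n(s) is the size of the 8-connected component containing
// the pixel when connectivity is evaluated strictly inside the centred
// s x s window, for s = 3, 5, ..., max_window.  The local dimension is the
// least-squares slope of log n(s) vs log s; fit quality is returned as R^2
// (defined as 1 when the residuals vanish, including constant n).
// [[Rcpp::export]]
List cpp_lcfd(LogicalMatrix bin, int max_window, bool include_border) {
  int nr = bin.nrow(), nc = bin.ncol();
  int rmax = (max_window - 1) / 2;
  NumericMatrix dim_map(nr, nc), r2_map(nr, nc);
  std::fill(dim_map.begin(), dim_map.end(), NA_REAL);
  std::fill(r2_map.begin(), r2_map.end(), NA_REAL);

  int side = 2 * rmax + 1;
  std::vector<int> visited(side * side, 0);
  std::vector<int> queue(side * side);
  int stamp = 0;
  static const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  std::vector<double> xs, ys;
  xs.reserve(rmax);
  ys.reserve(rmax);

  for (int cj = 0; cj < nc; ++cj) {
    for (int ci = 0; ci < nr; ++ci) {
      if (!bin(ci, cj)) continue;
      if (!include_border &&
          (ci < rmax || cj < rmax || ci >= nr - rmax || cj >= nc - rmax))
        continue;
      xs.clear();
      ys.clear();
      for (int r = 1; r <= rmax; ++r) {
        // BFS restricted to the (2r+1)^2 window around the centre
        ++stamp;
        int head = 0, tail = 0;
        queue[tail++] = rmax * side + rmax;  // centre in local coords
        visited[rmax * side + rmax] = stamp;
        int n = 0;
        while (head < tail) {
          int q = queue[head++];
          ++n;
          int li = q / side, lj = q % side;
          for (int k = 0; k < 8; ++k) {
            int ni = li + di8[k], nj = lj + dj8[k];
            if (ni < rmax - r || ni > rmax + r || nj < rmax - r ||
                nj > rmax + r)
              continue;
            int nq = ni * side + nj;
            if (visited[nq] == stamp) continue;
            int gi = ci + ni - rmax, gj = cj + nj - rmax;
            if (gi < 0 || gj < 0 || gi >= nr || gj >= nc) continue;
            if (!bin(gi, gj)) continue;
            visited[nq] = stamp;
            queue[tail++] = nq;
          }
        }
        xs.push_back(std::log((double)(2 * r + 1)));
        ys.push_back(std::log((double)n));
      }
      // least-squares slope of ys on xs
      int m = xs.size();
      double mx = 0, my = 0;
      for (int t = 0; t < m; ++t) { mx += xs[t]; my += ys[t]; }
      mx /= m;
      my /= m;
      double sxy = 0, sxx = 0, syy = 0;
      for (int t = 0; t < m; ++t) {
        sxy += (xs[t] - mx) * (ys[t] - my);
        sxx += (xs[t] - mx) * (xs[t] - mx);
        syy += (ys[t] - my) * (ys[t] - my);
      }
      double slope = sxy / sxx;
      double ssres = syy - slope * sxy;  // residual sum of squares
      double r2 = (syy > 0) ? 1.0 - ssres / syy : 1.0;
      if (r2 < 0) r2 = 0;
      dim_map(ci, cj) = slope;
      r2_map(ci, cj) = r2;
    }
  }
  return List::create(_["values"] = dim_map, _["r2"] = r2_map);
}
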