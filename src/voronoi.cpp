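// Bounded Voronoi tessellation by half-plane clipping.
//
// Each cell starts as the rectangular analysis window and is clipped by the
// perpendicular bisector of the segment joining its site to each nearby site,
// processed in order of increasing distance with the standard pruning rule
// (a site farther than twice the current max site-to-vertex distance cannot
// cut the cell). Edge labels are carried through the clipping so that the
// finished polygon knows, for every edge, whether it came from the window
// boundary or from which neighboring site; this yields the Voronoi adjacency
// graph and boundary flags without a Delaunay triangulation.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double EPS_SIDE = 1e-10;

// Clip convex polygon (vertices x,y; lab[t] labels edge t -> t+1 mod m) by
// half-plane nx*px + ny*py <= c. A new cut edge is labeled newlab.
// Returns true if the polygon was modified.
static bool clip_halfplane(std::vector<double>& x, std::vector<double>& y,
                           std::vector<int>& lab,
                           double nx, double ny, double c, int newlab) {
  const int m = (int)x.size();
  if (m == 0) return false;
  std::vector<double> d(m);
  bool any_out = false;
  for (int t = 0; t < m; ++t) {
    d[t] = nx * x[t] + ny * y[t] - c;
    if (d[t] > EPS_SIDE) any_out = true;
  }
  if (!any_out) return false;
  std::vector<double> X, Y;
  std::vector<int> L;
  X.reserve(m + 2); Y.reserve(m + 2); L.reserve(m + 2);
  for (int t = 0; t < m; ++t) {
    const int u = (t + 1) % m;
    const bool tin = d[t] <= EPS_SIDE, uin = d[u] <= EPS_SIDE;
    if (tin && uin) {
      X.push_back(x[t]); Y.push_back(y[t]); L.push_back(lab[t]);
    } else if (tin && !uin) {            // leaving the half-plane
      X.push_back(x[t]); Y.push_back(y[t]); L.push_back(lab[t]);
      const double s = d[t] / (d[t] - d[u]);
      X.push_back(x[t] + s * (x[u] - x[t]));
      Y.push_back(y[t] + s * (y[u] - y[t]));
      L.push_back(newlab);               // cut edge runs to the re-entry point
    } else if (!tin && uin) {            // re-entering
      const double s = d[t] / (d[t] - d[u]);
      X.push_back(x[t] + s * (x[u] - x[t]));
      Y.push_back(y[t] + s * (y[u] - y[t]));
      L.push_back(lab[t]);
    }
  }
  x.swap(X); y.swap(Y); lab.swap(L);
  return true;
}

// [[Rcpp::export]]
List voronoi_cells_cpp(NumericMatrix pts, NumericVector window) {
  const int n = pts.nrow();
  const double xmin = window[0], xmax = window[1];
  const double ymin = window[2], ymax = window[3];
  const double W = xmax - xmin, H = ymax - ymin;
  const double diag = std::sqrt(W * W + H * H);

  // grid bins for neighbor gathering
  double h = std::sqrt(std::max(W * H / std::max(n, 1), 1e-12));
  int nbx = std::max(1, (int)std::floor(W / h));
  int nby = std::max(1, (int)std::floor(H / h));
  std::vector<std::vector<int> > bins((size_t)nbx * nby);
  auto binof = [&](double px, double py) {
    int bx = std::min(nbx - 1, std::max(0, (int)((px - xmin) / W * nbx)));
    int by = std::min(nby - 1, std::max(0, (int)((py - ymin) / H * nby)));
    return by * nbx + bx;
  };
  for (int i = 0; i < n; ++i) bins[binof(pts(i, 0), pts(i, 1))].push_back(i);

  NumericVector areas(n);
  LogicalVector boundary(n);
  List nbrs(n), polys(n);

  std::vector<int> cand;
  std::vector<std::pair<double, int> > byd;

  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1);
    double R = 3.5 * h;
    bool done = false;
    std::vector<double> x, y;
    std::vector<int> lab;
    while (!done) {
      // initialize cell as the window rectangle
      x = {xmin, xmax, xmax, xmin};
      y = {ymin, ymin, ymax, ymax};
      lab = {-1, -2, -3, -4};
      // gather candidates within R
      cand.clear(); byd.clear();
      const double R2 = R * R;
      int bx0 = std::max(0, (int)((px - R - xmin) / W * nbx));
      int bx1 = std::min(nbx - 1, (int)((px + R - xmin) / W * nbx));
      int by0 = std::max(0, (int)((py - R - ymin) / H * nby));
      int by1 = std::min(nby - 1, (int)((py + R - ymin) / H * nby));
      for (int by = by0; by <= by1; ++by)
        for (int bx = bx0; bx <= bx1; ++bx)
          for (int j : bins[(size_t)by * nbx + bx]) {
            if (j == i) continue;
            const double dx = pts(j, 0) - px, dy = pts(j, 1) - py;
            const double d2 = dx * dx + dy * dy;
            if (d2 <= R2) byd.push_back(std::make_pair(d2, j));
          }
      std::sort(byd.begin(), byd.end());
      double maxv2 = 0.0;
      for (size_t t = 0; t < x.size(); ++t) {
        const double dx = x[t] - px, dy = y[t] - py;
        maxv2 = std::max(maxv2, dx * dx + dy * dy);
      }
      done = true;
      for (size_t q = 0; q < byd.size(); ++q) {
        if (byd[q].first > 4.0 * maxv2) break;  // cannot cut the cell
        const int j = byd[q].second;
        const double nxj = pts(j, 0) - px, nyj = pts(j, 1) - py;
        const double mx = 0.5 * (pts(j, 0) + px), my = 0.5 * (pts(j, 1) + py);
        if (clip_halfplane(x, y, lab, nxj, nyj, nxj * mx + nyj * my, j)) {
          maxv2 = 0.0;
          for (size_t t = 0; t < x.size(); ++t) {
            const double dx = x[t] - px, dy = y[t] - py;
            maxv2 = std::max(maxv2, dx * dx + dy * dy);
          }
        }
      }
      // a site beyond R could still cut the cell: enlarge and redo
      if (R < diag && 4.0 * maxv2 > R * R) {
        R = std::min(diag, 2.0 * R);
        done = false;
      }
    }

    // area (shoelace), boundary flag, adjacency from surviving edge labels
    const int m = (int)x.size();
    double A = 0.0;
    bool onb = false;
    std::vector<int> nb;
    for (int t = 0; t < m; ++t) {
      const int u = (t + 1) % m;
      A += x[t] * y[u] - x[u] * y[t];
      const double el = std::hypot(x[u] - x[t], y[u] - y[t]);
      if (el < 1e-9) continue;
      if (lab[t] < 0) onb = true;
      else nb.push_back(lab[t] + 1);  // 1-based
    }
    areas[i] = 0.5 * std::fabs(A);
    boundary[i] = onb;
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    nbrs[i] = IntegerVector(nb.begin(), nb.end());
    NumericMatrix P(m, 2);
    for (int t = 0; t < m; ++t) { P(t, 0) = x[t]; P(t, 1) = y[t]; }
    polys[i] = P;
  }

  return List::create(_["area"] = areas, _["boundary"] = boundary,
                      _["neighbors"] = nbrs, _["polygons"] = polys);
}
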