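#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <map>
#include <utility>
using namespace Rcpp;

// Nearest- and second-nearest-seed distance fields for a periodic-free
// Voronoi foam. A pixel belongs to the septal wall when the bisector of its
// two nearest nuclei passes within half the wall thickness, i.e. when
// (d2 - d1) <= wall_thickness (both distances in micrometres). Seeds are
// bucketed on a uniform grid so each pixel inspects only nearby buckets.
//
// Returns a logical matrix (ny rows = image rows = y, nx cols = x),
// TRUE = tissue (septal wall).
// [[Rcpp::export]]
LogicalMatrix foam_wall_mask_cpp(int nx, int ny,
                                 NumericVector sx, NumericVector sy,
                                 double pixel_size, double wall_thickness) {
  const int ns = sx.size();
  const double W = nx * pixel_size, H = ny * pixel_size;
  // bucket grid: about one seed per cell
  double cs = std::sqrt(W * H / std::max(ns, 1));
  int bx = std::max(1, (int)std::ceil(W / cs));
  int by = std::max(1, (int)std::ceil(H / cs));
  double cw = W / bx, ch = H / by;
  std::vector< std::vector<int> > bucket((size_t)bx * by);
  for (int s = 0; s < ns; ++s) {
    int ix = std::min(bx - 1, std::max(0, (int)(sx[s] / cw)));
    int iy = std::min(by - 1, std::max(0, (int)(sy[s] / ch)));
    bucket[(size_t)iy * bx + ix].push_back(s);
  }
  LogicalMatrix out(ny, nx);
  for (int py = 0; py < ny; ++py) {
    double yc = (py + 0.5) * pixel_size;
    int cy = std::min(by - 1, std::max(0, (int)(yc / ch)));
    for (int px = 0; px < nx; ++px) {
      double xc = (px + 0.5) * pixel_size;
      int cx = std::min(bx - 1, std::max(0, (int)(xc / cw)));
      double d1 = R_PosInf, d2 = R_PosInf;
      for (int ring = 0; ; ++ring) {
        // min distance from pixel to any cell in this ring
        if (ring > 0) {
          double ringdist = (ring - 1) * std::min(cw, ch);
          if (d2 < ringdist) break;
        }
        bool any_cell = false;
        for (int iy = cy - ring; iy <= cy + ring; ++iy) {
          if (iy < 0 || iy >= by) continue;
          for (int ix = cx - ring; ix <= cx + ring; ++ix) {
            if (ix < 0 || ix >= bx) continue;
            if (std::max(std::abs(ix - cx), std::abs(iy - cy)) != ring) continue;
            any_cell = true;
            const std::vector<int>& b = bucket[(size_t)iy * bx + ix];
            for (size_t k = 0; k < b.size(); ++k) {
              double dx = sx[b[k]] - xc, dy = sy[b[k]] - yc;
              double d = std::sqrt(dx * dx + dy * dy);
              if (d < d1) { d2 = d1; d1 = d; }
              else if (d < d2) { d2 = d; }
            }
          }
        }
        if (!any_cell && ring > bx + by) break;
      }
      out(py, px) = (d2 - d1) <= wall_thickness;
    }
  }
  return out;
}

struct QNode {
  double dist;
  int idx;
  int label;
};
struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const { return a.dist > b.dist; }
};

// Attribute every tissue pixel to a septal wall segment, defined as the
// unordered pair of the two nearest distinct airspace components (geodesic
// distance through tissue, multi-source Dijkstra seeded at airspace pixels).
// Airspace components are 4-connected. Tissue pixels reached by fewer than
// two distinct airspace labels (e.g. image-frame walls) get segment 0 and
// are never eligible for removal.
//
// Returns list(segment = integer matrix (0 = airspace or unpaired),
//              n_segments = count of distinct pairs).
// [[Rcpp::export]]
List wall_segments_cpp(LogicalMatrix tissue) {
  const int ny = tissue.nrow(), nx = tissue.ncol();
  const int n = ny * nx;
  std::vector<int> air_label(n, 0);
  int n_air = 0;
  // 4-connected airspace labelling (BFS)
  {
    std::vector<int> stack;
    for (int i = 0; i < n; ++i) {
      int py = i % ny, px = i / ny;
      if (tissue(py, px) || air_label[i]) continue;
      ++n_air;
      stack.push_back(i);
      air_label[i] = n_air;
      while (!stack.empty()) {
        int j = stack.back(); stack.pop_back();
        int jy = j % ny, jx = j / ny;
        const int dy[4] = {1, -1, 0, 0}, dx[4] = {0, 0, 1, -1};
        for (int k = 0; k < 4; ++k) {
          int qy = jy + dy[k], qx = jx + dx[k];
          if (qy < 0 || qy >= ny || qx < 0 || qx >= nx) continue;
          int q = qx * ny + qy;
          if (!tissue(qy, qx) && !air_label[q]) {
            air_label[q] = n_air;
            stack.push_back(q);
          }
        }
      }
    }
  }
  std::vector<int> lab1(n, 0), lab2(n, 0);
  std::vector<double> d1(n, R_PosInf), d2(n, R_PosInf);
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  // seed the queue with tissue pixels adjacent to airspace
  const int dy8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dx8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const double step8[8] = {1, 1, 1, 1, M_SQRT2, M_SQRT2, M_SQRT2, M_SQRT2};
  for (int px = 0; px < nx; ++px) {
    for (int py = 0; py < ny; ++py) {
      if (!tissue(py, px)) continue;
      for (int k = 0; k < 8; ++k) {
        int qy = py + dy8[k], qx = px + dx8[k];
        if (qy < 0 || qy >= ny || qx < 0 || qx >= nx) continue;
        if (!tissue(qy, qx)) {
          QNode nd; nd.dist = step8[k]; nd.idx = px * ny + py;
          nd.label = air_label[(size_t)qx * ny + qy];
          pq.push(nd);
        }
      }
    }
  }
  while (!pq.empty()) {
    QNode nd = pq.top(); pq.pop();
    int i = nd.idx;
    if (lab1[i] == nd.label || lab2[i] == nd.label) continue;
    if (lab1[i] && lab2[i]) continue;
    if (!lab1[i]) { lab1[i] = nd.label; d1[i] = nd.dist; }
    else { lab2[i] = nd.label; d2[i] = nd.dist; }
    // propagate the accepted wavefront through tissue (each pixel accepts
    // at most two labels, so total pushes stay linear in pixel count)
    int py = i % ny, px = i / ny;
    for (int k = 0; k < 8; ++k) {
      int qy = py + dy8[k], qx = px + dx8[k];
      if (qy < 0 || qy >= ny || qx < 0 || qx >= nx) continue;
      if (!tissue(qy, qx)) continue;
      int q = qx * ny + qy;
      if (lab1[q] && lab2[q]) continue;
      QNode m; m.dist = nd.dist + step8[k]; m.idx = q; m.label = nd.label;
      pq.push(m);
    }
  }
  // enumerate unordered label pairs
  std::map< std::pair<int, int>, int > pair_id;
  IntegerMatrix seg(ny, nx);
  for (int px = 0; px < nx; ++px) {
    for (int py = 0; py < ny; ++py) {
      int i = px * ny + py;
      if (!tissue(py, px)) { seg(py, px) = 0; continue; }
      if (!lab1[i] || !lab2[i]) { seg(py, px) = 0; continue; }
      std::pair<int, int> key(std::min(lab1[i], lab2[i]),
                              std::max(lab1[i], lab2[i]));
      std::map< std::pair<int, int>, int >::iterator it = pair_id.find(key);
      int id;
      if (it == pair_id.end()) {
        id = (int)pair_id.size() + 1;
        pair_id[key] = id;
      } else id = it->second;
      seg(py, px) = id;
    }
  }
  return List::create(_["segment"] = seg,
                      _["n_segments"] = (int)pair_id.size(),
                      _["n_airspaces"] = n_air);
}
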