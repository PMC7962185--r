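#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Connected-component labelling of a binary mask.
// Foreground is 8-connected (diagonally touching pore pixels merge);
// ids are assigned in row-major scan order (topmost, then leftmost first
// pixel), which fixes pore numbering across platforms.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % H, pc = p / H;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int nr = pr + dr, nc = pc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(nr + nc * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Filled pixel area per label: component pixel count plus any enclosed
// holes (4-connected background components that do not reach the frame).
// [[Rcpp::export(name = ".filled_areas_cpp")]]
NumericVector filled_areas_cpp(IntegerMatrix lab, int nlab) {
  const int H = lab.nrow(), W = lab.ncol();
  NumericVector area(nlab);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (lab(r, c) > 0) area[lab(r, c) - 1] += 1.0;

  // flood 4-connected background from the border; unreached background = holes
  std::vector<char> open(static_cast<size_t>(H) * W, 0);
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    if (lab(0, c) == 0 && !open[0 + (size_t)c * H]) { open[0 + (size_t)c * H] = 1; stack.push_back(0 + c * H); }
    if (lab(H - 1, c) == 0 && !open[(H - 1) + (size_t)c * H]) { open[(H - 1) + (size_t)c * H] = 1; stack.push_back(H - 1 + c * H); }
  }
  for (int r = 0; r < H; ++r) {
    if (lab(r, 0) == 0 && !open[r]) { open[r] = 1; stack.push_back(r); }
    if (lab(r, W - 1) == 0 && !open[r + (size_t)(W - 1) * H]) { open[r + (size_t)(W - 1) * H] = 1; stack.push_back(r + (W - 1) * H); }
  }
  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int pr = p % H, pc = p / H;
    for (int k = 0; k < 4; ++k) {
      int nr = pr + dr4[k], nc = pc + dc4[k];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      size_t q = nr + (size_t)nc * H;
      if (lab(nr, nc) == 0 && !open[q]) { open[q] = 1; stack.push_back(nr + nc * H); }
    }
  }
  // assign each hole pixel to the label of an adjacent foreground pixel
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (lab(r, c) != 0 || open[r + (size_t)c * H]) continue;
      int owner = 0;
      for (int dr = -1; dr <= 1 && owner == 0; ++dr)
        for (int dc = -1; dc <= 1 && owner == 0; ++dc) {
          int nr = r + dr, nc = c + dc;
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (lab(nr, nc) > 0) owner = lab(nr, nc);
        }
      if (owner == 0) {
        // nested hole pixel whose 8-neighbourhood is all background:
        // walk right until a labelled pixel is met
        for (int cc = c + 1; cc < W; ++cc)
          if (lab(r, cc) > 0) { owner = lab(r, cc); break; }
      }
      if (owner > 0) area[owner - 1] += 1.0;
    }
  }
  return area;
}

// Moore-neighbour boundary trace of one labelled component with Jacob's
// stopping criterion. Returns the ordered closed external boundary as
// 1-based (x = column, y = row) pixel-centre coordinates; holes are never
// visited because the trace starts at the topmost-leftmost pixel and walks
// the outer boundary only.
// [[Rcpp::export(name = ".trace_contour_cpp")]]
NumericMatrix trace_contour_cpp(IntegerMatrix lab, int id, int start_r, int start_c) {
  const int H = lab.nrow(), W = lab.ncol();
  // clockwise Moore neighbourhood in (row, col) offsets, starting west
  const int mr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int mc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<int> xs, ys;
  xs.reserve(256); ys.reserve(256);
  xs.push_back(start_c + 1); ys.push_back(start_r + 1);

  // scan from `dir` clockwise for the first pixel of this component
  auto scan = [&](int r, int c, int dir) {
    for (int k = 0; k < 8; ++k) {
      int d = (dir + k) % 8;
      int nr = r + mr[d], nc = c + mc[d];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      if (lab(nr, nc) == id) return d;
    }
    return -1;
  };

  // the west neighbour of the topmost-leftmost pixel is background
  int d1 = scan(start_r, start_c, 0);
  if (d1 < 0) { // isolated single pixel
    NumericMatrix out(1, 2);
    out(0, 0) = start_c + 1; out(0, 1) = start_r + 1;
    return out;
  }
  int r = start_r + mr[d1], c = start_c + mc[d1];
  int dir = (d1 + 6) % 8; // backtrack for a clockwise trace
  const long guard_max = 8L * H * W;
  for (long guard = 0; guard < guard_max; ++guard) {
    bool at_start = (r == start_r && c == start_c);
    int d = scan(r, c, dir);
    if (d < 0) break; // cannot happen for a multi-pixel component
    if (at_start && d == d1) break; // Jacob's criterion: leaving start the same way again
    xs.push_back(c + 1); ys.push_back(r + 1);
    r += mr[d]; c += mc[d];
    dir = (d + 6) % 8;
  }
  NumericMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  return out;
}

// Exact Euclidean nearest-site transform (Felzenszwalb & Huttenlocher
// lower-envelope algorithm applied per column then per row). For every
// pixel returns the label of the nearest foreground pixel and the squared
// Euclidean distance to it. Ties between equidistant sites are broken
// deterministically by the transform's scan order (smallest site column,
// then smallest site row).
// [[Rcpp::export(name = ".nearest_label_cpp")]]
List nearest_label_cpp(IntegerMatrix lab) {
  const int H = lab.nrow(), W = lab.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dy2(static_cast<size_t>(H) * W, INF);
  std::vector<int> frow(static_cast<size_t>(H) * W, -1);

  // pass 1: per column, nearest foreground row (tie -> smaller row)
  for (int c = 0; c < W; ++c) {
    int last = -1;
    for (int r = 0; r < H; ++r) {
      if (lab(r, c) > 0) last = r;
      if (last >= 0) {
        double d = (double)(r - last) * (r - last);
        size_t q = r + (size_t)c * H;
        dy2[q] = d; frow[q] = last;
      }
    }
    last = -1;
    for (int r = H - 1; r >= 0; --r) {
      if (lab(r, c) > 0) last = r;
      if (last >= 0) {
        double d = (double)(last - r) * (last - r);
        size_t q = r + (size_t)c * H;
        if (d < dy2[q]) { dy2[q] = d; frow[q] = last; } // strict: tie keeps smaller row
      }
    }
  }

  IntegerMatrix out(H, W);
  NumericMatrix dist2(H, W);
  std::vector<int> v(W);
  std::vector<double> z(W + 1);

  // pass 2: per row, 1D lower envelope across columns
  for (int r = 0; r < H; ++r) {
    int k = -1;
    for (int c = 0; c < W; ++c) {
      double f = dy2[r + (size_t)c * H];
      if (f == INF) continue;
      double s = 0.0;
      while (k >= 0) {
        double fv = dy2[r + (size_t)v[k] * H];
        s = ((f + (double)c * c) - (fv + (double)v[k] * v[k])) / (2.0 * (c - v[k]));
        if (s <= z[k]) --k; else break;
      }
      if (k < 0) { k = 0; v[0] = c; z[0] = -INF; z[1] = INF; }
      else { ++k; v[k] = c; z[k] = s; z[k + 1] = INF; }
    }
    if (k < 0) { // no foreground anywhere
      for (int c = 0; c < W; ++c) { out(r, c) = NA_INTEGER; dist2(r, c) = NA_REAL; }
      continue;
    }
    int j = 0;
    for (int c = 0; c < W; ++c) {
      while (z[j + 1] < c) ++j; // strict: at an exact tie stay on the lower column
      int site_c = v[j];
      size_t q = r + (size_t)site_c * H;
      double d = dy2[q] + (double)(c - site_c) * (c - site_c);
      out(r, c) = lab(frow[q], site_c);
      dist2(r, c) = d;
    }
  }
  return List::create(_["label"] = out, _["dist2"] = dist2);
}

// Minimum distance from each query point to a closed polyline (vertices
// given in order; the segment last->first closes it). Used by the LSTP
// grid search.
// [[Rcpp::export(name = ".min_dist_to_polyline_cpp")]]
NumericVector min_dist_to_polyline_cpp(NumericMatrix pts, NumericMatrix poly) {
  const int n = pts.nrow(), m = poly.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      int j2 = (j + 1) % m;
      double ax = poly(j, 0), ay = poly(j, 1);
      double bx = poly(j2, 0), by = poly(j2, 1);
      double dx = bx - ax, dy = by - ay;
      double L2 = dx * dx + dy * dy;
      double t = L2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / L2 : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double ex = px - (ax + t * dx), ey = py - (ay + t * dy);
      double d2 = ex * ex + ey * ey;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
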