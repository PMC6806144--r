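#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Pixel-level primitives shared by the segmentation, region-analysis and
// circle-detection layers. Coordinates follow the package convention:
// x = column, y = row, both 0-based; matrices are indexed (row, col).

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  const int nn = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int k = 0; k < nn; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Fill interior holes: background is flood-filled 4-connected from the image
// border; background pixels never reached are holes and become foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix reach(H, W); // background reachable from border
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; c += (r == 0 || r == H - 1) ? 1 : (W > 1 ? W - 1 : 1)) {
      if (!mask(r, c) && !reach(r, c)) { reach(r, c) = true; q.push(std::make_pair(r, c)); }
    }
  }
  static const int dr[4] = {-1, 0, 0, 1};
  static const int dc[4] = {0, -1, 1, 0};
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int k = 0; k < 4; ++k) {
      int rr = p.first + dr[k], cc = p.second + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (!mask(rr, cc) && !reach(rr, cc)) { reach(rr, cc) = true; q.push(std::make_pair(rr, cc)); }
    }
  }
  LogicalMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = mask(r, c) || !reach(r, c);
  return out;
}

// Binary erosion/dilation with an arbitrary structuring element given as
// (dr, dc) offsets. Outside the image counts as background.
// [[Rcpp::export]]
LogicalMatrix cpp_binary_morph(const LogicalMatrix& mask, const IntegerMatrix& offsets, bool erode) {
  const int H = mask.nrow(), W = mask.ncol(), n = offsets.nrow();
  LogicalMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (erode) {
        bool all = true;
        for (int k = 0; k < n && all; ++k) {
          int rr = r + offsets(k, 0), cc = c + offsets(k, 1);
          if (rr < 0 || rr >= H || cc < 0 || cc >= W || !mask(rr, cc)) all = false;
        }
        out(r, c) = all;
      } else {
        bool any = false;
        for (int k = 0; k < n && !any; ++k) {
          int rr = r + offsets(k, 0), cc = c + offsets(k, 1);
          if (rr >= 0 && rr < H && cc >= 0 && cc < W && mask(rr, cc)) any = true;
        }
        out(r, c) = any;
      }
    }
  }
  return out;
}

// Moore-neighbour tracing of the outer contour of the component containing
// the start pixel (must be its topmost, then leftmost, foreground pixel).
// Returns an ordered closed boundary as 0-based (row, col) pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_trace_boundary(const LogicalMatrix& mask, int sr, int sc) {
  const int H = mask.nrow(), W = mask.ncol();
  // clockwise Moore neighbourhood starting west
  static const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  static const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<int> rows, cols;
  rows.push_back(sr); cols.push_back(sc);
  // Single-pixel component?
  bool lone = true;
  for (int k = 0; k < 8; ++k) {
    int rr = sr + dr[k], cc = sc + dc[k];
    if (rr >= 0 && rr < H && cc >= 0 && cc < W && mask(rr, cc)) { lone = false; break; }
  }
  if (!lone) {
    int cr = sr, cc = sc;
    int backtrack = 0; // came from the west (start pixel is topmost-leftmost)
    int guard = 8 * H * W;
    while (guard-- > 0) {
      int found = -1;
      for (int k = 0; k < 8; ++k) {
        int dir = (backtrack + k) % 8;
        int rr = cr + dr[dir], c2 = cc + dc[dir];
        if (rr >= 0 && rr < H && c2 >= 0 && c2 < W && mask(rr, c2)) { found = dir; break; }
      }
      if (found < 0) break; // isolated after all (shouldn't happen)
      int nr = cr + dr[found], nc = cc + dc[found];
      // Jacob's stopping criterion: back at start entering from same direction
      if (nr == sr && nc == sc && rows.size() > 1) break;
      rows.push_back(nr); cols.push_back(nc);
      // new backtrack: direction pointing to the previous pixel, advanced one
      backtrack = (found + 5) % 8; // opposite is +4; start scan one past it
      cr = nr; cc = nc;
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) { out(i, 0) = rows[i]; out(i, 1) = cols[i]; }
  return out;
}

// Circle Hough transform on a set of edge points. Full (cx, cy, r)
// accumulator at 1-px resolution; votes for a candidate centre/radius count
// edge points whose rounded distance equals the radius. Peaks are scored as
// supported fraction of the circle perimeter (radius bins pooled +-1),
// thresholded at vote_frac, sorted by score and greedily merged: a candidate
// is absorbed by an already-kept circle when the centre distance is below
// merge_dist_frac * min(radius) and the relative radius difference is below
// merge_radius_tol.
// Returns a matrix with columns cx, cy, r, score.
// [[Rcpp::export]]
NumericMatrix cpp_hough_circles(const NumericMatrix& edges,
                                int cx0, int cx1, int cy0, int cy1,
                                int rmin, int rmax, double vote_frac,
                                double merge_dist_frac, double merge_radius_tol,
                                int max_circles) {
  const int n = edges.nrow();
  const int nx = cx1 - cx0 + 1, ny = cy1 - cy0 + 1, nr = rmax - rmin + 1;
  NumericMatrix empty(0, 4);
  if (n < 3 || nx <= 0 || ny <= 0 || nr <= 0) return empty;
  std::vector<int> acc((size_t)nx * ny * nr, 0);
  for (int iy = 0; iy < ny; ++iy) {
    double cy = cy0 + iy;
    for (int ix = 0; ix < nx; ++ix) {
      double cx = cx0 + ix;
      size_t base = ((size_t)iy * nx + ix) * nr;
      for (int e = 0; e < n; ++e) {
        double dx = edges(e, 0) - cx, dy = edges(e, 1) - cy;
        int ri = (int)std::floor(std::sqrt(dx * dx + dy * dy) + 0.5) - rmin;
        if (ri >= 0 && ri < nr) acc[base + ri]++;
      }
    }
  }
  struct Cand { double score; int cx, cy, r; };
  std::vector<Cand> cands;
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      size_t base = ((size_t)iy * nx + ix) * nr;
      for (int ir = 0; ir < nr; ++ir) {
        int v = acc[base + ir];
        if (ir > 0) v += acc[base + ir - 1];
        if (ir < nr - 1) v += acc[base + ir + 1];
        double r = rmin + ir;
        double score = v / (2.0 * M_PI * r);
        if (score >= vote_frac) {
          Cand c; c.score = score; c.cx = cx0 + ix; c.cy = cy0 + iy; c.r = (int)r;
          cands.push_back(c);
        }
      }
    }
  }
  if (cands.empty()) return empty;
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.r != b.r) return a.r < b.r;
    if (a.cy != b.cy) return a.cy < b.cy;
    return a.cx < b.cx;
  });
  std::vector<Cand> kept;
  for (size_t i = 0; i < cands.size() && (int)kept.size() < max_circles; ++i) {
    bool merged = false;
    for (size_t j = 0; j < kept.size(); ++j) {
      double dx = cands[i].cx - kept[j].cx, dy = cands[i].cy - kept[j].cy;
      double d = std::sqrt(dx * dx + dy * dy);
      double rm = std::min(cands[i].r, kept[j].r);
      double rd = std::fabs((double)cands[i].r - kept[j].r) / rm;
      if (d < merge_dist_frac * rm && rd < merge_radius_tol) { merged = true; break; }
      // containment suppression: weaker candidate centred inside a kept
      // circle of larger radius is accumulator bleed, not a second fruit
      if (d < kept[j].r && cands[i].r <= kept[j].r) { merged = true; break; }
    }
    if (!merged) kept.push_back(cands[i]);
  }
  NumericMatrix out(kept.size(), 4);
  for (size_t i = 0; i < kept.size(); ++i) {
    out(i, 0) = kept[i].cx; out(i, 1) = kept[i].cy;
    out(i, 2) = kept[i].r;  out(i, 3) = kept[i].score;
  }
  colnames(out) = CharacterVector::create("cx", "cy", "r", "score");
  return out;
}

// Per-degree centroid-to-boundary distances: march along each ray in `step`
// px increments up to rmax and keep the outermost sample still inside the
// mask. Degrees with no foreground sample at all get distance -1 (the caller
// raises the centroid-outside error). Returns 360 x 3: distance, x, y.
// [[Rcpp::export]]
NumericMatrix cpp_polar_profile(const LogicalMatrix& mask, double cx, double cy,
                                double step, double rmax) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix out(360, 3);
  for (int d = 0; d < 360; ++d) {
    double th = d * M_PI / 180.0;
    double ct = std::cos(th), st = std::sin(th);
    double best = -1.0, bx = cx, by = cy;
    for (double t = 0.0; t <= rmax; t += step) {
      double x = cx + t * ct, y = cy + t * st;
      int c = (int)std::floor(x + 0.5), r = (int)std::floor(y + 0.5);
      if (c < 0 || c >= W || r < 0 || r >= H) continue;
      if (mask(r, c)) { best = t; bx = x; by = y; }
    }
    out(d, 0) = best; out(d, 1) = bx; out(d, 2) = by;
  }
  colnames(out) = CharacterVector::create("distance", "x", "y");
  return out;
}
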