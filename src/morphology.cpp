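#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Matrices are R column-major: index = c * nr + r. Raster order (top-left
// first, row by row) therefore iterates r outer only when scanning by rows;
// all raster-sensitive loops below do exactly that.

static inline bool inb(int r, int c, int nr, int nc) {
  return r >= 0 && r < nr && c >= 0 && c < nc;
}

// Grayscale morphological reconstruction by dilation of `marker` under
// `mask` (marker <= mask elementwise), 8-connectivity. Hybrid algorithm:
// forward and backward raster sweeps followed by FIFO queue propagation
// (Vincent-style), exact for arbitrary real-valued images.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must have identical dimensions");
  NumericMatrix J(clone(marker));
  // clamp marker under mask
  for (int i = 0; i < nr * nc; ++i)
    if (J[i] > mask[i]) J[i] = mask[i];

  const int drp[4] = {0, -1, -1, -1};  // N+: W, NW, N, NE
  const int dcp[4] = {-1, -1, 0, 1};
  const int drm[4] = {0, 1, 1, 1};     // N-: E, SE, S, SW
  const int dcm[4] = {1, 1, 0, -1};

  // forward raster sweep
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + drp[k], cc = c + dcp[k];
        if (inb(rr, cc, nr, nc) && J(rr, cc) > v) v = J(rr, cc);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
    }
  }
  // backward sweep + queue seeding
  std::queue<int> q;
  for (int r = nr - 1; r >= 0; --r) {
    for (int c = nc - 1; c >= 0; --c) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + drm[k], cc = c + dcm[k];
        if (inb(rr, cc, nr, nc) && J(rr, cc) > v) v = J(rr, cc);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
      for (int k = 0; k < 4; ++k) {
        int rr = r + drm[k], cc = c + dcm[k];
        if (inb(rr, cc, nr, nc) &&
            J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
          q.push(c * nr + r);
          break;
        }
      }
    }
  }
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int r = idx % nr, c = idx / nr;
    double vp = J(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], cc = c + dc8[k];
      if (!inb(rr, cc, nr, nc)) continue;
      double vq = J(rr, cc), mq = mask(rr, cc);
      if (vq < vp && vq < mq) {
        J(rr, cc) = vp < mq ? vp : mq;
        q.push(cc * nr + rr);
      }
    }
  }
  return J;
}

// 8-connected component labeling of a logical matrix. Labels are assigned
// in raster order of each component's first (top-left-most) pixel, so label
// 1 is always the component whose first pixel comes earliest in a row-wise
// scan -- this makes downstream tie-breaking deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix bin) {
  int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!bin(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(c * nr + r);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (inb(r2, c2, nr, nc) && bin(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(c2 * nr + r2);
          }
        }
      }
    }
  }
  return lab;
}

// Regional maxima of a grayscale image, 8-connectivity: a plateau (maximal
// connected set of equal-valued pixels) is a regional maximum iff no pixel
// 8-adjacent to it has a strictly greater value. Returns a logical matrix.
// [[Rcpp::export]]
LogicalMatrix cpp_regional_maxima(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<char> seen((size_t)nr * nc, 0);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::vector<int> stack, plateau;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int idx0 = c * nr + r;
      if (seen[idx0]) continue;
      double v = img(r, c);
      bool higher = false;
      plateau.clear();
      stack.push_back(idx0);
      seen[idx0] = 1;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        plateau.push_back(idx);
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (!inb(r2, c2, nr, nc)) continue;
          double v2 = img(r2, c2);
          if (v2 > v) higher = true;
          else if (v2 == v) {
            int idx2 = c2 * nr + r2;
            if (!seen[idx2]) { seen[idx2] = 1; stack.push_back(idx2); }
          }
        }
      }
      if (!higher)
        for (size_t i = 0; i < plateau.size(); ++i) out[plateau[i]] = true;
    }
  }
  return out;
}

// Traced perimeter of each labeled 8-connected component, in pixel units.
// Moore-neighbor contour tracing from the raster-first pixel of each
// component; consecutive contour pixels contribute 1 for axial moves and
// sqrt(2) for diagonal moves. An isolated pixel has no moves: perimeter 0.
// Only the outer contour is traced (holes are handled by the caller).
// [[Rcpp::export]]
NumericVector cpp_trace_perimeter(IntegerMatrix lab, int nlabels) {
  int nr = lab.nrow(), nc = lab.ncol();
  NumericVector out(nlabels);
  if (nlabels == 0) return out;
  std::vector<int> startr(nlabels, -1), startc(nlabels, -1);
  std::vector<long> area(nlabels, 0);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int L = lab(r, c);
      if (L > 0 && L <= nlabels) {
        if (startr[L - 1] < 0) { startr[L - 1] = r; startc[L - 1] = c; }
        ++area[L - 1];
      }
    }
  // clockwise Moore neighborhood starting at W
  const int dr8[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc8[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const double sq2 = std::sqrt(2.0);
  for (int L = 1; L <= nlabels; ++L) {
    int r0 = startr[L - 1], c0 = startc[L - 1];
    if (r0 < 0) { out[L - 1] = NA_REAL; continue; }
    int cr = r0, cc0 = c0, b = 0;  // backtrack dir index (W of start: bg)
    double len = 0.0;
    long moves = 0, guard = 8 * area[L - 1] + 16;
    int firstr = -1, firstc = -1, firstj = -1;
    bool closed = false;
    while (!closed && moves <= guard) {
      bool found = false;
      for (int k = 0; k < 8; ++k) {
        int j = (b + k) % 8;
        int rr = cr + dr8[j], cc = cc0 + dc8[j];
        if (!inb(rr, cc, nr, nc) || lab(rr, cc) != L) continue;
        if (moves > 0 && cr == firstr && cc0 == firstc && j == firstj) {
          closed = true; found = true; break;
        }
        if (moves == 0) { firstr = cr; firstc = cc0; firstj = j; }
        len += (dr8[j] != 0 && dc8[j] != 0) ? sq2 : 1.0;
        ++moves;
        int prev = (j + 7) % 8;
        int br = cr + dr8[prev], bc = cc0 + dc8[prev];
        cr = rr; cc0 = cc;
        int ddr = br - cr, ddc = bc - cc0;
        b = 0;
        for (int t = 0; t < 8; ++t)
          if (dr8[t] == ddr && dc8[t] == ddc) { b = t; break; }
        found = true;
        break;
      }
      if (!found) break;  // isolated pixel
    }
    out[L - 1] = len;
  }
  return out;
}
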