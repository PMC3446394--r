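#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a binary matrix (0 = background).
// Components are numbered in column-major scan order, so component 1 contains
// the foreground pixel with the smallest linear index.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(IntegerMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = {0, 0, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int r0 = idx % nr, c0 = idx / nr;
        for (int k = 0; k < nd; ++k) {
          const int r2 = r0 + dr[k], c2 = c0 + dc[k];
          if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc &&
              mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Per-region area and maximal pixel-centroid distance for a label matrix
// (labels 1..nlab, 0 = background). Returns an nlab x 2 matrix [area, maxdist].
// [[Rcpp::export]]
NumericMatrix region_stats_cpp(IntegerMatrix lab, int nlab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  std::vector<double> area(nlab, 0.0), sr(nlab, 0.0), sc(nlab, 0.0), md2(nlab, 0.0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      const int l = lab(r, c);
      if (l > 0) { area[l - 1] += 1.0; sr[l - 1] += r; sc[l - 1] += c; }
    }
  for (int l = 0; l < nlab; ++l)
    if (area[l] > 0) { sr[l] /= area[l]; sc[l] /= area[l]; }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      const int l = lab(r, c);
      if (l > 0) {
        const double d2 = (r - sr[l - 1]) * (r - sr[l - 1]) +
                          (c - sc[l - 1]) * (c - sc[l - 1]);
        if (d2 > md2[l - 1]) md2[l - 1] = d2;
      }
    }
  NumericMatrix out(nlab, 2);
  for (int l = 0; l < nlab; ++l) {
    out(l, 0) = area[l];
    out(l, 1) = std::sqrt(md2[l]);
  }
  return out;
}

// SGF support: for each threshold alpha = 1..15 of a 16-level quantized ROI
// (invalid pixels coded -1), label the 8-connected regions of the stack
// B_alpha = (level >= alpha) and of its within-mask complement, and return
// the four curves over alpha: region counts (NOC1, NOC0) and area-weighted
// mean irregularities (IRGL1, IRGL0), with
// irregularity = max(0, sqrt(pi) * maxdist_centroid / sqrt(area) - 1).
namespace {

struct RegionAgg {
  double wsum = 0.0, asum = 0.0;
  int count = 0;
};

RegionAgg label_and_measure(const std::vector<signed char>& fg, int nr, int nc,
                            std::vector<int>& lab, std::vector<int>& stack) {
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::fill(lab.begin(), lab.end(), 0);
  RegionAgg agg;
  std::vector<double> area, sr, sc;
  int next = 0;
  const int n = nr * nc;
  for (int idx = 0; idx < n; ++idx) {
    if (!fg[idx] || lab[idx] != 0) continue;
    ++next;
    area.push_back(0.0); sr.push_back(0.0); sc.push_back(0.0);
    lab[idx] = next;
    stack.clear();
    stack.push_back(idx);
    while (!stack.empty()) {
      const int id = stack.back(); stack.pop_back();
      const int r0 = id % nr, c0 = id / nr;
      area[next - 1] += 1.0; sr[next - 1] += r0; sc[next - 1] += c0;
      for (int k = 0; k < 8; ++k) {
        const int r2 = r0 + dr8[k], c2 = c0 + dc8[k];
        if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) {
          const int id2 = r2 + c2 * nr;
          if (fg[id2] && lab[id2] == 0) { lab[id2] = next; stack.push_back(id2); }
        }
      }
    }
  }
  agg.count = next;
  if (next == 0) return agg;
  std::vector<double> md2(next, 0.0);
  for (int l = 0; l < next; ++l) { sr[l] /= area[l]; sc[l] /= area[l]; }
  for (int idx = 0; idx < n; ++idx) {
    const int l = lab[idx];
    if (l > 0) {
      const int r0 = idx % nr, c0 = idx / nr;
      const double d2 = (r0 - sr[l - 1]) * (r0 - sr[l - 1]) +
                        (c0 - sc[l - 1]) * (c0 - sc[l - 1]);
      if (d2 > md2[l - 1]) md2[l - 1] = d2;
    }
  }
  for (int l = 0; l < next; ++l) {
    double irr = std::sqrt(M_PI) * std::sqrt(md2[l]) / std::sqrt(area[l]) - 1.0;
    if (irr < 0) irr = 0;
    agg.wsum += area[l] * irr;
    agg.asum += area[l];
  }
  return agg;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix sgf_curves_cpp(IntegerMatrix levels) {
  const int nr = levels.nrow(), nc = levels.ncol(), n = nr * nc;
  NumericMatrix out(15, 4);  // columns: NOC1, NOC0, IRGL1, IRGL0
  std::vector<signed char> fg(n);
  std::vector<int> lab(n), stack;
  for (int a = 1; a <= 15; ++a) {
    for (int idx = 0; idx < n; ++idx) {
      const int v = levels[idx];
      fg[idx] = (v != NA_INTEGER && v >= 0 && v >= a) ? 1 : 0;
    }
    RegionAgg r1 = label_and_measure(fg, nr, nc, lab, stack);
    for (int idx = 0; idx < n; ++idx) {
      const int v = levels[idx];
      fg[idx] = (v != NA_INTEGER && v >= 0 && v < a) ? 1 : 0;
    }
    RegionAgg r0 = label_and_measure(fg, nr, nc, lab, stack);
    out(a - 1, 0) = r1.count;
    out(a - 1, 1) = r0.count;
    out(a - 1, 2) = r1.asum > 0 ? r1.wsum / r1.asum : 0.0;
    out(a - 1, 3) = r0.asum > 0 ? r0.wsum / r0.asum : 0.0;
  }
  return out;
}

// Run-length counting along one direction (dr, dc): counts of maximal
// runs of equal quantized level, indexed by (level 0..15, run length).
// NA levels (off-mask) break runs.
// [[Rcpp::export]]
IntegerMatrix rl_counts_cpp(IntegerMatrix levels, int dr, int dc) {
  const int nr = levels.nrow(), nc = levels.ncol();
  std::vector<std::vector<int> > counts(16);
  int lmax = 1;
  auto flush = [&](int lev, int len) {
    if (len <= 0 || lev < 0 || lev > 15) return;
    if (len > lmax) lmax = len;
    if ((int)counts[lev].size() < len) counts[lev].resize(len, 0);
    counts[lev][len - 1] += 1;
  };
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      // start of a scan line: no predecessor inside the image
      const int rp = r0 - dr, cp = c0 - dc;
      if (rp >= 0 && rp < nr && cp >= 0 && cp < nc) continue;
      int cur = -1, len = 0;
      int r = r0, c = c0;
      while (r >= 0 && r < nr && c >= 0 && c < nc) {
        const int v = levels(r, c);
        const bool na = (v == NA_INTEGER);
        if (!na && v == cur) ++len;
        else {
          flush(cur, len);
          cur = na ? -1 : v;
          len = na ? 0 : 1;
        }
        r += dr; c += dc;
      }
      flush(cur, len);
    }
  }
  IntegerMatrix out(16, lmax);
  for (int l = 0; l < 16; ++l)
    for (int k = 0; k < (int)counts[l].size(); ++k)
      out(l, k) = counts[l][k];
  return out;
}

// Moore-neighbour boundary tracing of the outer contour of a binary
// mask, 8-connected, starting at the first foreground pixel in
// column-major scan order. Returns the ordered closed boundary as
// 1-based (row, col) pairs.
// [[Rcpp::export]]
IntegerMatrix trace_contour_cpp(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  // clockwise: N, NE, E, SE, S, SW, W, NW
  static const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  static const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  int r0 = -1, c0 = -1;
  for (int c = 0; c < nc && r0 < 0; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c) != 0) { r0 = r; c0 = c; break; }
  if (r0 < 0) stop("mask has no foreground pixels");
  auto fg = [&](int r, int c) {
    return r >= 0 && r < nr && c >= 0 && c < nc && mask(r, c) != 0;
  };
  std::vector<int> rows, cols;
  int r = r0, c = c0;
  int back = 0;  // backtrack direction: the scan predecessor to the north
  int first_move = -1;
  const int maxit = 4 * (nr + nc) * 8 + 8 * nr * nc;
  for (int it = 0; it < maxit; ++it) {
    rows.push_back(r + 1);
    cols.push_back(c + 1);
    int move = -1;
    for (int k = 1; k <= 8; ++k) {
      const int d = (back + k) % 8;
      if (fg(r + dr[d], c + dc[d])) { move = d; break; }
    }
    if (move < 0) break;                       // isolated pixel
    if (r == r0 && c == c0) {
      if (first_move < 0) first_move = move;   // first departure from start
      else if (move == first_move && it > 0) { // Jacob's stopping criterion
        rows.pop_back(); cols.pop_back();
        break;
      }
    }
    r += dr[move];
    c += dc[move];
    back = (move + 4) % 8;  // the cell we came from; scan resumes after it
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
  }
  return out;
}

// Binary erosion (mode 0) or dilation (mode 1) by an arbitrary offset
// set; pixels outside the image count as background.
// [[Rcpp::export]]
IntegerMatrix morph_cpp(IntegerMatrix mask, IntegerMatrix offs, int mode) {
  const int nr = mask.nrow(), nc = mask.ncol(), K = offs.nrow();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      bool v = (mode == 0);
      for (int k = 0; k < K; ++k) {
        const int rr = r + offs(k, 0), cc = c + offs(k, 1);
        const bool in = rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
                        mask(rr, cc) != 0;
        if (mode == 0) { if (!in) { v = false; break; } }
        else if (in) { v = true; break; }
      }
      out(r, c) = v ? 1 : 0;
    }
  }
  return out;
}
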