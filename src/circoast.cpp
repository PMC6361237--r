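#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Binary dilation of `mask` by the structuring element given as a list of
// (drow, dcol) offsets. Clipped at the image border: no pixels outside the
// image are ever created or consulted. Only pixels with at least one false
// (or out-of-bounds-missing) 4-neighbour are stamped; interior pixels of the
// mask are covered by the dilation of the boundary because the element is a
// centred disk containing the origin and its 4-neighbours whenever r >= 1.
// [[Rcpp::export]]
LogicalMatrix cpp_dilate(const LogicalMatrix& mask, const IntegerMatrix& offsets) {
  const int h = mask.nrow(), w = mask.ncol(), k = offsets.nrow();
  LogicalMatrix out(h, w);
  // start from the mask itself (offsets always include the origin)
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      out(i, j) = mask(i, j);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j)) continue;
      bool boundary =
        (i == 0 || !mask(i - 1, j)) || (i == h - 1 || !mask(i + 1, j)) ||
        (j == 0 || !mask(i, j - 1)) || (j == w - 1 || !mask(i, j + 1));
      if (!boundary) continue;
      for (int t = 0; t < k; ++t) {
        const int r = i + offsets(t, 0), c = j + offsets(t, 1);
        if (r >= 0 && r < h && c >= 0 && c < w) out(r, c) = true;
      }
    }
  }
  return out;
}

// Nearest-seed (Euclidean) label for every pixel, exact integer arithmetic,
// ties broken toward the lowest seed index. Seeds are 0-based (row, col).
// Bucketed ring search keeps this near-linear in the pixel count.
// [[Rcpp::export]]
IntegerMatrix cpp_nearest_labels(int h, int w, const IntegerMatrix& seeds) {
  const int ns = seeds.nrow();
  if (ns < 1) stop("at least one seed required");
  int bs = (int)std::ceil(std::sqrt((double)h * (double)w / (double)ns));
  if (bs < 4) bs = 4;
  const int gb_r = (h + bs - 1) / bs, gb_c = (w + bs - 1) / bs;
  std::vector< std::vector<int> > bucket((size_t)gb_r * gb_c);
  for (int s = 0; s < ns; ++s) {
    const int br = seeds(s, 0) / bs, bc = seeds(s, 1) / bs;
    bucket[(size_t)br * gb_c + bc].push_back(s);
  }
  IntegerMatrix lab(h, w);
  const int max_ring = gb_r + gb_c + 2;
  for (int i = 0; i < h; ++i) {
    const int pbr = i / bs;
    for (int j = 0; j < w; ++j) {
      const int pbc = j / bs;
      long best = -1; int bidx = -1;
      for (int ring = 0; ring <= max_ring; ++ring) {
        if (best >= 0) {
          // ring at Chebyshev bucket distance `ring` cannot hold anything
          // closer than (ring-1)*bs pixels
          const long lo = (long)(ring - 1) * bs;
          if (lo > 0 && lo * lo > best) break;
        }
        const int r0 = pbr - ring, r1 = pbr + ring, c0 = pbc - ring, c1 = pbc + ring;
        for (int br = r0; br <= r1; ++br) {
          if (br < 0 || br >= gb_r) continue;
          const bool edge_row = (br == r0 || br == r1);
          for (int bc = c0; bc <= c1; ++bc) {
            if (bc < 0 || bc >= gb_c) continue;
            if (!edge_row && bc != c0 && bc != c1) continue; // ring only
            const std::vector<int>& v = bucket[(size_t)br * gb_c + bc];
            for (size_t t = 0; t < v.size(); ++t) {
              const int s = v[t];
              const long dr = i - seeds(s, 0), dc = j - seeds(s, 1);
              const long d2 = dr * dr + dc * dc;
              if (best < 0 || d2 < best || (d2 == best && s < bidx)) {
                best = d2; bidx = s;
              }
            }
          }
        }
      }
      lab(i, j) = bidx + 1; // 1-based labels
    }
  }
  return lab;
}

// 8-connected component labelling (0 = background, components 1..K).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * h);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % h, pj = p / h;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= h || qj < 0 || qj >= w) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * h);
            }
          }
        }
      }
    }
  }
  return lab;
}

static inline bool px(const LogicalMatrix& m, int i, int j) {
  return i >= 0 && i < m.nrow() && j >= 0 && j < m.ncol() && m(i, j);
}

// Guo-Hall parallel thinning to a 1-pixel-wide skeleton (8-connected
// centreline). Chosen over Zhang-Suen, whose simultaneous form annihilates
// 2-pixel staircases and whose sequential form leaves them unthinned;
// Guo-Hall's connectivity operator C(p) handles diagonal runs cleanly.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  LogicalMatrix img = clone(mask);
  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < w; ++j) {
        for (int i = 0; i < h; ++i) {
          if (!img(i, j)) continue;
          // neighbours p2..p9 clockwise from north
          const bool p2 = px(img, i - 1, j),     p3 = px(img, i - 1, j + 1),
                     p4 = px(img, i,     j + 1), p5 = px(img, i + 1, j + 1),
                     p6 = px(img, i + 1, j),     p7 = px(img, i + 1, j - 1),
                     p8 = px(img, i,     j - 1), p9 = px(img, i - 1, j - 1);
          const int C = ((!p2) && (p3 || p4)) + ((!p4) && (p5 || p6)) +
                        ((!p6) && (p7 || p8)) + ((!p8) && (p9 || p2));
          if (C != 1) continue;
          const int N1 = (p9 || p2) + (p3 || p4) + (p5 || p6) + (p7 || p8);
          const int N2 = (p2 || p3) + (p4 || p5) + (p6 || p7) + (p8 || p9);
          const int N = N1 < N2 ? N1 : N2;
          if (N < 2 || N > 3) continue;
          const bool m = pass == 0 ? ((p6 || p7 || !p9) && p8)
                                   : ((p2 || p3 || !p5) && p4);
          if (m) continue;
          kill.push_back(i + j * h);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t t = 0; t < kill.size(); ++t)
        img(kill[t] % h, kill[t] / h) = false;
    }
  }
  return img;
}

// Sequential random placement of non-overlapping, fully contained pixelated
// disks. `forbidden` lists centre offsets under which two disks would share
// at least one pixel (the Minkowski sum of the disk with itself, includes
// the origin). A free-position index with O(1) swap-removal makes uniform
// sampling over the remaining admissible centres exact; rejection sampling
// over all pixels conditioned on admissibility gives the same law.
// Saturation (no admissible centre left) is detected exactly.
// Uses R's RNG, so set.seed() governs reproducibility.
// [[Rcpp::export]]
List cpp_place_nonoverlap(int h, int w, int margin, const IntegerMatrix& forbidden,
                          int nmax) {
  const long npx = (long)h * w;
  std::vector<int> pos;          // linear indices of currently free centres
  std::vector<int> where(npx, -1); // position of a pixel in `pos`, -1 if gone
  pos.reserve(npx);
  for (int j = margin; j < w - margin; ++j)
    for (int i = margin; i < h - margin; ++i) {
      where[i + (long)j * h] = (int)pos.size();
      pos.push_back(i + j * h);
    }
  const int k = forbidden.nrow();
  std::vector<int> rows, cols;
  while ((nmax < 0 || (int)rows.size() < nmax) && !pos.empty()) {
    int j = (int)(unif_rand() * pos.size());
    if (j >= (int)pos.size()) j = (int)pos.size() - 1;
    const int centre = pos[j];
    const int ci = centre % h, cj = centre / h;
    rows.push_back(ci); cols.push_back(cj);
    for (int t = 0; t < k; ++t) {
      const int r = ci + forbidden(t, 0), c = cj + forbidden(t, 1);
      if (r < 0 || r >= h || c < 0 || c >= w) continue;
      const long q = r + (long)c * h;
      const int at = where[q];
      if (at < 0) continue;
      const int last = pos.back();
      pos[at] = last;
      where[last] = at;
      pos.pop_back();
      where[q] = -1;
    }
  }
  IntegerMatrix centers((int)rows.size(), 2);
  for (size_t t = 0; t < rows.size(); ++t) {
    centers((int)t, 0) = rows[t];
    centers((int)t, 1) = cols[t];
  }
  return List::create(_["centers"] = centers, _["saturated"] = pos.empty());
}
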