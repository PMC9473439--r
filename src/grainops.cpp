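#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-neighbour offsets, clockwise from North
static const int DR8[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC8[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};

// Topology-preservation lookup: for each of the 256 neighbourhood
// configurations, is the centre pixel "simple" (deletable without changing
// the number of foreground or background components)? bit i corresponds to
// neighbour i in DR8/DC8 order.
static bool simple_lut[256];
static bool lut_ready = false;

// number of 8-connected components of set bits among the 8 neighbours
static int fg_components(int cfg) {
  bool cell[8];
  for (int i = 0; i < 8; i++) cell[i] = (cfg >> i) & 1;
  bool seen[8] = {false};
  int comps = 0;
  for (int i = 0; i < 8; i++) {
    if (!cell[i] || seen[i]) continue;
    comps++;
    std::queue<int> q;
    q.push(i);
    seen[i] = true;
    while (!q.empty()) {
      int a = q.front(); q.pop();
      for (int b = 0; b < 8; b++) {
        if (cell[b] && !seen[b]) {
          int dr = DR8[a] - DR8[b], dc = DC8[a] - DC8[b];
          // adjacency between neighbourhood cells (8-adjacent positions)
          if (dr >= -1 && dr <= 1 && dc >= -1 && dc <= 1) {
            seen[b] = true;
            q.push(b);
          }
        }
      }
    }
  }
  return comps;
}

// number of 4-connected background components among the 8 neighbours that
// touch the centre through a 4-neighbour
static int bg_components(int cfg) {
  bool cell[8];
  for (int i = 0; i < 8; i++) cell[i] = !((cfg >> i) & 1);
  bool seen[8] = {false};
  int comps = 0;
  for (int i = 0; i < 8; i++) {
    if (!cell[i] || seen[i]) continue;
    // grow the 4-connected component containing cell i
    std::vector<int> comp;
    std::queue<int> q;
    q.push(i);
    seen[i] = true;
    comp.push_back(i);
    while (!q.empty()) {
      int a = q.front(); q.pop();
      for (int b = 0; b < 8; b++) {
        if (cell[b] && !seen[b]) {
          int dr = DR8[a] - DR8[b], dc = DC8[a] - DC8[b];
          if ((dr == 0 && (dc == 1 || dc == -1)) ||
              (dc == 0 && (dr == 1 || dr == -1))) {
            seen[b] = true;
            q.push(b);
            comp.push_back(b);
          }
        }
      }
    }
    // component counts only if it contains a 4-neighbour of the centre
    bool touches = false;
    for (size_t k = 0; k < comp.size(); k++) {
      int idx = comp[k];
      if (DR8[idx] == 0 || DC8[idx] == 0) { touches = true; break; }
    }
    if (touches) comps++;
  }
  return comps;
}

static void build_lut() {
  for (int cfg = 0; cfg < 256; cfg++)
    simple_lut[cfg] = (fg_components(cfg) == 1) && (bg_components(cfg) == 1);
  lut_ready = true;
}

static inline int neighbour_cfg(const IntegerMatrix& m, int r, int c) {
  int nr = m.nrow(), nc = m.ncol(), cfg = 0;
  for (int i = 0; i < 8; i++) {
    int rr = r + DR8[i], cc = c + DC8[i];
    if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && m(rr, cc) != 0)
      cfg |= (1 << i);
  }
  return cfg;
}

static inline int neighbour_count(const IntegerMatrix& m, int r, int c) {
  int nr = m.nrow(), nc = m.ncol(), n = 0;
  for (int i = 0; i < 8; i++) {
    int rr = r + DR8[i], cc = c + DC8[i];
    if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && m(rr, cc) != 0) n++;
  }
  return n;
}

// Sequential directional thinning to a unit-width, topology-preserving
// skeleton. Border pixels are peeled in N/S/E/W subcycles; a pixel is
// removed only if it is simple at the moment of removal and is not a path
// endpoint (<= 1 foreground neighbour). Deleting only simple points
// guarantees the component count and hole structure of the input survive.
// [[Rcpp::export]]
IntegerMatrix thin_mask(IntegerMatrix mask) {
  if (!lut_ready) build_lut();
  IntegerMatrix m = clone(mask);
  int nr = m.nrow(), nc = m.ncol();
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 4; dir++) {
      int dr = DR4[dir], dc = DC4[dir];
      // collect current border pixels for this direction
      std::vector<std::pair<int,int> > border;
      for (int c = 0; c < nc; c++) {
        for (int r = 0; r < nr; r++) {
          if (m(r, c) == 0) continue;
          int rr = r + dr, cc = c + dc;
          bool bg = (rr < 0 || rr >= nr || cc < 0 || cc >= nc) ||
                    (m(rr, cc) == 0);
          if (bg) border.push_back(std::make_pair(r, c));
        }
      }
      for (size_t k = 0; k < border.size(); k++) {
        int r = border[k].first, c = border[k].second;
        if (m(r, c) == 0) continue;
        int rr = r + dr, cc = c + dc;
        bool bg = (rr < 0 || rr >= nr || cc < 0 || cc >= nc) ||
                  (m(rr, cc) == 0);
        if (!bg) continue;
        int nn = neighbour_count(m, r, c);
        if (nn <= 1) continue;        // endpoint or isolated pixel: keep
        if (simple_lut[neighbour_cfg(m, r, c)]) {
          m(r, c) = 0;
          changed = true;
        }
      }
    }
  }
  return m;
}

// Connected-component labelling by BFS; connectivity 4 or 8.
// [[Rcpp::export]]
IntegerMatrix label_components(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int nnb = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? DR8 : DR4;
  const int* dc = (connectivity == 8) ? DC8 : DC4;
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int c = 0; c < nc; c++) {
    for (int r = 0; r < nr; r++) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      next++;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int i = 0; i < nnb; i++) {
          int rr = p.first + dr[i], cc = p.second + dc[i];
          if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
              mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Exact area-average (box) downsampling of one channel. Each output pixel
// averages the input over its back-projected rectangle with fractional
// edge weights, the standard anti-aliased resampler for shrinking.
// [[Rcpp::export]]
NumericMatrix resize_area_cpp(NumericMatrix img, int out_nr, int out_nc) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(out_nr, out_nc);
  double sr = (double)nr / out_nr, sc = (double)nc / out_nc;
  for (int oc = 0; oc < out_nc; oc++) {
    double c0 = oc * sc, c1 = (oc + 1) * sc;
    int ci0 = (int)std::floor(c0), ci1 = (int)std::ceil(c1);
    if (ci1 > nc) ci1 = nc;
    for (int orow = 0; orow < out_nr; orow++) {
      double r0 = orow * sr, r1 = (orow + 1) * sr;
      int ri0 = (int)std::floor(r0), ri1 = (int)std::ceil(r1);
      if (ri1 > nr) ri1 = nr;
      double acc = 0.0, wacc = 0.0;
      for (int c = ci0; c < ci1; c++) {
        double wc = std::min((double)c + 1, c1) - std::max((double)c, c0);
        for (int r = ri0; r < ri1; r++) {
          double wr = std::min((double)r + 1, r1) - std::max((double)r, r0);
          acc += img(r, c) * wr * wc;
          wacc += wr * wc;
        }
      }
      out(orow, oc) = acc / wacc;
    }
  }
  return out;
}

// Foreground fraction of the window_size x window_size window centred on
// each pixel, computed from an integral image. Pixels beyond the matrix
// edge count as background (the paper sheet continues past the photo), so
// the fraction is always normalised by the full window area.
// [[Rcpp::export]]
NumericMatrix window_fraction_cpp(IntegerMatrix mask, int window_size) {
  int nr = mask.nrow(), nc = mask.ncol();
  int rad = window_size / 2;
  // integral image: S(r, c) = sum of mask[0..r-1, 0..c-1]
  std::vector<double> S((nr + 1) * (nc + 1), 0.0);
  for (int c = 0; c < nc; c++)
    for (int r = 0; r < nr; r++)
      S[(r + 1) + (c + 1) * (nr + 1)] =
        (double)(mask(r, c) != 0) +
        S[r + (c + 1) * (nr + 1)] + S[(r + 1) + c * (nr + 1)] -
        S[r + c * (nr + 1)];
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; c++) {
    int c0 = std::max(0, c - rad), c1 = std::min(nc - 1, c + rad);
    for (int r = 0; r < nr; r++) {
      int r0 = std::max(0, r - rad), r1 = std::min(nr - 1, r + rad);
      double s = S[(r1 + 1) + (c1 + 1) * (nr + 1)] -
                 S[r0 + (c1 + 1) * (nr + 1)] -
                 S[(r1 + 1) + c0 * (nr + 1)] + S[r0 + c0 * (nr + 1)];
      out(r, c) = s / ((double)window_size * window_size);
    }
  }
  return out;
}
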