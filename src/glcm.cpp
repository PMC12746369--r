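#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Displacements for the four canonical offsets, (row, col) with row
// increasing downward: 0deg -> (0,+d), 45deg -> (-d,+d), 90deg -> (-d,0),
// 135deg -> (-d,-d).
static inline void offset_disp(int angle, int d, int &drow, int &dcol) {
  switch (angle) {
  case 0:   drow = 0;  dcol = d;  break;
  case 45:  drow = -d; dcol = d;  break;
  case 90:  drow = -d; dcol = 0;  break;
  case 135: drow = -d; dcol = -d; break;
  default: stop("angle must be one of 0, 45, 90, 135");
  }
}

// Linear quantization of [lo, hi] into L equal bins; values <= lo map to
// bin 0, values >= hi to bin L-1. A degenerate range (hi <= lo) collapses
// everything onto level 0.
static inline int quantize_one(double x, double lo, double hi, int L) {
  if (hi <= lo) return 0;
  if (x <= lo) return 0;
  if (x >= hi) return L - 1;
  int q = (int)std::floor((x - lo) / (hi - lo) * (double)L);
  if (q > L - 1) q = L - 1;
  if (q < 0) q = 0;
  return q;
}

// [[Rcpp::export]]
IntegerMatrix cpp_quantize(NumericMatrix img, int L, double lo, double hi) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = quantize_one(img(i, j), lo, hi, L);
  return out;
}

// Accumulate co-occurrence counts for the window [r0, r0+side) x [c0, c0+side)
// of q into the L x L buffer `counts` (caller zeroes it). Returns total count.
static double glcm_window(const IntegerMatrix &q, int r0, int c0,
                          int hgt, int wid, int drow, int dcol,
                          bool symmetric, std::vector<double> &counts, int L) {
  double total = 0.0;
  for (int c = 0; c < wid; ++c) {
    int cn = c + dcol;
    if (cn < 0 || cn >= wid) continue;
    for (int r = 0; r < hgt; ++r) {
      int rn = r + drow;
      if (rn < 0 || rn >= hgt) continue;
      int a = q(r0 + r, c0 + c);
      int b = q(r0 + rn, c0 + cn);
      counts[(size_t)a + (size_t)L * b] += 1.0;
      total += 1.0;
      if (symmetric) {
        counts[(size_t)b + (size_t)L * a] += 1.0;
        total += 1.0;
      }
    }
  }
  return total;
}

// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerMatrix q, int L, int angle, int d,
                              bool symmetric) {
  int drow, dcol;
  offset_disp(angle, d, drow, dcol);
  std::vector<double> buf((size_t)L * L, 0.0);
  double total = glcm_window(q, 0, 0, q.nrow(), q.ncol(), drow, dcol,
                             symmetric, buf, L);
  NumericMatrix out(L, L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i)
      out(i, j) = buf[(size_t)i + (size_t)L * j];
  out.attr("total") = total;
  return out;
}

// Five Haralick statistics from an L x L probability buffer (column-major).
// Order: contrast, correlation, energy, homogeneity, entropy (nats).
// Correlation is NA when either marginal has zero variance.
static void haralick_stats(const std::vector<double> &P, int L, double *f) {
  double contrast = 0.0, energy = 0.0, homog = 0.0, entropy = 0.0;
  std::vector<double> pi(L, 0.0), pj(L, 0.0);
  for (int j = 0; j < L; ++j) {
    for (int i = 0; i < L; ++i) {
      double p = P[(size_t)i + (size_t)L * j];
      if (p == 0.0) continue;
      double dij = (double)(i - j);
      contrast += dij * dij * p;
      energy += p * p;
      homog += p / (1.0 + std::fabs(dij));
      entropy -= p * std::log(p);
      pi[i] += p;
      pj[j] += p;
    }
  }
  double mui = 0.0, muj = 0.0;
  for (int k = 0; k < L; ++k) {
    mui += (double)k * pi[k];
    muj += (double)k * pj[k];
  }
  double vi = 0.0, vj = 0.0;
  for (int k = 0; k < L; ++k) {
    vi += ((double)k - mui) * ((double)k - mui) * pi[k];
    vj += ((double)k - muj) * ((double)k - muj) * pj[k];
  }
  double corr;
  if (vi <= 0.0 || vj <= 0.0) {
    corr = NA_REAL;
  } else {
    double s = 0.0;
    for (int j = 0; j < L; ++j)
      for (int i = 0; i < L; ++i) {
        double p = P[(size_t)i + (size_t)L * j];
        if (p != 0.0) s += ((double)i - mui) * ((double)j - muj) * p;
      }
    corr = s / (std::sqrt(vi) * std::sqrt(vj));
  }
  f[0] = contrast; f[1] = corr; f[2] = energy; f[3] = homog; f[4] = entropy;
}

// [[Rcpp::export]]
NumericVector cpp_haralick(NumericMatrix P) {
  int L = P.nrow();
  if (P.ncol() != L) stop("P must be square");
  std::vector<double> buf((size_t)L * L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i)
      buf[(size_t)i + (size_t)L * j] = P(i, j);
  NumericVector out(5);
  double f[5];
  haralick_stats(buf, L, f);
  for (int k = 0; k < 5; ++k) out[k] = f[k];
  out.names() = CharacterVector::create("contrast", "correlation", "energy",
                                        "homogeneity", "entropy");
  return out;
}

// Sliding-window texture maps. The image is quantized once against [lo, hi];
// per window each of the four offsets yields a GLCM, its five features are
// computed, and the per-feature mean over the offsets (in the order 0, 45,
// 90, 135) is placed at the window centre. Returns a list of five H x W maps
// (NA outside computed centres).
// [[Rcpp::export]]
List cpp_texture_map(NumericMatrix img, int side, int stride, int L,
                     double lo, double hi, int d, bool symmetric) {
  int H = img.nrow(), W = img.ncol();
  if (side > H || side > W) stop("window larger than image");
  int half = (side - 1) / 2;
  IntegerMatrix q = cpp_quantize(img, L, lo, hi);

  const int angles[4] = {0, 45, 90, 135};
  int drow[4], dcol[4];
  for (int a = 0; a < 4; ++a) offset_disp(angles[a], d, drow[a], dcol[a]);

  List maps(5);
  std::vector<NumericMatrix> M;
  for (int k = 0; k < 5; ++k) {
    NumericMatrix m(H, W);
    std::fill(m.begin(), m.end(), NA_REAL);
    maps[k] = m;
    M.push_back(m);
  }

  std::vector<double> counts((size_t)L * L), P((size_t)L * L);
  for (int rc = half; rc + half < H; rc += stride) {
    for (int cc = half; cc + half < W; cc += stride) {
      double acc[5] = {0, 0, 0, 0, 0};
      bool ok = true;
      for (int a = 0; a < 4 && ok; ++a) {
        std::fill(counts.begin(), counts.end(), 0.0);
        double total = glcm_window(q, rc - half, cc - half, side, side,
                                   drow[a], dcol[a], symmetric, counts, L);
        if (total <= 0.0) { ok = false; break; }
        for (size_t t = 0; t < P.size(); ++t) P[t] = counts[t] / total;
        double f[5];
        haralick_stats(P, L, f);
        for (int k = 0; k < 5; ++k) acc[k] += f[k];
      }
      if (!ok) continue;
      for (int k = 0; k < 5; ++k) M[k](rc, cc) = acc[k] / 4.0;
    }
  }
  maps.names() = CharacterVector::create("contrast", "correlation", "energy",
                                         "homogeneity", "entropy");
  return maps;
}

// Distance from each pixel centre to a segment (x1,y1)-(x2,y2) in pixel
// coordinates, restricted to a bounding box; used to render capsule-shaped
// cells. Returns a matrix of distances over the full field.
// [[Rcpp::export]]
NumericMatrix cpp_segment_distance(int H, int W, double r1, double c1,
                                   double r2, double c2, double rad) {
  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), R_PosInf);
  int rlo = std::max(0, (int)std::floor(std::min(r1, r2) - rad - 1));
  int rhi = std::min(H - 1, (int)std::ceil(std::max(r1, r2) + rad + 1));
  int clo = std::max(0, (int)std::floor(std::min(c1, c2) - rad - 1));
  int chi = std::min(W - 1, (int)std::ceil(std::max(c1, c2) + rad + 1));
  double vr = r2 - r1, vc = c2 - c1;
  double len2 = vr * vr + vc * vc;
  for (int c = clo; c <= chi; ++c) {
    for (int r = rlo; r <= rhi; ++r) {
      double wr = (double)r - r1, wc = (double)c - c1;
      double t = len2 > 0.0 ? (wr * vr + wc * vc) / len2 : 0.0;
      if (t < 0.0) t = 0.0;
      if (t > 1.0) t = 1.0;
      double dr = wr - t * vr, dc = wc - t * vc;
      out(r, c) = std::sqrt(dr * dr + dc * dc);
    }
  }
  return out;
}
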