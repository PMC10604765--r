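#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Render a speckle frame as a sum of anisotropic Gaussian point-spread
// functions. Positions are 0-based pixel coordinates (x along columns,
// y along rows); evaluation is truncated at 4 sigma per scatterer.
// [[Rcpp::export]]
NumericMatrix cpp_render(NumericVector xs, NumericVector ys, NumericVector amp,
                         int ny, int nx, double sx, double sy) {
  NumericMatrix img(ny, nx);
  const int n = xs.size();
  const double wx = 4.0 * sx, wy = 4.0 * sy;
  const double inv2sx2 = 1.0 / (2.0 * sx * sx);
  const double inv2sy2 = 1.0 / (2.0 * sy * sy);
  for (int k = 0; k < n; ++k) {
    const double x = xs[k], y = ys[k], a = amp[k];
    int j0 = (int)std::ceil(x - wx), j1 = (int)std::floor(x + wx);
    int i0 = (int)std::ceil(y - wy), i1 = (int)std::floor(y + wy);
    if (j0 < 0) j0 = 0;
    if (i0 < 0) i0 = 0;
    if (j1 > nx - 1) j1 = nx - 1;
    if (i1 > ny - 1) i1 = ny - 1;
    for (int j = j0; j <= j1; ++j) {
      const double ex = std::exp(-(j - x) * (j - x) * inv2sx2);
      for (int i = i0; i <= i1; ++i) {
        img(i, j) += a * ex * std::exp(-(i - y) * (i - y) * inv2sy2);
      }
    }
  }
  return img;
}

static inline double ncc_at(const NumericMatrix &a, const NumericMatrix &b,
                            int ci, int cj, int di, int dj, int h) {
  // zero-mean normalized cross-correlation between the kernel of `a`
  // centred at (ci, cj) and the window of `b` displaced by (di, dj)
  const int n = (2 * h + 1) * (2 * h + 1);
  double sa = 0, sb = 0;
  for (int j = -h; j <= h; ++j)
    for (int i = -h; i <= h; ++i) {
      sa += a(ci + i, cj + j);
      sb += b(ci + di + i, cj + dj + j);
    }
  const double ma = sa / n, mb = sb / n;
  double num = 0, va = 0, vb = 0;
  for (int j = -h; j <= h; ++j)
    for (int i = -h; i <= h; ++i) {
      const double da = a(ci + i, cj + j) - ma;
      const double db = b(ci + di + i, cj + dj + j) - mb;
      num += da * db;
      va += da * da;
      vb += db * db;
    }
  if (va <= 1e-12 || vb <= 1e-12) return 0.0;
  return num / std::sqrt(va * vb);
}

static inline double sad_at(const NumericMatrix &a, const NumericMatrix &b,
                            int ci, int cj, int di, int dj, int h) {
  double s = 0;
  for (int j = -h; j <= h; ++j)
    for (int i = -h; i <= h; ++i)
      s += std::fabs(a(ci + i, cj + j) - b(ci + di + i, cj + dj + j));
  return s;
}

// Block matching on a grid of kernel centres.
//
// a, b       consecutive frames (ny x nx), kernels taken from `a`
// ci, cj     0-based kernel-centre rows/cols; caller guarantees that the
//            kernel plus the full search window stay inside both frames
// half_k     kernel half-size (kernel is (2*half_k+1)^2)
// radius     integer search radius (scores computed over the full window,
//            needed for parabolic refinement at the candidate boundary)
// sad        0 = NCC (maximised), 1 = SAD (minimised)
// d_cap      candidate-lag cap in pixels (Euclidean); best integer lags are
//            restricted to |lag| <= d_cap, mirroring a tracker whose search
//            distance is proportional to its velocity limit. Pass a huge
//            value for an uncapped search.
//
// Ties on the selection score are broken deterministically: smallest lag
// magnitude, then smallest |di|, |dj|, then signed di, dj.
//
// Returns an n x 5 matrix: columns di, dj (best integer lag, rows/cols),
// dy, dx (sub-pixel refined lag), quality (NCC at the best integer lag).
// [[Rcpp::export]]
NumericMatrix cpp_match_grid(NumericMatrix a, NumericMatrix b,
                             IntegerVector ci, IntegerVector cj,
                             int half_k, int radius, int sad, double d_cap,
                             int gaussfit) {
  const int nker = ci.size();
  const int w = 2 * radius + 1;
  NumericMatrix out(nker, 5);

  // deterministic candidate order: by magnitude^2, then |di|, |dj|, di, dj
  std::vector<std::array<int, 2>> lags;
  lags.reserve(w * w);
  for (int di = -radius; di <= radius; ++di)
    for (int dj = -radius; dj <= radius; ++dj)
      lags.push_back({di, dj});
  std::sort(lags.begin(), lags.end(),
            [](const std::array<int, 2> &p, const std::array<int, 2> &q) {
              int mp = p[0] * p[0] + p[1] * p[1];
              int mq = q[0] * q[0] + q[1] * q[1];
              if (mp != mq) return mp < mq;
              if (std::abs(p[0]) != std::abs(q[0]))
                return std::abs(p[0]) < std::abs(q[0]);
              if (std::abs(p[1]) != std::abs(q[1]))
                return std::abs(p[1]) < std::abs(q[1]);
              if (p[0] != q[0]) return p[0] < q[0];
              return p[1] < q[1];
            });
  const double cap2 = d_cap * d_cap;

  const int kw = 2 * half_k + 1;
  const int npx = kw * kw;
  std::vector<double> ker(npx);
  std::vector<double> score(w * w);
  for (int k = 0; k < nker; ++k) {
    const int r = ci[k], c = cj[k];
    // zero-mean kernel buffer (NCC numerator then needs no window mean)
    double sa = 0, va = 0;
    for (int j = -half_k; j <= half_k; ++j)
      for (int i = -half_k; i <= half_k; ++i)
        sa += a(r + i, c + j);
    const double ma = sa / npx;
    {
      int p = 0;
      for (int j = -half_k; j <= half_k; ++j)
        for (int i = -half_k; i <= half_k; ++i, ++p) {
          ker[p] = a(r + i, c + j) - ma;
          va += ker[p] * ker[p];
        }
    }
    for (int di = -radius; di <= radius; ++di)
      for (int dj = -radius; dj <= radius; ++dj) {
        double s;
        if (sad) {
          s = -sad_at(a, b, r, c, di, dj, half_k);
        } else {
          double num = 0, sb = 0, sbb = 0;
          int p = 0;
          for (int j = -half_k; j <= half_k; ++j) {
            const int cc = c + dj + j;
            for (int i = -half_k; i <= half_k; ++i, ++p) {
              const double bv = b(r + di + i, cc);
              num += ker[p] * bv;
              sb += bv;
              sbb += bv * bv;
            }
          }
          const double vb = sbb - sb * sb / npx;
          s = (va <= 1e-12 || vb <= 1e-12) ? 0.0 : num / std::sqrt(va * vb);
        }
        score[(di + radius) * w + (dj + radius)] = s;
      }
    int bi = 0, bj = 0;
    double best = -HUGE_VAL;
    for (const auto &lg : lags) {
      if (lg[0] * lg[0] + lg[1] * lg[1] > cap2) continue;
      const double s = score[(lg[0] + radius) * w + (lg[1] + radius)];
      if (s > best) {
        best = s;
        bi = lg[0];
        bj = lg[1];
      }
    }
    // 3-point peak refinement per axis on the selection score:
    // Gaussian (log-parabolic) fit when the three scores allow it — the
    // correlation peak of Gaussian speckle is Gaussian, so this removes
    // most sub-pixel peak locking — with a plain parabolic fallback
    auto refine = [&](double sm, double s0, double sp) -> double {
      double d = 0.0;
      if (gaussfit && sm > 1e-9 && s0 > 1e-9 && sp > 1e-9 &&
          s0 >= sm && s0 >= sp) {
        const double lm = std::log(sm), l0 = std::log(s0),
                     lp = std::log(sp);
        const double den = lm - 2.0 * l0 + lp;
        if (den < -1e-12) d = 0.5 * (lm - lp) / den;
      } else {
        const double den = sm - 2.0 * s0 + sp;
        if (den < -1e-12) d = 0.5 * (sm - sp) / den;
      }
      if (d > 0.5) d = 0.5;
      if (d < -0.5) d = -0.5;
      return d;
    };
    double deli = 0, delj = 0;
    if (bi > -radius && bi < radius) {
      deli = refine(score[(bi - 1 + radius) * w + (bj + radius)],
                    score[(bi + radius) * w + (bj + radius)],
                    score[(bi + 1 + radius) * w + (bj + radius)]);
    }
    if (bj > -radius && bj < radius) {
      delj = refine(score[(bi + radius) * w + (bj - 1 + radius)],
                    score[(bi + radius) * w + (bj + radius)],
                    score[(bi + radius) * w + (bj + 1 + radius)]);
    }
    double q = sad ? ncc_at(a, b, r, c, bi, bj, half_k) : best;
    out(k, 0) = bi;
    out(k, 1) = bj;
    out(k, 2) = bi + deli;
    out(k, 3) = bj + delj;
    out(k, 4) = q;
  }
  return out;
}
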