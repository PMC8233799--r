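#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Mirror (symmetric) reflection with edge duplication: -1 -> 0, n -> n-1.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Normalized patch-kernel weights for offsets (-radp..radp) * stride per axis.
// a == Inf gives the uniform kernel; finite a a Gaussian of spatial std a (pixels).
static std::vector<double> patch_kernel(int radp, int stride, double a) {
  int side = 2 * radp + 1;
  std::vector<double> kw(side * side);
  double total = 0.0;
  for (int dr = -radp; dr <= radp; ++dr) {
    for (int dc = -radp; dc <= radp; ++dc) {
      double w;
      if (!R_FINITE(a)) {
        w = 1.0;
      } else {
        double rr = dr * stride, cc = dc * stride;
        w = std::exp(-(rr * rr + cc * cc) / (2.0 * a * a));
      }
      kw[(dr + radp) * side + (dc + radp)] = w;
      total += w;
    }
  }
  for (double &w : kw) w /= total;
  return kw;
}

// Kernel-weighted squared patch distance between centers (r1,c1) and (r2,c2).
static inline double patch_dist2(const NumericMatrix &img, int r1, int c1,
                                 int r2, int c2, int radp, int stride,
                                 const std::vector<double> &kw) {
  int H = img.nrow(), W = img.ncol();
  int side = 2 * radp + 1;
  double d2 = 0.0;
  for (int dr = -radp; dr <= radp; ++dr) {
    int a1 = reflect_idx(r1 + dr * stride, H);
    int a2 = reflect_idx(r2 + dr * stride, H);
    for (int dc = -radp; dc <= radp; ++dc) {
      int b1 = reflect_idx(c1 + dc * stride, W);
      int b2 = reflect_idx(c2 + dc * stride, W);
      double diff = img(a1, b1) - img(a2, b2);
      d2 += kw[(dr + radp) * side + (dc + radp)] * diff * diff;
    }
  }
  return d2;
}

// Weights over the clipped search window at (r, c). Fills `w` (row-major over
// the clipped window) and returns the window bounds through r0/r1/c0/c1.
// scheme: 0 = patch-only weights with max-non-central self-weight (NLM/RNLM);
//         1 = patch * pixel similarity with rescaled self-weight (RNLM*).
static void window_weights(const NumericMatrix &img, int r, int c,
                           double h, int radp, int rads, double degc,
                           double omega, int stride,
                           const std::vector<double> &kw, int scheme,
                           std::vector<double> &w,
                           int &r0, int &r1, int &c0, int &c1) {
  int H = img.nrow(), W = img.ncol();
  r0 = std::max(0, r - rads); r1 = std::min(H - 1, r + rads);
  c0 = std::max(0, c - rads); c1 = std::min(W - 1, c + rads);
  int wn = (r1 - r0 + 1) * (c1 - c0 + 1);
  w.assign(wn, 0.0);
  double h2 = h * h;
  double yi = img(r, c);
  double maxw = -1.0;
  int kidx = -1;      // argmax over non-central weights, raster order
  int self_idx = (r - r0) * (c1 - c0 + 1) + (c - c0);

  int idx = 0;
  for (int jr = r0; jr <= r1; ++jr) {
    for (int jc = c0; jc <= c1; ++jc, ++idx) {
      if (jr == r && jc == c) continue;
      double d2 = patch_dist2(img, r, c, jr, jc, radp, stride, kw);
      double phi = std::exp(-d2 / h2);
      double wij;
      if (scheme == 1) {
        double dd = std::fabs(yi - img(jr, jc));
        double rho = 1.0 / (1.0 + std::pow(dd / degc, omega));
        wij = phi * rho;
      } else {
        wij = phi;
      }
      w[idx] = wij;
      if (wij > maxw) { maxw = wij; kidx = idx; }
    }
  }

  double self;
  if (scheme == 1 && kidx >= 0) {
    int jr = r0 + kidx / (c1 - c0 + 1);
    int jc = c0 + kidx % (c1 - c0 + 1);
    double dd = std::fabs(yi - img(jr, jc));
    double theta = 1.0;
    if (dd > 0.0) {
      int side = 2 * radp + 1;
      theta = 1.0 + (double)(side * side) /
                    (1.0 + std::pow(degc / dd, omega));
    }
    self = maxw * theta;
  } else {
    self = (maxw > 0.0) ? maxw : 0.0;
  }
  w[self_idx] = self;

  double total = 0.0;
  for (double v : w) total += v;
  if (total <= 0.0) {
    // all similarities underflowed: keep the center pixel untouched
    std::fill(w.begin(), w.end(), 0.0);
    w[self_idx] = 1.0;
    total = 1.0;
  }
  for (double &v : w) v /= total;
}

// variant: 0 = NLM (weighted mean), 1 = RNLM, 2 = RNLM* (Rician-corrected).
// [[Rcpp::export(name = ".nlm_family_cpp")]]
NumericMatrix nlm_family_cpp(NumericMatrix img, double h, int radp, int rads,
                             double degc, double omega, double a, double sigma,
                             int variant, int stride, bool apply_sqrt) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  std::vector<double> kw = patch_kernel(radp, stride, a);
  int scheme = (variant == 2) ? 1 : 0;
  bool rician = (variant != 0);
  double bias = 2.0 * sigma * sigma;
  std::vector<double> w;

  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int r0, r1, c0, c1;
      window_weights(img, r, c, h, radp, rads, degc, omega, stride, kw,
                     scheme, w, r0, r1, c0, c1);
      double acc = 0.0;
      int idx = 0;
      for (int jr = r0; jr <= r1; ++jr) {
        for (int jc = c0; jc <= c1; ++jc, ++idx) {
          double y = img(jr, jc);
          acc += w[idx] * (rician ? y * y : y);
        }
      }
      if (rician) {
        double v = std::max(acc - bias, 0.0);
        out(r, c) = apply_sqrt ? std::sqrt(v) : v;
      } else {
        out(r, c) = acc;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".weight_field_cpp")]]
List weight_field_cpp(NumericMatrix img, int r, int c, double h, int radp,
                      int rads, double degc, double omega, double a,
                      int scheme, int stride) {
  std::vector<double> kw = patch_kernel(radp, stride, a);
  std::vector<double> w;
  int r0, r1, c0, c1;
  window_weights(img, r, c, h, radp, rads, degc, omega, stride, kw,
                 scheme, w, r0, r1, c0, c1);
  int nr = r1 - r0 + 1, nc = c1 - c0 + 1;
  NumericMatrix wm(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      wm(i, j) = w[i * nc + j];
  return List::create(_["weights"] = wm,
                      _["row_range"] = IntegerVector::create(r0 + 1, r1 + 1),
                      _["col_range"] = IntegerVector::create(c0 + 1, c1 + 1));
}

// [[Rcpp::export(name = ".box_filter_cpp")]]
NumericMatrix box_filter_cpp(NumericMatrix img, int rad, bool median) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  int side = 2 * rad + 1;
  std::vector<double> buf(side * side);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int n = 0;
      double s = 0.0;
      for (int dr = -rad; dr <= rad; ++dr) {
        int rr = reflect_idx(r + dr, H);
        for (int dc = -rad; dc <= rad; ++dc) {
          int cc = reflect_idx(c + dc, W);
          double v = img(rr, cc);
          buf[n++] = v;
          s += v;
        }
      }
      if (median) {
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
        out(r, c) = buf[n / 2]; // n odd
      } else {
        out(r, c) = s / n;
      }
    }
  }
  return out;
}
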