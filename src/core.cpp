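#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// bilinear sample of a matrix at (row, col) in 0-based fractional pixel
// coordinates; out-of-bounds coordinates are clamped to the nearest edge
static inline double sample_bilinear(const NumericMatrix& m, double r, double c) {
  const int nr = m.nrow(), nc = m.ncol();
  r = clampd(r, 0.0, nr - 1.0);
  c = clampd(c, 0.0, nc - 1.0);
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = r0 + 1 < nr ? r0 + 1 : r0;
  int c1 = c0 + 1 < nc ? c0 + 1 : c0;
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * ((1 - fc) * m(r0, c0) + fc * m(r0, c1)) +
         fr       * ((1 - fc) * m(r1, c0) + fc * m(r1, c1));
}

// [[Rcpp::export(name = ".cs_sample_bilinear")]]
NumericVector cs_sample_bilinear(NumericMatrix img, NumericVector rows,
                                 NumericVector cols) {
  const int n = rows.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_bilinear(img, rows[i], cols[i]);
  return out;
}

// warp an image by a displacement field: out(x) = img(x + u(x))
// [[Rcpp::export(name = ".cs_warp")]]
NumericMatrix cs_warp(NumericMatrix img, NumericMatrix ur, NumericMatrix uc) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = sample_bilinear(img, r + ur(r, c), c + uc(r, c));
  return out;
}

// compose displacement fields: out(x) = a(x) + b(x + a(x)).
// If a maps phase i -> j coordinates and b maps j -> k, out maps i -> k.
// [[Rcpp::export(name = ".cs_compose")]]
List cs_compose(NumericMatrix ar, NumericMatrix ac,
                NumericMatrix br, NumericMatrix bc) {
  const int nr = ar.nrow(), nc = ar.ncol();
  NumericMatrix outr(nr, nc), outc(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double tr = r + ar(r, c), tc = c + ac(r, c);
      outr(r, c) = ar(r, c) + sample_bilinear(br, tr, tc);
      outc(r, c) = ac(r, c) + sample_bilinear(bc, tr, tc);
    }
  return List::create(Named("ur") = outr, Named("uc") = outc);
}

// fixed-point estimate of the inverse displacement field:
// inv(x) <- -fwd(x + inv(x)), iterated
// [[Rcpp::export(name = ".cs_invert_field")]]
List cs_invert_field(NumericMatrix ur, NumericMatrix uc, int iters) {
  const int nr = ur.nrow(), nc = ur.ncol();
  NumericMatrix ir(nr, nc), ic(nr, nc);
  for (int it = 0; it < iters; ++it) {
    NumericMatrix nir(nr, nc), nic(nr, nc);
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double tr = r + ir(r, c), tc = c + ic(r, c);
        nir(r, c) = -sample_bilinear(ur, tr, tc);
        nic(r, c) = -sample_bilinear(uc, tr, tc);
      }
    ir = nir; ic = nic;
  }
  return List::create(Named("ur") = ir, Named("uc") = ic);
}

// separable Gaussian smoothing with reflected borders
// [[Rcpp::export(name = ".cs_gauss_blur")]]
NumericMatrix cs_gauss_blur(NumericMatrix img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto& v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // rows
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0) rr = -rr;
        if (rr >= nr) rr = 2 * nr - 2 - rr;
        if (rr < 0) rr = 0;
        acc += k[i + rad] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  // cols
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0) cc = -cc;
        if (cc >= nc) cc = 2 * nc - 2 - cc;
        if (cc < 0) cc = 0;
        acc += k[i + rad] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  return out;
}

// local (windowed) mean with truncated windows at the borders,
// window = (2*halfwin+1)^2, computed via integral image
// [[Rcpp::export(name = ".cs_box_mean")]]
NumericMatrix cs_box_mean(NumericMatrix img, int halfwin) {
  const int nr = img.nrow(), nc = img.ncol();
  // integral image with a zero first row/col
  std::vector<double> ii((nr + 1) * (nc + 1), 0.0);
  auto I = [&](int r, int c) -> double& { return ii[(size_t)c * (nr + 1) + r]; };
  for (int c = 1; c <= nc; ++c)
    for (int r = 1; r <= nr; ++r)
      I(r, c) = img(r - 1, c - 1) + I(r - 1, c) + I(r, c - 1) - I(r - 1, c - 1);
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    int c0 = std::max(0, c - halfwin), c1 = std::min(nc - 1, c + halfwin);
    for (int r = 0; r < nr; ++r) {
      int r0 = std::max(0, r - halfwin), r1 = std::min(nr - 1, r + halfwin);
      double sum = I(r1 + 1, c1 + 1) - I(r0, c1 + 1) - I(r1 + 1, c0) + I(r0, c0);
      out(r, c) = sum / ((double)(r1 - r0 + 1) * (c1 - c0 + 1));
    }
  }
  return out;
}

// central-difference gradient (one-sided at the borders), unit pixel spacing
// [[Rcpp::export(name = ".cs_gradient")]]
List cs_gradient(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix gr(nr, nc), gc(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int rm = r > 0 ? r - 1 : r, rp = r < nr - 1 ? r + 1 : r;
      int cm = c > 0 ? c - 1 : c, cp = c < nc - 1 ? c + 1 : c;
      gr(r, c) = (img(rp, c) - img(rm, c)) / (double)(rp - rm);
      gc(r, c) = (img(r, cp) - img(r, cm)) / (double)(cp - cm);
    }
  return List::create(Named("dr") = gr, Named("dc") = gc);
}

// Minimum-cost closed path in a polar cost image (DAG over angles), one
// radius bin per angle, |r(theta+1) - r(theta)| <= smoothness, closed:
// r(n_angles) == r(0). Path cost = sum of the n_angles node costs.
// Ties broken by smaller radius sum, then by preferring smaller bins.
// Returns 1-based radius indices and the cost.
// [[Rcpp::export(name = ".cs_closed_path")]]
List cs_closed_path(NumericMatrix cost, int smoothness) {
  const int na = cost.nrow(), nrad = cost.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  double bestCost = INF, bestRadsum = INF;
  std::vector<int> bestPath;
  std::vector<double> dp(nrad), dps(nrad), ndp(nrad), ndps(nrad);
  std::vector<int> back((size_t)na * nrad);
  for (int s = 0; s < nrad; ++s) {
    for (int r = 0; r < nrad; ++r) { dp[r] = INF; dps[r] = INF; }
    dp[s] = cost(0, s); dps[s] = s;
    for (int a = 1; a < na; ++a) {
      for (int r = 0; r < nrad; ++r) {
        double bc = INF, bs = INF; int barg = -1;
        int lo = std::max(0, r - smoothness), hi = std::min(nrad - 1, r + smoothness);
        for (int p = lo; p <= hi; ++p) {
          if (dp[p] < bc || (dp[p] == bc && dps[p] < bs)) {
            bc = dp[p]; bs = dps[p]; barg = p;
          }
        }
        if (barg >= 0 && bc < INF) {
          ndp[r] = bc + cost(a, r);
          ndps[r] = bs + r;
          back[(size_t)a * nrad + r] = barg;
        } else {
          ndp[r] = INF; ndps[r] = INF;
          back[(size_t)a * nrad + r] = -1;
        }
      }
      dp.swap(ndp); dps.swap(ndps);
    }
    // close the loop: last angle's bin must be within smoothness of s
    int lo = std::max(0, s - smoothness), hi = std::min(nrad - 1, s + smoothness);
    for (int r = lo; r <= hi; ++r) {
      if (dp[r] < bestCost || (dp[r] == bestCost && dps[r] < bestRadsum)) {
        bestCost = dp[r]; bestRadsum = dps[r];
        std::vector<int> path(na);
        path[na - 1] = r;
        for (int a = na - 1; a > 0; --a)
          path[a - 1] = back[(size_t)a * nrad + path[a]];
        bestPath = path;
      }
    }
  }
  if (!std::isfinite(bestCost)) stop("no feasible closed path");
  IntegerVector out(na);
  for (int a = 0; a < na; ++a) out[a] = bestPath[a] + 1;
  return List::create(Named("radii") = out, Named("cost") = bestCost);
}
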