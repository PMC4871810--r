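#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Average fraction folded of an n-helix chain by a forward-backward
// transfer-matrix pass, O(n) per denaturant point. Accumulators are
// renormalised at every step so arbitrarily large Boltzmann weights
// (encountered during random multi-start fitting) cannot overflow.
//
// Forward: (f_i, u_i) = weight of helices 1..i with helix i folded/unfolded,
//   f_i = k_i (t_{i-1,i} f_{i-1} + u_{i-1}),  u_i = f_{i-1} + u_{i-1}.
// Backward: (bf_i, bu_i) = weight of helices i+1..n conditional on the state
// of helix i. P(helix i folded) = f_i * bf_i / q.
static double theta_one(const std::vector<double>& k,
                        const std::vector<double>& t, int n) {
  std::vector<double> F(n), U(n), Ls(n), Bf(n), Bu(n), Lb(n);
  double f = 0.0, u = 1.0, lsc = 0.0;
  for (int i = 0; i < n; ++i) {
    double ti = (i == 0) ? 1.0 : t[i - 1];
    double fi = k[i] * (ti * f + u);
    double ui = f + u;
    double s = fi + ui;
    lsc += std::log(s);
    f = fi / s;
    u = ui / s;
    F[i] = f; U[i] = u; Ls[i] = lsc;
  }
  const double lq = Ls[n - 1];
  double bf = 1.0, bu = 1.0, lbc = 0.0;
  Bf[n - 1] = 1.0; Bu[n - 1] = 1.0; Lb[n - 1] = 0.0;
  for (int i = n - 2; i >= 0; --i) {
    double bfi = k[i + 1] * t[i] * bf + bu;
    double bui = k[i + 1] * bf + bu;
    double s = bfi + bui;
    lbc += std::log(s);
    bf = bfi / s;
    bu = bui / s;
    Bf[i] = bf; Bu[i] = bu; Lb[i] = lbc;
  }
  double acc = 0.0;
  for (int i = 0; i < n; ++i)
    acc += F[i] * Bf[i] * std::exp(Ls[i] + Lb[i] - lq);
  return acc / n;
}

static void fill_weights(const NumericVector& Gh, const NumericVector& mh,
                         const NumericVector& Gt, const NumericVector& mt,
                         double RT, double x,
                         std::vector<double>& k, std::vector<double>& t) {
  const int n = Gh.size();
  for (int i = 0; i < n; ++i)
    k[i] = std::exp(-(Gh[i] + mh[i] * x) / RT);
  for (int i = 0; i + 1 < n; ++i)
    t[i] = std::exp(-(Gt[i] + mt[i] * x) / RT);
}

// Average fraction folded on a denaturant grid for one topology. Gh, mh:
// per-helix intrinsic free energies and active intrinsic m-values; Gt, mt:
// per-interface free energies and active interfacial m-values; RT kcal/mol.
// [[Rcpp::export]]
NumericVector theta_f_grid_cpp(NumericVector Gh, NumericVector mh,
                               NumericVector Gt, NumericVector mt,
                               double RT, NumericVector x) {
  const int n = Gh.size(), nx = x.size();
  NumericVector theta(nx);
  if (n == 0) return theta;
  std::vector<double> k(n), t(n > 0 ? n - 1 : 0);
  for (int j = 0; j < nx; ++j) {
    fill_weights(Gh, mh, Gt, mt, RT, x[j], k, t);
    theta[j] = theta_one(k, t, n);
  }
  return theta;
}

// Stacked residuals y - (1 - theta) for a whole curve series sharing one
// parameter vector. 'views' holds, per curve, 1-based indices into 'par'
// for the helix free energies (hG), helix m-values (hm, empty = inactive),
// interface free energies (iG) and interface m-values (im, empty =
// inactive), plus the x and y data of that curve.
// [[Rcpp::export]]
NumericVector series_residuals_cpp(NumericVector par, List views, double RT) {
  int total = 0;
  const int nc = views.size();
  for (int c = 0; c < nc; ++c) {
    List v = views[c];
    total += as<NumericVector>(v["x"]).size();
  }
  NumericVector out(total);
  int pos = 0;
  for (int c = 0; c < nc; ++c) {
    List v = views[c];
    IntegerVector hG = v["hG"], hm = v["hm"], iG = v["iG"], im = v["im"];
    NumericVector x = v["x"], y = v["y"];
    const int n = hG.size(), nx = x.size();
    std::vector<double> k(n), t(n > 0 ? n - 1 : 0);
    const bool has_hm = hm.size() > 0, has_im = im.size() > 0;
    for (int j = 0; j < nx; ++j) {
      for (int i = 0; i < n; ++i) {
        double m = has_hm ? par[hm[i] - 1] : 0.0;
        k[i] = std::exp(-(par[hG[i] - 1] + m * x[j]) / RT);
      }
      for (int i = 0; i + 1 < n; ++i) {
        double m = has_im ? par[im[i] - 1] : 0.0;
        t[i] = std::exp(-(par[iG[i] - 1] + m * x[j]) / RT);
      }
      out[pos++] = y[j] - (1.0 - theta_one(k, t, n));
    }
  }
  return out;
}
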