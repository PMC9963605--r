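#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Closed-form concentration after a single oral dose routed through
// n_transit transit compartments (rate ktr each), an absorption
// compartment (rate ka) and a one-compartment disposition with
// ke = CL/V1.  Laplace inversion of
//   C(s) = dose * ktr^n * ka / (V1 * (s+ktr)^n * (s+ka) * (s+ke))
// gives simple poles at -ka and -ke and a pole of order n at -ktr, so
//   C(t) = sum_i coef_i * t^pow_i * exp(-lam_i * t).
// Caller must keep ka, ktr, ke pairwise distinct; near-coincident rates
// are nudged apart (tiny multiplicative shift) so an optimizer crossing
// a degenerate ridge sees a finite, continuous-to-within-1e-9 surface.
// The user-facing R wrapper switches to a matrix-exponential evaluation
// well before the nudge matters.

struct ModeSet {
  std::vector<double> lam;
  std::vector<int> pow;
  std::vector<double> coef;
};

static ModeSet transit_modes(double dose, double ka, double ktr,
                             double CL, double V1, int n) {
  double ke = CL / V1;
  // nudge near-coincident rates apart (relative gap < 1e-7)
  const double gap = 1e-7;
  if (std::fabs(ka - ke) < gap * std::max(ka, ke)) ke *= 1.0 + gap;
  if (n > 0) {
    if (std::fabs(ktr - ka) < gap * std::max(ktr, ka)) ktr *= 1.0 + gap;
    if (std::fabs(ktr - ke) < gap * std::max(ktr, ke)) ktr *= 1.0 + 2.0 * gap;
  }
  ModeSet m;
  double scale = dose * ka / V1 * std::pow(ktr, n);
  m.lam.push_back(ka); m.pow.push_back(0);
  m.lam.push_back(ke); m.pow.push_back(0);
  if (n == 0) {
    m.coef.push_back(scale / (ke - ka));
    m.coef.push_back(scale / (ka - ke));
  } else {
    m.coef.push_back(scale / (std::pow(ktr - ka, n) * (ke - ka)));
    m.coef.push_back(scale / (std::pow(ktr - ke, n) * (ka - ke)));
    for (int mm = 0; mm < n; ++mm) {
      // residue expansion of the order-n pole at -ktr:
      // coef = scale * (-1)^mm * (1/(ka-ktr)^{mm+1} - 1/(ke-ktr)^{mm+1})
      //        / ((ke-ka) * (n-1-mm)!)
      double sgn = (mm % 2) ? -1.0 : 1.0;
      double g = sgn / (ke - ka) *
        (1.0 / std::pow(ka - ktr, mm + 1) - 1.0 / std::pow(ke - ktr, mm + 1));
      double fact = 1.0;
      for (int i = 2; i <= n - 1 - mm; ++i) fact *= i;
      m.lam.push_back(ktr);
      m.pow.push_back(n - 1 - mm);
      m.coef.push_back(scale * g / fact);
    }
  }
  return m;
}

static double eval_modes_at(const ModeSet& m, double t) {
  if (t <= 0.0) return 0.0;
  double out = 0.0;
  for (size_t i = 0; i < m.lam.size(); ++i) {
    double term = m.coef[i] * std::exp(-m.lam[i] * t);
    for (int p = 0; p < m.pow[i]; ++p) term *= t;
    out += term;
  }
  return out;
}

// [[Rcpp::export(name = ".conc_transit_cpp")]]
NumericVector conc_transit_cpp(NumericVector t, double dose, double ka,
                               double ktr, double CL, double V1,
                               int n_transit) {
  ModeSet m = transit_modes(dose, ka, ktr, CL, V1, n_transit);
  NumericVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i) out[i] = eval_modes_at(m, t[i]);
  return out;
}

// Penalized least-squares objective for the empirical-Bayes (MAP) fit on
// the log scale: phi are log-deviations from the typical values
// (order ka, ktr, CL, V1),
//   obj = sum((log c_obs - log c_pred)^2) / sigma^2 + sum(phi^2 / w2)
// with w2 the effective prior variances. Non-finite intermediate values
// return a large penalty so line searches back off.
// [[Rcpp::export(name = ".map_objective_cpp")]]
double map_objective_cpp(NumericVector phi, NumericVector log_typ,
                         NumericVector w2, double dose,
                         NumericVector times, NumericVector log_obs,
                         double sigma2, int n_transit) {
  double ka = std::exp(log_typ[0] + phi[0]);
  double ktr = std::exp(log_typ[1] + phi[1]);
  double CL = std::exp(log_typ[2] + phi[2]);
  double V1 = std::exp(log_typ[3] + phi[3]);
  if (!std::isfinite(ka) || !std::isfinite(ktr) ||
      !std::isfinite(CL) || !std::isfinite(V1))
    return 1e30;
  ModeSet m = transit_modes(dose, ka, ktr, CL, V1, n_transit);
  double obj = 0.0;
  for (R_xlen_t i = 0; i < times.size(); ++i) {
    double c = eval_modes_at(m, times[i]);
    if (!(c > 0.0) || !std::isfinite(c)) return 1e30;
    double r = log_obs[i] - std::log(c);
    obj += r * r;
  }
  obj /= sigma2;
  for (int j = 0; j < 4; ++j) {
    if (w2[j] > 0) obj += phi[j] * phi[j] / w2[j];
    else if (phi[j] != 0.0) return 1e30;  // zero prior variance pins phi at 0
  }
  if (!std::isfinite(obj)) return 1e30;
  return obj;
}
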