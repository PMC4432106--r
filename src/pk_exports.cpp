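#include <Rcpp.h>
#include "pk.h"

using namespace Rcpp;

static tks::Regimen make_reg(double dose, double tau, int n_doses,
                             double start) {
  tks::Regimen reg;
  reg.dose = dose; reg.tau = tau; reg.n_doses = n_doses; reg.start = start;
  return reg;
}

// Noise-free concentration at arbitrary times (need not be sorted).
// [[Rcpp::export]]
NumericVector cpp_predict(int model, NumericVector params, NumericVector times,
                          double dose, double tau, int n_doses, double start,
                          double rtol, double atol, int mm_fixed = 0) {
  tks::Regimen reg = make_reg(dose, tau, n_doses, start);
  size_t n = times.size();
  std::vector<double> tt(times.begin(), times.end());
  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return tt[a] < tt[b]; });
  std::vector<double> ts(n);
  for (size_t i = 0; i < n; ++i) ts[i] = tt[ord[i]];
  std::vector<double> out;
  tks::predict_model(model, REAL(params), ts, reg, rtol, atol, out,
                     mm_fixed);
  NumericVector res(n);
  for (size_t i = 0; i < n; ++i) res[ord[i]] = out[i];
  return res;
}

// Cumulative AUC from time 0 for the closed-form (linear) models.
// [[Rcpp::export]]
NumericVector cpp_cum_auc(int model, NumericVector params, NumericVector times,
                          double dose, double tau, int n_doses, double start) {
  tks::Regimen reg = make_reg(dose, tau, n_doses, start);
  size_t n = times.size();
  NumericVector res(n);
  double* p = REAL(params);
  for (size_t i = 0; i < n; ++i) {
    if (model == 1)
      res[i] = tks::cauc_onecmt(times[i], reg, p[0], p[1], p[2]);
    else if (model == 3)
      res[i] = tks::cauc_twocmt(times[i], reg, p[0], p[1], p[2], p[3], p[4]);
    else
      stop("cpp_cum_auc: closed-form AUC only for models 1 and 3");
  }
  return res;
}

// Full Michaelis-Menten solution at sorted times: concentration, cumulative
// AUC, cumulative amount eliminated, plus the analytic depot amount (for
// mass-balance checks).
// [[Rcpp::export]]
List cpp_mm_profile(NumericVector params, NumericVector times,
                    double dose, double tau, int n_doses, double start,
                    double rtol, double atol) {
  tks::Regimen reg = make_reg(dose, tau, n_doses, start);
  std::vector<double> ts(times.begin(), times.end());
  std::vector<double> conc, cauc, elim;
  tks::mm_profile(ts, reg, params[0], params[1], params[2], params[3],
                  rtol, atol, conc, cauc, elim);
  size_t n = ts.size();
  NumericVector depot(n), dosed(n);
  for (size_t i = 0; i < n; ++i) {
    depot[i] = tks::mm_depot(ts[i], reg, params[0]);
    dosed[i] = dose * tks::doses_given(reg, ts[i]);
  }
  return List::create(_["conc"] = wrap(conc), _["cauc"] = wrap(cauc),
                      _["eliminated"] = wrap(elim), _["depot"] = depot,
                      _["dosed"] = dosed);
}
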