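#include <Rcpp.h>
using namespace Rcpp;

// Coupled logistic-migration derivative on the selected link subset.
// mode: 0 = conservative (per-source weight split, mass conserving),
//       1 = pool (global pool, weighted-inflow allocation, mass conserving),
//       2 = literal (printed closure k_i * X_tilde; not conserving).
// Emigration is scaled per node by escale = retained fraction of the node's
// full-network out-weight (conservative/pool modes; 0/1 out-link indicator
// in literal mode): removing a dispersal corridor removes the flow that
// used it, rather than re-routing it through the remaining links.
static void deriv(const std::vector<double>& X,
                  const IntegerVector& from, const IntegerVector& to,
                  const NumericVector& wn, const NumericVector& escale,
                  const NumericVector& w, const NumericVector& r,
                  double s, int mode, std::vector<double>& dX,
                  std::vector<double>& scratch, std::vector<double>& emig) {
  const int n = X.size();
  const int m = from.size();
  for (int i = 0; i < n; ++i) {
    double e = s * r[i] * X[i] * escale[i];
    emig[i] = e;
    dX[i] = r[i] * X[i] * (1.0 - X[i]) - e;
  }
  if (s <= 0.0 || m == 0) return;
  std::fill(scratch.begin(), scratch.end(), 0.0);
  if (mode == 0) {
    // wn[e] = w[e] / w_out[from[e]] precomputed by the caller
    for (int e = 0; e < m; ++e)
      scratch[to[e]] += emig[from[e]] * wn[e];
    for (int i = 0; i < n; ++i) dX[i] += scratch[i];
  } else if (mode == 1) {
    double E = 0.0;
    for (int j = 0; j < n; ++j) E += emig[j];
    for (int e = 0; e < m; ++e) scratch[to[e]] += w[e] * X[from[e]];
    double den = 0.0;
    for (int i = 0; i < n; ++i) den += scratch[i];
    if (den > 0.0)
      for (int i = 0; i < n; ++i) dX[i] += E * scratch[i] / den;
  } else {
    // wn[e] = w[e] / w_in[to[e]] precomputed by the caller
    double xt = 0.0;
    for (int j = 0; j < n; ++j) xt += r[j] * X[j];
    for (int e = 0; e < m; ++e) scratch[to[e]] += wn[e] * X[from[e]];
    for (int i = 0; i < n; ++i) dX[i] += scratch[i] * xt;
  }
}

// Normalized edge weights for the division-free derivative loops.
static NumericVector norm_weights(const IntegerVector& from,
                                  const IntegerVector& to,
                                  const NumericVector& w,
                                  const NumericVector& w_out,
                                  const NumericVector& w_in, int mode) {
  const int m = w.size();
  NumericVector wn(m);
  if (mode == 0) {
    for (int e = 0; e < m; ++e) wn[e] = w[e] / w_out[from[e]];
  } else if (mode == 2) {
    for (int e = 0; e < m; ++e)
      wn[e] = (w_in[to[e]] > 0.0) ? w[e] / w_in[to[e]] : 0.0;
  }
  return wn;
}

// One classical RK4 step of length h, then clip biomass at zero.
static bool rk4_step(std::vector<double>& X, double h,
                     const IntegerVector& from, const IntegerVector& to,
                     const NumericVector& wn, const NumericVector& escale,
                     const NumericVector& w, const NumericVector& r,
                     double s, int mode,
                     std::vector<double>& k1, std::vector<double>& k2,
                     std::vector<double>& k3, std::vector<double>& k4,
                     std::vector<double>& tmp, std::vector<double>& scratch,
                     std::vector<double>& emig) {
  const int n = X.size();
  deriv(X, from, to, wn, escale, w, r, s, mode, k1, scratch, emig);
  for (int i = 0; i < n; ++i) tmp[i] = X[i] + 0.5 * h * k1[i];
  deriv(tmp, from, to, wn, escale, w, r, s, mode, k2, scratch, emig);
  for (int i = 0; i < n; ++i) tmp[i] = X[i] + 0.5 * h * k2[i];
  deriv(tmp, from, to, wn, escale, w, r, s, mode, k3, scratch, emig);
  for (int i = 0; i < n; ++i) tmp[i] = X[i] + h * k3[i];
  deriv(tmp, from, to, wn, escale, w, r, s, mode, k4, scratch, emig);
  bool ok = true;
  for (int i = 0; i < n; ++i) {
    X[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (X[i] < 0.0) X[i] = 0.0;
    if (!std::isfinite(X[i])) ok = false;
  }
  return ok;
}

// Integrate over `horizon` unit-time intervals, recording the state at unit
// checkpoints. If stop_frac > 0, stop at the first checkpoint whose
// aggregate reaches stop_frac * init_agg (t_rec = that checkpoint; -1
// otherwise). status: 0 ok, 1 non-finite state encountered.
// [[Rcpp::export]]
List cpp_integrate(NumericVector X0, IntegerVector from, IntegerVector to,
                   NumericVector w, NumericVector w_out, NumericVector w_in,
                   NumericVector escale,
                   NumericVector r, double s, int mode, double dt,
                   int horizon, bool record, double stop_frac,
                   double init_agg) {
  const int n = X0.size();
  int spu = (int)std::lround(1.0 / dt);
  if (spu < 1) spu = 1;
  const double h = 1.0 / spu;
  std::vector<double> X(X0.begin(), X0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n), scratch(n), emig(n);
  NumericVector wn = norm_weights(from, to, w, w_out, w_in, mode);

  NumericMatrix Xrec;
  if (record) Xrec = NumericMatrix(horizon + 1, n);
  NumericVector agg(horizon + 1);
  double a0 = 0.0;
  for (int i = 0; i < n; ++i) a0 += X[i];
  agg[0] = a0;
  if (record) for (int i = 0; i < n; ++i) Xrec(0, i) = X[i];

  int t_rec = -1, status = 0, last = 0;
  const double target = (stop_frac > 0.0) ? stop_frac * init_agg : -1.0;
  if (target > 0.0 && a0 >= target) t_rec = 0;
  for (int t = 1; t <= horizon && t_rec < 0 && status == 0; ++t) {
    for (int k = 0; k < spu; ++k) {
      if (!rk4_step(X, h, from, to, wn, escale, w, r, s, mode,
                    k1, k2, k3, k4, tmp, scratch, emig)) { status = 1; break; }
    }
    if (status != 0) break;
    double a = 0.0;
    for (int i = 0; i < n; ++i) a += X[i];
    agg[t] = a;
    if (record) for (int i = 0; i < n; ++i) Xrec(t, i) = X[i];
    last = t;
    if (target > 0.0 && a >= target) t_rec = t;
  }
  if (t_rec < 0 && target < 0.0) {
    // full-horizon run
  }
  List out = List::create(
      _["agg"] = agg[Range(0, std::max(last, 0))],
      _["t_rec"] = t_rec, _["status"] = status,
      _["X_final"] = NumericVector(X.begin(), X.end()));
  if (record) {
    out["X"] = Xrec(Range(0, std::max(last, 0)), _);
  } else {
    out["X"] = R_NilValue;
  }
  return out;
}

// Relax toward the fixed point: integrate unit intervals until the residual
// max|dX/dt| drops below tol or t_max units elapse.
// [[Rcpp::export]]
List cpp_relax(NumericVector X0, IntegerVector from, IntegerVector to,
               NumericVector w, NumericVector w_out, NumericVector w_in,
               NumericVector escale, NumericVector r, double s, int mode,
               double dt, int t_max, double tol) {
  const int n = X0.size();
  int spu = (int)std::lround(1.0 / dt);
  if (spu < 1) spu = 1;
  const double h = 1.0 / spu;
  std::vector<double> X(X0.begin(), X0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n), scratch(n), emig(n);
  NumericVector wn = norm_weights(from, to, w, w_out, w_in, mode);
  double resid = R_PosInf;
  int t = 0, status = 0;
  for (; t < t_max; ++t) {
    deriv(X, from, to, wn, escale, w, r, s, mode, k1, scratch, emig);
    resid = 0.0;
    for (int i = 0; i < n; ++i) resid = std::max(resid, std::fabs(k1[i]));
    if (resid < tol) break;
    for (int k = 0; k < spu; ++k) {
      if (!rk4_step(X, h, from, to, wn, escale, w, r, s, mode,
                    k1, k2, k3, k4, tmp, scratch, emig)) { status = 1; break; }
    }
    if (status != 0) break;
  }
  if (status == 0) {
    deriv(X, from, to, wn, escale, w, r, s, mode, k1, scratch, emig);
    resid = 0.0;
    for (int i = 0; i < n; ++i) resid = std::max(resid, std::fabs(k1[i]));
  }
  return List::create(_["X"] = NumericVector(X.begin(), X.end()),
                      _["residual"] = resid, _["t"] = t,
                      _["status"] = status);
}
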