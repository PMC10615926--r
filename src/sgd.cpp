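#include <Rcpp.h>
using namespace Rcpp;

// Fused SGD-with-momentum parameter update, mutating w and v in place:
//   g <- g_raw + wd * w ; v <- mom * v - lr * g ; w <- w + v
// Element order matches the equivalent vectorised R expressions exactly,
// so results are bit-identical to the pure-R update.

// [[Rcpp::export(rng = false)]]
void sgd_step_inplace(NumericMatrix w, NumericMatrix v, NumericMatrix g_raw,
                      double lr, double mom, double wd) {
  R_xlen_t n = w.size();
  if (v.size() != n || g_raw.size() != n) {
    stop("parameter, velocity and gradient shapes differ");
  }
  double *pw = REAL(w), *pv = REAL(v), *pg = REAL(g_raw);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i] + wd * pw[i];
    pv[i] = mom * pv[i] - lr * gi;
    pw[i] += pv[i];
  }
}

// [[Rcpp::export(rng = false)]]
void sgd_step_inplace_vec(NumericVector w, NumericVector v, NumericVector g_raw,
                          double lr, double mom) {
  R_xlen_t n = w.size();
  if (v.size() != n || g_raw.size() != n) {
    stop("parameter, velocity and gradient shapes differ");
  }
  double *pw = REAL(w), *pv = REAL(v), *pg = REAL(g_raw);
  for (R_xlen_t i = 0; i < n; ++i) {
    pv[i] = mom * pv[i] - lr * pg[i];
    pw[i] += pv[i];
  }
}

// Bernoulli(keep)/keep dropout mask drawn from R's RNG stream in the same
// order as matrix(stats::rbinom(n * m, 1, keep) / keep, n) would draw it.

// [[Rcpp::export]]
NumericMatrix dropout_mask(int n, int m, double keep) {
  NumericMatrix out(n, m);
  double *p = REAL(out);
  R_xlen_t total = (R_xlen_t)n * m;
  for (R_xlen_t i = 0; i < total; ++i) {
    p[i] = R::rbinom(1.0, keep) / keep;
  }
  return out;
}
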