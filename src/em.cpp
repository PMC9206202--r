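#include <Rcpp.h>
using namespace Rcpp;

// Two-component mixture (any-number-of-repetitions) EM for motif discovery
// on small-alphabet sequences.
//
// windows: n x w integer matrix of letter codes in 1..A (no masked letters)
// logbg_win: length-n vector, log background probability of each window
// pwm0: w x A initial letter-probability matrix
//
// Each iteration: E-step computes the per-window motif posterior and the
// objective at the current parameters; the M-step re-estimates the PWM
// (with pseudocounts) and lambda. Iteration stops when the objective
// improves by less than tol (relative), or after max_iter E-steps.
//
// The recorded objective is the penalized log-likelihood
//   ll + pseudo * sum(log pwm)
// (the log-posterior under the Dirichlet(1 + pseudo) prior implied by the
// pseudocounted M-step, up to a constant); this is the quantity the EM
// update ascends, so the trace is non-decreasing.

// [[Rcpp::export]]
List em_tcm_cpp(const IntegerMatrix& windows, const NumericVector& logbg_win,
                NumericMatrix pwm0, double lambda0, int max_iter, double tol,
                double pseudo) {
  const int n = windows.nrow(), w = windows.ncol(), A = pwm0.ncol();
  NumericMatrix pwm = clone(pwm0);
  double lambda = lambda0;
  std::vector<double> z(n), logpm(n), trace;
  trace.reserve(max_iter);

  if (n == 0) stop("no windows");
  double prev_ll = R_NegInf;

  for (int iter = 0; iter < max_iter; ++iter) {
    // E-step at current parameters
    NumericMatrix logpwm(w, A);
    for (int k = 0; k < w; ++k)
      for (int a = 0; a < A; ++a)
        logpwm(k, a) = std::log(pwm(k, a));
    const double llam = std::log(lambda), l1m = std::log1p(-lambda);
    double ll = 0.0, prior = 0.0;
    for (int k = 0; k < w; ++k)
      for (int a = 0; a < A; ++a)
        prior += logpwm(k, a);
    for (int i = 0; i < n; ++i) {
      double lp = 0.0;
      for (int k = 0; k < w; ++k) lp += logpwm(k, windows(i, k) - 1);
      logpm[i] = lp;
      double a = llam + lp, b = l1m + logbg_win[i];
      double m = a > b ? a : b;
      double s = m + std::log(std::exp(a - m) + std::exp(b - m));
      ll += s;
      z[i] = std::exp(a - s);
    }
    trace.push_back(ll + pseudo * prior);
    // relative convergence: improvements scale with |ll|
    if (R_FINITE(tol) == false ||
        (iter > 0 && std::fabs(ll - prev_ll) < tol * (1.0 + std::fabs(ll))))
      break;
    prev_ll = ll;
    if (iter == max_iter - 1) break; // keep params that produced last ll

    // M-step
    double zsum = 0.0;
    for (int i = 0; i < n; ++i) zsum += z[i];
    for (int k = 0; k < w; ++k) {
      std::vector<double> cnt(A, pseudo);
      for (int i = 0; i < n; ++i) cnt[windows(i, k) - 1] += z[i];
      double tot = zsum + A * pseudo;
      for (int a = 0; a < A; ++a) pwm(k, a) = cnt[a] / tot;
    }
    lambda = zsum / n;
    if (lambda < 1e-8) lambda = 1e-8;
    if (lambda > 1.0 - 1e-8) lambda = 1.0 - 1e-8;
  }

  return List::create(_["pwm"] = pwm, _["lambda"] = lambda,
                      _["z"] = NumericVector(z.begin(), z.end()),
                      _["logpm"] = NumericVector(logpm.begin(), logpm.end()),
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// One-iteration warm-start scores for a set of seed words.
// seeds: m x w matrix of letter codes; returns the observed-data log
// likelihood after a single EM update from each seed's pseudocounted PWM.

// [[Rcpp::export]]
NumericVector warm_start_scores_cpp(const IntegerMatrix& windows,
                                    const NumericVector& logbg_win,
                                    const IntegerMatrix& seeds,
                                    double lambda0, double pseudo,
                                    double seed_weight, int A) {
  const int n = windows.nrow(), w = windows.ncol(), m = seeds.nrow();
  NumericVector out(m);
  std::vector<double> z(n);
  const double lo = std::log(pseudo / (seed_weight + A * pseudo));
  const double hi = std::log((seed_weight + pseudo) / (seed_weight + A * pseudo));
  const double llam = std::log(lambda0), l1m = std::log1p(-lambda0);

  for (int s = 0; s < m; ++s) {
    // E-step under the seed PWM: log P(window | motif) depends only on the
    // number of positions agreeing with the seed word
    double zsum = 0.0;
    for (int i = 0; i < n; ++i) {
      int match = 0;
      for (int k = 0; k < w; ++k)
        if (windows(i, k) == seeds(s, k)) ++match;
      double lp = match * hi + (w - match) * lo;
      double a = llam + lp, b = l1m + logbg_win[i];
      double mx = a > b ? a : b;
      double sum = mx + std::log(std::exp(a - mx) + std::exp(b - mx));
      z[i] = std::exp(a - sum);
      zsum += z[i];
    }
    // M-step
    std::vector<double> pwm(w * A);
    for (int k = 0; k < w; ++k) {
      std::vector<double> cnt(A, pseudo);
      for (int i = 0; i < n; ++i) cnt[windows(i, k) - 1] += z[i];
      double tot = zsum + A * pseudo;
      for (int a = 0; a < A; ++a) pwm[k * A + a] = std::log(cnt[a] / tot);
    }
    double lambda = zsum / n;
    if (lambda < 1e-8) lambda = 1e-8;
    if (lambda > 1.0 - 1e-8) lambda = 1.0 - 1e-8;
    // penalized likelihood at the updated parameters (same objective as
    // the full EM records in its trace)
    const double llam1 = std::log(lambda), l1m1 = std::log1p(-lambda);
    double ll = 0.0, prior = 0.0;
    for (size_t t = 0; t < pwm.size(); ++t) prior += pwm[t];
    for (int i = 0; i < n; ++i) {
      double lp = 0.0;
      for (int k = 0; k < w; ++k) lp += pwm[k * A + windows(i, k) - 1];
      double a = llam1 + lp, b = l1m1 + logbg_win[i];
      double mx = a > b ? a : b;
      ll += mx + std::log(std::exp(a - mx) + std::exp(b - mx));
    }
    out[s] = ll + pseudo * prior;
  }
  return out;
}
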