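#include <Rcpp.h>
using namespace Rcpp;

// Forward-backward for an HMM whose transition matrix is
// self_p on the diagonal and (1 - self_p)/(K-1) elsewhere.
// The rank-1 structure lets each step run in O(K).
// logemit: T x K matrix of log emission densities.
// Returns gamma (T x K posterior), loglik.
// [[Rcpp::export(name = ".fb_rank1")]]
List fb_rank1(NumericMatrix logemit, double self_p) {
  const int T = logemit.nrow(), K = logemit.ncol();
  const double off = (1.0 - self_p) / (K - 1);
  const double a = self_p - off;  // A = a*I + off*J
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector cvec(T);
  // stabilize emissions per row
  NumericMatrix emit(T, K);
  for (int t = 0; t < T; ++t) {
    double m = logemit(t, 0);
    for (int k = 1; k < K; ++k) if (logemit(t, k) > m) m = logemit(t, k);
    for (int k = 0; k < K; ++k) emit(t, k) = std::exp(logemit(t, k) - m);
    cvec[t] = m;  // reuse: carries the row max; scaling factors added below
  }
  double loglik = 0.0;
  // forward with per-step normalization
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = emit(0, k) / K; s += alpha(0, k); }
  loglik += std::log(s) + cvec[0];
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    double S = 1.0;  // alpha rows are normalized to sum 1
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double v = emit(t, k) * (a * alpha(t - 1, k) + off * S);
      alpha(t, k) = v; s += v;
    }
    loglik += std::log(s) + cvec[t];
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  // backward, normalized each step for stability
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    double S = 0.0, mx = 0.0;
    NumericVector eb(K);
    for (int k = 0; k < K; ++k) {
      eb[k] = emit(t + 1, k) * beta(t + 1, k);
      S += eb[k];
    }
    for (int k = 0; k < K; ++k) {
      double v = a * eb[k] + off * S;
      beta(t, k) = v;
      if (v > mx) mx = v;
    }
    if (mx > 0) for (int k = 0; k < K; ++k) beta(t, k) /= mx;
  }
  for (int t = 0; t < T; ++t) {
    double s2 = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s2 += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s2;
  }
  return List::create(_["gamma"] = gamma, _["loglik"] = loglik);
}

// Viterbi path for the same rank-1 transition structure. Uniform initial
// distribution. Returns 1-based state indices.
// [[Rcpp::export(name = ".viterbi_rank1")]]
IntegerVector viterbi_rank1(NumericMatrix logemit, double self_p) {
  const int T = logemit.nrow(), K = logemit.ncol();
  if (K < 2) return IntegerVector(T, 1);
  const double loff = std::log((1.0 - self_p) / (K - 1));
  const double lself = std::log(self_p);
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = -std::log((double)K) + logemit(0, k);
  for (int t = 1; t < T; ++t) {
    // best and runner-up of previous row
    int i1 = 0; double b1 = delta(t - 1, 0), b2 = -INFINITY; int i2 = -1;
    for (int k = 1; k < K; ++k) {
      double v = delta(t - 1, k);
      if (v > b1) { b2 = b1; i2 = i1; b1 = v; i1 = k; }
      else if (v > b2) { b2 = v; i2 = k; }
    }
    for (int k = 0; k < K; ++k) {
      double stay = delta(t - 1, k) + lself;
      double jumpv; int jumpi;
      if (k == i1) { jumpv = b2 + loff; jumpi = i2; }
      else { jumpv = b1 + loff; jumpi = i1; }
      if (stay >= jumpv) { delta(t, k) = stay + logemit(t, k); psi(t, k) = k; }
      else { delta(t, k) = jumpv + logemit(t, k); psi(t, k) = jumpi; }
    }
  }
  IntegerVector path(T);
  int best = 0; double bv = delta(T - 1, 0);
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > bv) { bv = delta(T - 1, k); best = k; }
  path[T - 1] = best;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}

// Maximal absolute two-sample t statistic over circular arcs (i, j]:
// the arc x[i+1..j] against the remainder. Returns t, i, j (0-based
// boundaries, 0 <= i < j <= n, excluding the full-vector arc).
// Degenerate zero-variance splits with distinct means get a large finite t.
// [[Rcpp::export(name = ".cbs_max_t")]]
List cbs_max_t(NumericVector x) {
  const int n = x.size();
  NumericVector cs(n + 1), cs2(n + 1);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  const double tot = cs[n], tot2 = cs2[n];
  double best = -1.0; int bi = 0, bj = 1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      int n1 = j - i;
      int n2 = n - n1;
      if (n2 == 0) continue;  // full vector: no split
      double s1 = cs[j] - cs[i];
      double m1 = s1 / n1;
      double m2 = (tot - s1) / n2;
      double ssw = tot2 - n1 * m1 * m1 - n2 * m2 * m2;
      double tval;
      if (n <= 2 || ssw <= 1e-12 * (std::fabs(tot2) + 1.0)) {
        tval = (std::fabs(m1 - m2) > 1e-12) ? 1e12 * std::fabs(m1 - m2) : 0.0;
      } else {
        double s2 = ssw / (n - 2);
        tval = std::fabs(m1 - m2) / std::sqrt(s2 * (1.0 / n1 + 1.0 / n2));
      }
      if (tval > best) { best = tval; bi = i; bj = j; }
    }
  }
  return List::create(_["t"] = best, _["i"] = bi, _["j"] = bj);
}

// Permutation exceedance count for the max-t statistic with early stopping:
// shuffles are provided as an n x n_perm matrix of 0-based index columns.
// Stops once `stop_at` exceedances are seen; returns exceedances and the
// number of permutations evaluated.
// [[Rcpp::export(name = ".cbs_perm_count")]]
List cbs_perm_count(NumericVector x, IntegerMatrix idx, double t_obs,
                    int stop_at) {
  const int n = x.size(), P = idx.ncol();
  NumericVector xp(n);
  int exceed = 0, used = 0;
  for (int p = 0; p < P; ++p) {
    for (int i = 0; i < n; ++i) xp[i] = x[idx(i, p)];
    List r = cbs_max_t(xp);
    if (as<double>(r["t"]) >= t_obs) ++exceed;
    ++used;
    if (exceed >= stop_at) break;
  }
  return List::create(_["exceed"] = exceed, _["used"] = used);
}
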