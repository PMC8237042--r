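#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// lambda_max of the 0/1 adjacency matrix spanned by the edges listed in
// kept[0..K), to absolute accuracy tol.
//
// Algorithm: Lanczos iteration with full reorthogonalization, warm-started
// from the caller-supplied vector v. The start is mixed with a strictly
// positive uniform component so it always overlaps the Perron eigenspace of
// every connected component. The largest eigenvalue of the Lanczos
// tridiagonal is found by Sturm-count bisection, its eigenvector by inverse
// iteration, and convergence is declared on the Lanczos residual bound
// |beta_m * s_m| <= 0.5 * tol followed by an explicit check of the true
// residual ||A y - theta y||_2 <= tol of the assembled Ritz vector, which
// for a symmetric matrix bounds the distance from theta to an eigenvalue.
// If the Krylov basis fills up without convergence the iteration restarts
// from the current best Ritz vector. No RNG is consumed.
// ---------------------------------------------------------------------------

static inline void matvec(const int* eu, const int* ev, const int* kept,
                          int K, const double* x, double* y, int n) {
  std::fill(y, y + n, 0.0);
  for (int t = 0; t < K; ++t) {
    const int e = kept[t];
    y[eu[e]] += x[ev[e]];
    y[ev[e]] += x[eu[e]];
  }
}

// number of eigenvalues of the tridiagonal (alpha, beta) strictly below s
static int sturm_count(const std::vector<double>& alpha,
                       const std::vector<double>& beta, int m, double s) {
  int cnt = 0;
  double d = 1.0;
  for (int i = 0; i < m; ++i) {
    const double b2 = i > 0 ? beta[i - 1] * beta[i - 1] : 0.0;
    d = alpha[i] - s - (d != 0.0 ? b2 / d : b2 / 1e-300);
    if (d < 0.0) ++cnt;
  }
  return cnt;
}

static double tridiag_lambda_max(const std::vector<double>& alpha,
                                 const std::vector<double>& beta, int m) {
  double lo = alpha[0], hi = alpha[0];
  for (int i = 0; i < m; ++i) {
    const double bl = i > 0 ? std::fabs(beta[i - 1]) : 0.0;
    const double br = i < m - 1 ? std::fabs(beta[i]) : 0.0;
    lo = std::min(lo, alpha[i] - bl - br);
    hi = std::max(hi, alpha[i] + bl + br);
  }
  for (int it = 0; it < 200 && hi - lo > 1e-13 * std::max(1.0, std::fabs(hi));
       ++it) {
    const double mid = 0.5 * (lo + hi);
    if (sturm_count(alpha, beta, m, mid) < m) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// eigenvector of the tridiagonal for eigenvalue theta, by inverse
// iteration with a Thomas-style LU solve (partial safeguarding via a
// floor on pivots); s is overwritten (length m, normalized).
static void tridiag_eigvec(const std::vector<double>& alpha,
                           const std::vector<double>& beta, int m,
                           double theta, std::vector<double>& s) {
  s.assign(m, 1.0 / std::sqrt((double)m));
  std::vector<double> c(m), d(m), x(m);
  const double shift = theta * (1.0 + 1e-12) + 1e-12;
  for (int sweep = 0; sweep < 3; ++sweep) {
    // solve (T - shift I) x = s by forward elimination / back substitution
    d[0] = alpha[0] - shift;
    if (std::fabs(d[0]) < 1e-12) d[0] = d[0] < 0 ? -1e-12 : 1e-12;
    x[0] = s[0];
    for (int i = 1; i < m; ++i) {
      const double l = beta[i - 1] / d[i - 1];
      d[i] = alpha[i] - shift - l * beta[i - 1];
      if (std::fabs(d[i]) < 1e-12) d[i] = d[i] < 0 ? -1e-12 : 1e-12;
      x[i] = s[i] - l * x[i - 1];
    }
    x[m - 1] /= d[m - 1];
    for (int i = m - 2; i >= 0; --i)
      x[i] = (x[i] - beta[i] * x[i + 1]) / d[i];
    double nrm = 0.0;
    for (int i = 0; i < m; ++i) nrm += x[i] * x[i];
    nrm = std::sqrt(nrm);
    for (int i = 0; i < m; ++i) s[i] = x[i] / nrm;
  }
}

static double lanczos_lambda(const int* eu, const int* ev, const int* kept,
                             int K, int n, std::vector<double>& v,
                             double tol, int maxit) {
  if (K == 0) {
    std::fill(v.begin(), v.end(), 1.0 / std::sqrt((double)n));
    return 0.0;
  }
  // strictly positive warm start
  double nv = 0.0;
  for (int i = 0; i < n; ++i) {
    if (v[i] < 0.0 || !std::isfinite(v[i])) v[i] = 0.0;
    nv += v[i] * v[i];
  }
  nv = std::sqrt(nv);
  const double unif = 1.0 / std::sqrt((double)n);
  double nw = 0.0;
  for (int i = 0; i < n; ++i) {
    v[i] = (nv > 0.0 ? 0.9 * v[i] / nv : 0.0) + 0.1 * unif;
    nw += v[i] * v[i];
  }
  nw = std::sqrt(nw);
  for (int i = 0; i < n; ++i) v[i] /= nw;

  const int mmax = std::min(n, 80);
  std::vector<double> Q((size_t)(mmax + 1) * n), alpha(mmax), beta(mmax);
  std::vector<double> w(n), s, y(n);
  double theta = 0.0;
  int used = 0;

  while (used < maxit) {
    std::copy(v.begin(), v.end(), Q.begin());
    int m = 0;
    bool breakdown = false;
    for (int j = 0; j < mmax && used < maxit; ++j, ++used) {
      const double* qj = &Q[(size_t)j * n];
      matvec(eu, ev, kept, K, qj, w.data(), n);
      double a = 0.0;
      for (int i = 0; i < n; ++i) a += qj[i] * w[i];
      alpha[j] = a;
      for (int i = 0; i < n; ++i) w[i] -= a * qj[i];
      if (j > 0) {
        const double* qm = &Q[(size_t)(j - 1) * n];
        const double b = beta[j - 1];
        for (int i = 0; i < n; ++i) w[i] -= b * qm[i];
      }
      // full reorthogonalization
      for (int k = 0; k <= j; ++k) {
        const double* qk = &Q[(size_t)k * n];
        double dot = 0.0;
        for (int i = 0; i < n; ++i) dot += qk[i] * w[i];
        for (int i = 0; i < n; ++i) w[i] -= dot * qk[i];
      }
      double b = 0.0;
      for (int i = 0; i < n; ++i) b += w[i] * w[i];
      b = std::sqrt(b);
      beta[j] = b;
      m = j + 1;
      theta = tridiag_lambda_max(alpha, beta, m);
      if (b < 1e-12) { breakdown = true; break; } // invariant subspace: exact
      tridiag_eigvec(alpha, beta, m, theta, s);
      if (std::fabs(b * s[m - 1]) <= 0.5 * tol) {
        // assemble the Ritz vector and verify the true residual
        std::fill(y.begin(), y.end(), 0.0);
        for (int k = 0; k < m; ++k) {
          const double* qk = &Q[(size_t)k * n];
          const double sk = s[k];
          for (int i = 0; i < n; ++i) y[i] += sk * qk[i];
        }
        matvec(eu, ev, kept, K, y.data(), w.data(), n);
        double res = 0.0, yn = 0.0;
        for (int i = 0; i < n; ++i) {
          const double d = w[i] - theta * y[i];
          res += d * d;
          yn += y[i] * y[i];
        }
        if (std::sqrt(res) <= tol * std::sqrt(yn)) {
          const double inv = 1.0 / std::sqrt(yn);
          for (int i = 0; i < n; ++i) v[i] = y[i] * inv;
          return theta;
        }
      }
      double* qn = &Q[(size_t)(j + 1) * n];
      for (int i = 0; i < n; ++i) qn[i] = w[i] / b;
    }
    // restart from the current best Ritz vector
    tridiag_eigvec(alpha, beta, m, theta, s);
    std::fill(y.begin(), y.end(), 0.0);
    for (int k = 0; k < m; ++k) {
      const double* qk = &Q[(size_t)k * n];
      const double sk = s[k];
      for (int i = 0; i < n; ++i) y[i] += sk * qk[i];
    }
    double yn = 0.0;
    for (int i = 0; i < n; ++i) yn += y[i] * y[i];
    yn = std::sqrt(yn);
    if (yn < 1e-300) break;
    for (int i = 0; i < n; ++i) v[i] = y[i] / yn;
    if (breakdown) return theta;
  }
  return theta; // iteration budget exhausted; best available Ritz value
}

// [[Rcpp::export]]
List lanczos_lambda_cpp(int n, IntegerVector eu, IntegerVector ev,
                        double tol, int maxit) {
  const int K = eu.size();
  std::vector<int> kept(K);
  for (int i = 0; i < K; ++i) kept[i] = i;
  std::vector<double> v(n, 0.0);
  double lam = lanczos_lambda(
      K ? &eu[0] : (int*)nullptr, K ? &ev[0] : (int*)nullptr,
      K ? kept.data() : (int*)nullptr, K, n, v, tol, maxit);
  return List::create(_["lambda"] = lam,
                      _["vector"] = NumericVector(v.begin(), v.end()));
}

static inline int draw_index(int m) {
  // uniform on 0..m-1 via R's RNG
  int k = (int)(unif_rand() * m);
  if (k >= m) k = m - 1;
  return k;
}

// Metropolis edge-swap sampler over fixed-size subgraphs of the edge set
// (eu, ev); energy = lambda_max of the kept subgraph, acceptance
// min(1, exp(nu * (e_cur - e_prop))). kept_init holds 0-based indices into
// (eu, ev). Uses R's RNG: three draws per step (kept pick, removed pick,
// acceptance uniform). energies[t] is the energy AFTER step t.
// [[Rcpp::export]]
List mcmc_engine(int n, IntegerVector eu, IntegerVector ev,
                 IntegerVector kept_init, double nu, int steps, double tol,
                 int maxit, bool record_removed) {
  const int E = eu.size();
  const int K = kept_init.size();
  const int R = E - K;
  if (K <= 0 || R <= 0)
    stop("degenerate removal: both kept and removed edge sets must be non-empty");

  std::vector<char> is_kept(E, 0);
  std::vector<int> kept(K), removed;
  removed.reserve(R);
  for (int i = 0; i < K; ++i) {
    kept[i] = kept_init[i];
    is_kept[kept_init[i]] = 1;
  }
  for (int e = 0; e < E; ++e)
    if (!is_kept[e]) removed.push_back(e);

  std::vector<double> v_cur(n, 0.0), v_prop(n);
  double e_cur = lanczos_lambda(&eu[0], &ev[0], kept.data(), K, n, v_cur,
                                tol, maxit);
  const double e_init = e_cur;

  NumericVector energies(steps);
  LogicalVector accepted(steps);
  IntegerMatrix rem_hist = record_removed ? IntegerMatrix(steps, R)
                                          : IntegerMatrix(0, 0);

  for (int t = 0; t < steps; ++t) {
    const int a = draw_index(K);
    const int b = draw_index(R);
    std::swap(kept[a], removed[b]);
    v_prop = v_cur;
    const double e_prop = lanczos_lambda(&eu[0], &ev[0], kept.data(), K, n,
                                         v_prop, tol, maxit);
    const double u = unif_rand();
    bool acc;
    if (e_prop <= e_cur) {
      acc = true;
    } else {
      acc = u < std::exp(nu * (e_cur - e_prop));
    }
    if (acc) {
      e_cur = e_prop;
      v_cur.swap(v_prop);
    } else {
      std::swap(kept[a], removed[b]);
    }
    energies[t] = e_cur;
    accepted[t] = acc;
    if (record_removed)
      for (int j = 0; j < R; ++j) rem_hist(t, j) = removed[j];
  }

  return List::create(_["energies"] = energies, _["accepted"] = accepted,
                      _["kept_final"] = IntegerVector(kept.begin(), kept.end()),
                      _["initial_energy"] = e_init, _["final_energy"] = e_cur,
                      _["removed_history"] = rem_hist);
}
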