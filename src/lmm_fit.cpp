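// Profiled Gaussian (RE)ML machinery for the longitudinal analysis model:
//   Y_it = X_it'beta + b0_i + b1_i * t + e_it,
// with independent random intercept/slope and AR(1) residual correlation
// rho^|t1-t2| across (possibly non-contiguous) observed weeks.
//
// The marginal covariance for participant i is
//   V_i = sigma^2 * W_i,   W_i = tau0^2 11' + tau1^2 tt' + C_i(rho),
// where tau0 = sigma_b0/sigma, tau1 = sigma_b1/sigma.  The residual scale
// sigma^2 and the fixed effects are profiled out, leaving a 3-parameter
// optimization over (log tau0, log tau1, atanh rho).
//
// Participants are grouped by observed-week pattern: the Cholesky of W and
// the whitened base design are computed once per pattern and the pids
// sharing it are whitened as one matrix solve.  The per-pid design is
// X_i = G_p * diag(d_i): the base design G depends only on the week
// pattern, d_i carries age and arm, so X'W^-1X accumulates as
// (sum_i d_i d_i') (Hadamard) G'W^-1G with the first factor precomputed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Pattern {
  vec weeks;      // observed weeks
  umat lag;       // integer |t_j - t_k|
  mat tt;         // weeks * weeks'
  mat G6;         // smooth base columns (age/runin/post/t/t2/t3), n_p x 6
  uvec erow;      // rows with week >= 1 (these have a week-dummy column)
  uvec ecol;      // the dummy's column index in the full design
  mat Ymat;       // outcomes of member pids, one column each (n_p x k)
  mat Dt;         // member d-vectors, one column each (p x k)
  mat Dsum;       // sum_i d_i d_i' (p x p)
  uword k;        // member count
};

struct LmmData {
  std::vector<Pattern> pats;
  uword p, N;
  uword maxlag;
};

// Profiled -2 log (restricted) likelihood; returns a large value when the
// covariance is numerically indefinite.  Optionally fills estimation detail.
double neg2ll(const LmmData& D, double tau0, double tau1, double rho,
              bool reml, bool detail,
              vec* beta_out, mat* XtWiX_out, double* sigma2_out) {
  const double BIG = 1e10;
  const uword p = D.p;
  const double t02 = tau0 * tau0, t12 = tau1 * tau1;

  vec rpow(D.maxlag + 1);
  rpow[0] = 1.0;
  for (uword l = 1; l <= D.maxlag; ++l) rpow[l] = rpow[l - 1] * rho;

  mat A(p, p, fill::zeros);
  vec b(p, fill::zeros);
  double q_yy = 0.0, logdetW = 0.0;

  for (const Pattern& P : D.pats) {
    const uword n = P.weeks.n_elem;
    const uword ne = P.erow.n_elem;
    mat W(n, n);
    for (uword j = 0; j < n; ++j)
      for (uword q = 0; q <= j; ++q) {
        double v = t02 + t12 * P.tt(j, q) + rpow[P.lag(j, q)];
        W(j, q) = v;
        W(q, j) = v;
      }
    mat L;
    if (!chol(L, W, "lower")) return BIG;
    logdetW += 2.0 * static_cast<double>(P.k) * accu(log(L.diag()));
    mat Li = inv(trimatl(L));
    mat Winv = Li.t() * Li;

    // full-design Gram M = G' W^-1 G assembled from the smooth block and
    // the week-dummy rows (unit rows of G), which read W^-1 directly
    mat T6 = Winv * P.G6;                       // n x 6
    mat M(p, p, fill::zeros);
    M.submat(0, 0, 5, 5) = P.G6.t() * T6;
    for (uword a = 0; a < ne; ++a) {
      const uword r = P.erow[a], c = P.ecol[a];
      for (uword s = 0; s < 6; ++s) {
        M(s, c) = T6(r, s);
        M(c, s) = T6(r, s);
      }
      for (uword b2 = 0; b2 < ne; ++b2)
        M(c, P.ecol[b2]) = Winv(r, P.erow[b2]);
    }

    mat WY = Winv * P.Ymat;                     // n x k
    q_yy += accu(P.Ymat % WY);
    mat Gm(p, P.k, fill::zeros);
    Gm.rows(0, 5) = P.G6.t() * WY;
    for (uword a = 0; a < ne; ++a) Gm.row(P.ecol[a]) = WY.row(P.erow[a]);
    b += sum(P.Dt % Gm, 1);
    A += P.Dsum % M;
  }

  vec beta;
  if (!solve(beta, A, b, solve_opts::no_approx)) return BIG;
  double Q = q_yy - dot(b, beta);
  if (!(Q > 0) || !std::isfinite(Q)) return BIG;

  const double N = static_cast<double>(D.N);
  const double TWOPI = 2.0 * M_PI;
  double val;
  if (reml) {
    double ldA, signA;
    if (!log_det(ldA, signA, A) || signA <= 0) return BIG;
    double df = N - static_cast<double>(p);
    double s2 = Q / df;
    val = df * (std::log(TWOPI) + std::log(s2)) + logdetW + ldA + df;
    if (detail) *sigma2_out = s2;
  } else {
    double s2 = Q / N;
    val = N * (std::log(TWOPI) + std::log(s2)) + logdetW + N;
    if (detail) *sigma2_out = s2;
  }
  if (detail) {
    *beta_out = beta;
    *XtWiX_out = A;
  }
  return val;
}

LmmData unpack(const Rcpp::List& pat_weeks, const Rcpp::List& pat_G,
               const Rcpp::IntegerVector& pid_pat, const Rcpp::List& pid_y,
               const arma::mat& pid_d) {
  LmmData D;
  const uword npat = pat_weeks.size();
  const uword npid = pid_y.size();
  D.pats.resize(npat);
  D.p = pid_d.n_cols;
  D.N = 0;
  D.maxlag = 0;

  std::vector<std::vector<uword>> members(npat);
  for (uword i = 0; i < npid; ++i)
    members[static_cast<uword>(pid_pat[i])].push_back(i);

  for (uword q = 0; q < npat; ++q) {
    Pattern& P = D.pats[q];
    P.weeks = Rcpp::as<vec>(pat_weeks[q]);
    mat G = Rcpp::as<mat>(pat_G[q]);
    P.G6 = G.cols(0, 5);
    const uword n = P.weeks.n_elem;
    std::vector<uword> er, ec;
    for (uword j = 0; j < n; ++j) {
      long w = std::lround(P.weeks[j]);
      if (w >= 1) {
        if (5 + static_cast<uword>(w) >= pid_d.n_cols)
          Rcpp::stop("week outside the supported 0-24 range");
        er.push_back(j);
        ec.push_back(5 + static_cast<uword>(w));  // design column of dummy
      }
    }
    P.erow = uvec(er);
    P.ecol = uvec(ec);
    P.lag.set_size(n, n);
    P.tt.set_size(n, n);
    for (uword j = 0; j < n; ++j)
      for (uword k2 = 0; k2 < n; ++k2) {
        P.lag(j, k2) = static_cast<uword>(
            std::lround(std::abs(P.weeks[j] - P.weeks[k2])));
        P.tt(j, k2) = P.weeks[j] * P.weeks[k2];
        if (P.lag(j, k2) > D.maxlag) D.maxlag = P.lag(j, k2);
      }
    P.k = members[q].size();
    P.Ymat.set_size(n, P.k);
    P.Dt.set_size(D.p, P.k);
    for (uword m = 0; m < P.k; ++m) {
      P.Ymat.col(m) = Rcpp::as<vec>(pid_y[members[q][m]]);
      P.Dt.col(m) = pid_d.row(members[q][m]).t();
    }
    P.Dsum = P.Dt * P.Dt.t();
    D.N += n * P.k;
  }
  return D;
}

inline double par_tau(double x) { return std::exp(x); }
inline double par_rho(double x) { return std::tanh(x); }

double objective(const LmmData& D, const vec& par, bool reml) {
  return neg2ll(D, par_tau(par[0]), par_tau(par[1]), par_rho(par[2]),
                reml, false, nullptr, nullptr, nullptr);
}

// Plain Nelder-Mead on the 3 transformed variance parameters.
vec nelder_mead(const LmmData& D, const vec& start, bool reml,
                double reltol, int maxit, double step,
                int* neval, double* fmin) {
  const uword n = 3;
  std::vector<vec> x(n + 1);
  vec f(n + 1);
  x[0] = start;
  f[0] = objective(D, x[0], reml);
  for (uword i = 0; i < n; ++i) {
    vec xi = start;
    xi[i] += (std::abs(start[i]) > step / 0.4) ? step * std::abs(start[i]) : step;
    x[i + 1] = xi;
    f[i + 1] = objective(D, xi, reml);
  }
  int evals = n + 1;
  const double alpha = 1.0, gamma = 2.0, beta_c = 0.5, delta = 0.5;

  for (int it = 0; it < maxit; ++it) {
    uvec ord = sort_index(f);
    std::vector<vec> xs(n + 1);
    vec fs(n + 1);
    for (uword i = 0; i <= n; ++i) { xs[i] = x[ord[i]]; fs[i] = f[ord[i]]; }
    x = xs; f = fs;

    if (std::abs(f[n] - f[0]) <=
        reltol * (std::abs(f[0]) + std::abs(f[n]) + 1e-10)) break;

    vec cen(n, fill::zeros);
    for (uword i = 0; i < n; ++i) cen += x[i];
    cen /= static_cast<double>(n);

    vec xr = cen + alpha * (cen - x[n]);
    double fr = objective(D, xr, reml); ++evals;
    if (fr < f[0]) {
      vec xe = cen + gamma * (xr - cen);
      double fe = objective(D, xe, reml); ++evals;
      if (fe < fr) { x[n] = xe; f[n] = fe; } else { x[n] = xr; f[n] = fr; }
    } else if (fr < f[n - 1]) {
      x[n] = xr; f[n] = fr;
    } else {
      vec xc = cen + beta_c * (x[n] - cen);
      double fc = objective(D, xc, reml); ++evals;
      if (fc < f[n]) {
        x[n] = xc; f[n] = fc;
      } else {
        for (uword i = 1; i <= n; ++i) {
          x[i] = x[0] + delta * (x[i] - x[0]);
          f[i] = objective(D, x[i], reml); ++evals;
        }
      }
    }
  }
  uvec ord = sort_index(f);
  *neval = evals;
  *fmin = f[ord[0]];
  return x[ord[0]];
}

}  // namespace

// [[Rcpp::export]]
double lmm_neg2ll_cpp(double tau0, double tau1, double rho,
                      const Rcpp::List& pat_weeks, const Rcpp::List& pat_G,
                      const Rcpp::IntegerVector& pid_pat,
                      const Rcpp::List& pid_y, const arma::mat& pid_d,
                      bool reml) {
  LmmData D = unpack(pat_weeks, pat_G, pid_pat, pid_y, pid_d);
  return neg2ll(D, tau0, tau1, rho, reml, false, nullptr, nullptr, nullptr);
}

// [[Rcpp::export]]
Rcpp::List lmm_detail_cpp(double tau0, double tau1, double rho,
                          const Rcpp::List& pat_weeks, const Rcpp::List& pat_G,
                          const Rcpp::IntegerVector& pid_pat,
                          const Rcpp::List& pid_y, const arma::mat& pid_d,
                          bool reml) {
  LmmData D = unpack(pat_weeks, pat_G, pid_pat, pid_y, pid_d);
  vec beta;
  mat A;
  double s2 = NA_REAL;
  double val = neg2ll(D, tau0, tau1, rho, reml, true, &beta, &A, &s2);
  return Rcpp::List::create(
      Rcpp::Named("neg2ll") = val, Rcpp::Named("beta") = beta,
      Rcpp::Named("XtWiX") = A, Rcpp::Named("sigma2") = s2,
      Rcpp::Named("N") = static_cast<double>(D.N));
}

// [[Rcpp::export]]
Rcpp::List lmm_optim_cpp(const arma::vec& start,
                         const Rcpp::List& pat_weeks, const Rcpp::List& pat_G,
                         const Rcpp::IntegerVector& pid_pat,
                         const Rcpp::List& pid_y, const arma::mat& pid_d,
                         bool reml, double reltol, int maxit,
                         double step) {
  LmmData D = unpack(pat_weeks, pat_G, pid_pat, pid_y, pid_d);
  int neval = 0;
  double fmin = NA_REAL;
  vec best = nelder_mead(D, start, reml, reltol, maxit, step, &neval, &fmin);
  double s2 = NA_REAL;
  vec beta;
  mat A;
  double val = neg2ll(D, par_tau(best[0]), par_tau(best[1]), par_rho(best[2]),
                      reml, true, &beta, &A, &s2);
  return Rcpp::List::create(
      Rcpp::Named("par") = best, Rcpp::Named("neg2ll") = val,
      Rcpp::Named("evals") = neval, Rcpp::Named("beta") = beta,
      Rcpp::Named("XtWiX") = A, Rcpp::Named("sigma2") = s2,
      Rcpp::Named("N") = static_cast<double>(D.N));
}
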