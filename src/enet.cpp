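#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Elastic-net coordinate descent over a penalty path, gaussian squared-error
// loss with intercept:
//   min_b (1/2n) sum_i (y_i - b0 - x_i' b)^2 + lambda * (a*|b|_1 + (1-a)/2*|b|_2^2)
// Conventions follow the canonical glmnet implementation so the two solvers
// are interchangeable on a shared path: predictor columns are centred and
// (optionally) scaled to unit 1/n-variance, the response is centred and
// scaled by its 1/n standard deviation (the penalty therefore acts on the
// unit-variance problem; reported lambdas and coefficients are on the
// original scale), and the path is log-spaced from the smallest lambda that
// zeroes every coefficient. Warm starts along the path; covariance updates
// (O(p) per coordinate after an O(np) setup) when p is moderate, naive
// O(n) updates otherwise. Convergence: largest squared standardized
// coefficient update in a sweep below thresh.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export(name = ".enetPath")]]
List enetPath(NumericMatrix Xin, NumericVector yin, double alpha,
              NumericVector lambdaIn, int nlambda, double lambdaMinRatio,
              double thresh, int maxit, bool standardize) {
  const int n = Xin.nrow(), p = Xin.ncol();
  if (n < 2) stop("need at least 2 observations");
  if (alpha <= 0.0 || alpha > 1.0) stop("alpha must be in (0, 1]");

  // centre/scale working predictor copy
  std::vector<double> X((size_t)n * p);
  std::vector<double> xm(p), xs(p);
  std::vector<bool> ok(p, true);
  for (int j = 0; j < p; ++j) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += Xin(i, j);
    m /= n;
    double v = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = Xin(i, j) - m;
      X[(size_t)j * n + i] = d;
      v += d * d;
    }
    v /= n;
    xm[j] = m;
    xs[j] = std::sqrt(v);
    if (xs[j] < 1e-12) { ok[j] = false; xs[j] = 1.0; }
    double s = standardize ? xs[j] : 1.0;
    if (s != 1.0)
      for (int i = 0; i < n; ++i) X[(size_t)j * n + i] /= s;
  }
  // centre y, scale to unit 1/n-sd
  double ym = 0.0;
  for (int i = 0; i < n; ++i) ym += yin[i];
  ym /= n;
  double yv = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = yin[i] - ym;
    yv += d * d;
  }
  yv /= n;
  const double ys = std::sqrt(yv);
  const bool degenerate = (ys < 1e-14);
  std::vector<double> r(n);  // residual of scaled, centred y
  if (!degenerate)
    for (int i = 0; i < n; ++i) r[i] = (yin[i] - ym) / ys;
  else
    std::fill(r.begin(), r.end(), 0.0);

  // column squared norms / n (1 when standardized)
  std::vector<double> xv(p);
  for (int j = 0; j < p; ++j) {
    double v = 0.0;
    const double* xj = &X[(size_t)j * n];
    for (int i = 0; i < n; ++i) v += xj[i] * xj[i];
    xv[j] = v / n;
    if (xv[j] < 1e-300) ok[j] = false;
  }

  // gradient at b = 0 (for the path start)
  std::vector<double> g0(p, 0.0);
  for (int j = 0; j < p; ++j) {
    if (!ok[j]) continue;
    const double* xj = &X[(size_t)j * n];
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += xj[i] * r[i];
    g0[j] = g / n;
  }

  // penalty path (internal scale; reported scale multiplies by ys)
  std::vector<double> lam;
  if (lambdaIn.size() > 0) {
    lam.resize(lambdaIn.size());
    for (int k = 0; k < (int)lambdaIn.size(); ++k)
      lam[k] = degenerate ? lambdaIn[k] : lambdaIn[k] / ys;
  } else {
    double lmax = 0.0;
    for (int j = 0; j < p; ++j)
      if (ok[j] && std::fabs(g0[j]) > lmax) lmax = std::fabs(g0[j]);
    lmax /= alpha;
    if (lmax < 1e-300) lmax = 1e-3;
    lam.resize(nlambda);
    double llmax = std::log(lmax), llmin = std::log(lmax * lambdaMinRatio);
    for (int k = 0; k < nlambda; ++k)
      lam[k] = std::exp(llmax + (llmin - llmax) * k / (double)(nlambda - 1));
  }
  const int nl = (int)lam.size();

  // covariance-update mode: q[j] = (1/n) x_j' X b maintained incrementally
  const bool useCov = (p <= 500);
  std::vector<double> C;   // p x p gram / n, filled lazily per column
  std::vector<bool> haveC;
  std::vector<double> q;
  if (useCov) {
    C.assign((size_t)p * p, 0.0);
    haveC.assign(p, false);
    q.assign(p, 0.0);
  }

  NumericMatrix beta(p, nl);
  NumericVector a0(nl);
  IntegerVector df(nl);
  std::vector<double> b(p, 0.0);
  bool converged = true;
  int sweeps = 0;

  auto updateCoord = [&](int j, double lab, double den, double& dmax) {
    double g;
    if (useCov) {
      g = g0[j] - q[j] + xv[j] * b[j];
    } else {
      const double* xj = &X[(size_t)j * n];
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xj[i] * r[i];
      g = s / n + xv[j] * b[j];
    }
    double bn = soft(g, lab) / (xv[j] + den);
    double d = bn - b[j];
    if (d != 0.0) {
      if (useCov) {
        if (!haveC[j]) {  // fill gram column on first use
          const double* xj = &X[(size_t)j * n];
          double* Cj = &C[(size_t)j * p];
          for (int k2 = 0; k2 < p; ++k2) {
            if (!ok[k2]) { Cj[k2] = 0.0; continue; }
            const double* xk = &X[(size_t)k2 * n];
            double s = 0.0;
            for (int i = 0; i < n; ++i) s += xj[i] * xk[i];
            Cj[k2] = s / n;
          }
          haveC[j] = true;
        }
        const double* Cj = &C[(size_t)j * p];
        for (int k2 = 0; k2 < p; ++k2) q[k2] += Cj[k2] * d;
      } else {
        const double* xj = &X[(size_t)j * n];
        for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
      }
      b[j] = bn;
      double dd = xv[j] * d * d;
      if (dd > dmax) dmax = dd;
    }
  };

  for (int k = 0; k < nl; ++k) {
    if (!degenerate) {
      const double lab = lam[k] * alpha;
      const double den = lam[k] * (1.0 - alpha);
      std::vector<bool> active(p, false);
      for (int j = 0; j < p; ++j) active[j] = (b[j] != 0.0);
      while (true) {
        // full sweep
        double dmax = 0.0;
        for (int j = 0; j < p; ++j) {
          if (!ok[j]) continue;
          updateCoord(j, lab, den, dmax);
          if (b[j] != 0.0) active[j] = true;
        }
        ++sweeps;
        if (dmax < thresh) break;
        if (sweeps >= maxit) { converged = false; break; }
        // active-set sweeps until stable
        while (true) {
          double am = 0.0;
          for (int j = 0; j < p; ++j) {
            if (!active[j] || !ok[j]) continue;
            updateCoord(j, lab, den, am);
          }
          ++sweeps;
          if (am < thresh) break;
          if (sweeps >= maxit) { converged = false; break; }
        }
        if (sweeps >= maxit) { converged = false; break; }
      }
    }
    // store on original scale
    double icpt = ym;
    int nz = 0;
    for (int j = 0; j < p; ++j) {
      double bj = b[j];
      if (bj != 0.0) {
        bj *= ys;
        if (standardize) bj /= xs[j];
        ++nz;
      }
      beta(j, k) = bj;
      icpt -= xm[j] * bj;
    }
    a0[k] = icpt;
    df[k] = nz;
  }

  NumericVector lamOut(nl);
  for (int k = 0; k < nl; ++k)
    lamOut[k] = degenerate ? lam[k] : lam[k] * ys;

  return List::create(_["beta"] = beta, _["a0"] = a0, _["lambda"] = lamOut,
                      _["df"] = df, _["converged"] = converged,
                      _["nulldev"] = yv,
                      _["included"] = LogicalVector(ok.begin(), ok.end()));
}
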