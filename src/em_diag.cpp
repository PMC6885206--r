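// EM for Gaussian mixtures with spherical/diagonal covariance
// parameterizations (Sigma_k = lambda_k * diag(A_k), det A_k = 1).
// Hot path of the per-gene screen; semantics mirror the R-level
// contract in fit_mixture().
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

enum Family { F_E, F_V, F_EII, F_VII, F_EEI, F_VEI, F_EVI, F_VVI };

static int family_code(const std::string &f) {
  if (f == "E") return F_E;
  if (f == "V") return F_V;
  if (f == "EII") return F_EII;
  if (f == "VII") return F_VII;
  if (f == "EEI") return F_EEI;
  if (f == "VEI") return F_VEI;
  if (f == "EVI") return F_EVI;
  if (f == "VVI") return F_VVI;
  stop("unknown family");
}

static double geo_mean(const double *v, int m) {
  double s = 0.0;
  for (int i = 0; i < m; ++i) s += std::log(v[i]);
  return std::exp(s / m);
}

// [[Rcpp::export]]
List em_diag_cpp(NumericMatrix x, NumericMatrix z0, std::string family,
                 double tol, int max_iter, NumericVector floor_var) {
  const int n = x.nrow(), d = x.ncol(), K = z0.ncol();
  const int fam = family_code(family);
  NumericMatrix z(clone(z0));
  NumericVector pro(K);
  NumericMatrix mu(d, K), W(d, K), sigma2(d, K), shape(d, K);
  NumericVector lambda(K);
  const double *px = x.begin(), *pfloor = floor_var.begin();
  double *pz = z.begin(), *pmu = mu.begin(), *pW = W.begin();
  double *psig = sigma2.begin(), *pshape = shape.begin();
  std::vector<double> trace;
  trace.reserve(64);
  std::vector<double> A(d, 1.0);          // VEI shared shape, warm-started
  std::vector<double> nk(K), cst(K), lpro(K), lk(K);
  double ll = R_NegInf;
  bool converged = false, degenerate = false, clamped_iter = false;
  int iter = 0;
  std::string status = "ok";

  while (true) {
    // ---- M-step ----
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      const double *zk = pz + (size_t)k * n;
      for (int i = 0; i < n; ++i) s += zk[i];
      nk[k] = s;
      if (s < 1.0) { status = "collapse"; goto done; }
      pro[k] = s / n;
    }
    for (int k = 0; k < K; ++k) {
      const double *zk = pz + (size_t)k * n;
      for (int j = 0; j < d; ++j) {
        const double *xj = px + (size_t)j * n;
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += zk[i] * xj[i];
        double m = s / nk[k];
        double w = 0.0;
        for (int i = 0; i < n; ++i) {
          double dev = xj[i] - m;
          w += zk[i] * dev * dev;
        }
        pmu[j + (size_t)k * d] = m;
        pW[j + (size_t)k * d] = w;
      }
    }

    // covariance decomposition under the family constraint
    switch (fam) {
    case F_E: case F_EII: {
      double s = 0.0;
      for (int k = 0; k < K; ++k) for (int j = 0; j < d; ++j) s += W(j, k);
      double lam = s / (double(n) * d);
      for (int k = 0; k < K; ++k) {
        lambda[k] = lam;
        for (int j = 0; j < d; ++j) { shape(j, k) = 1.0; sigma2(j, k) = lam; }
      }
      break;
    }
    case F_V: case F_VII: {
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < d; ++j) s += W(j, k);
        lambda[k] = s / (nk[k] * d);
        for (int j = 0; j < d; ++j) { shape(j, k) = 1.0; sigma2(j, k) = lambda[k]; }
      }
      break;
    }
    case F_EEI: {
      std::vector<double> S(d);
      for (int j = 0; j < d; ++j) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += W(j, k);
        S[j] = s / n;
      }
      double lam = geo_mean(S.data(), d);
      for (int k = 0; k < K; ++k) {
        lambda[k] = lam;
        for (int j = 0; j < d; ++j) { shape(j, k) = S[j] / lam; sigma2(j, k) = S[j]; }
      }
      break;
    }
    case F_VEI: {
      // no joint closed form: alternate volume/shape updates
      std::vector<double> lam(K, 1.0), lam_new(K), C(d);
      for (int it = 0; it < 100; ++it) {
        double delta = 0.0;
        for (int k = 0; k < K; ++k) {
          double s = 0.0;
          for (int j = 0; j < d; ++j) s += W(j, k) / A[j];
          lam_new[k] = s / (d * nk[k]);
        }
        for (int j = 0; j < d; ++j) {
          double s = 0.0;
          for (int k = 0; k < K; ++k) s += W(j, k) / lam_new[k];
          C[j] = s;
        }
        double g = geo_mean(C.data(), d);
        for (int k = 0; k < K; ++k) {
          double r = std::fabs(lam_new[k] - lam[k]) / (std::fabs(lam[k]) + 1e-300);
          if (r > delta) delta = r;
          lam[k] = lam_new[k];
        }
        for (int j = 0; j < d; ++j) {
          double a_new = C[j] / g;
          double r = std::fabs(a_new - A[j]) / (std::fabs(A[j]) + 1e-300);
          if (r > delta) delta = r;
          A[j] = a_new;
        }
        if (delta < 1e-8) break;
      }
      for (int k = 0; k < K; ++k) {
        lambda[k] = lam[k];
        for (int j = 0; j < d; ++j) { shape(j, k) = A[j]; sigma2(j, k) = lam[k] * A[j]; }
      }
      break;
    }
    case F_EVI: {
      double lam = 0.0;
      std::vector<double> gk(K);
      for (int k = 0; k < K; ++k) {
        gk[k] = geo_mean(pW + (size_t)k * d, d);
        lam += gk[k];
      }
      lam /= n;
      for (int k = 0; k < K; ++k) {
        lambda[k] = lam;
        for (int j = 0; j < d; ++j) {
          shape(j, k) = W(j, k) / gk[k];
          sigma2(j, k) = lam * shape(j, k);
        }
      }
      break;
    }
    case F_VVI: {
      std::vector<double> sk(d);
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < d; ++j) sk[j] = W(j, k) / nk[k];
        double lam = geo_mean(sk.data(), d);
        lambda[k] = lam;
        for (int j = 0; j < d; ++j) { shape(j, k) = sk[j] / lam; sigma2(j, k) = sk[j]; }
      }
      break;
    }
    }

    // volume clamp: constrained M-step keeping sigma2 >= floor; a fit
    // is "degenerate" only if its final M-step needed the clamp
    {
      clamped_iter = false;
      bool shared = (fam == F_E || fam == F_EII || fam == F_EEI || fam == F_EVI);
      double need_shared = 0.0;
      for (int k = 0; k < K; ++k) {
        double need = 0.0;
        for (int j = 0; j < d; ++j) {
          double r = pfloor[j] / shape(j, k);
          if (r > need) need = r;
        }
        if (shared) { if (need > need_shared) need_shared = need; }
        else if (lambda[k] < need) {
          clamped_iter = true;
          lambda[k] = need;
          for (int j = 0; j < d; ++j) sigma2(j, k) = need * shape(j, k);
        }
      }
      if (shared && lambda[0] < need_shared) {
        clamped_iter = true;
        for (int k = 0; k < K; ++k) {
          lambda[k] = need_shared;
          for (int j = 0; j < d; ++j) sigma2(j, k) = need_shared * shape(j, k);
        }
      }
    }

    // ---- E-step ----
    for (int k = 0; k < K; ++k) {
      double c = 0.0;
      for (int j = 0; j < d; ++j) c += std::log(2.0 * M_PI * psig[j + (size_t)k * d]);
      cst[k] = std::log(pro[k]) - 0.5 * c;
    }
    double ll_new = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double q = 0.0;
        const double *muk = pmu + (size_t)k * d;
        const double *sk = psig + (size_t)k * d;
        for (int j = 0; j < d; ++j) {
          double dev = px[i + (size_t)j * n] - muk[j];
          q += dev * dev / sk[j];
        }
        lk[k] = cst[k] - 0.5 * q;
        if (lk[k] > mx) mx = lk[k];
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        lk[k] = std::exp(lk[k] - mx);
        s += lk[k];
      }
      ll_new += mx + std::log(s);
      for (int k = 0; k < K; ++k) pz[i + (size_t)k * n] = lk[k] / s;
    }
    ++iter;
    trace.push_back(ll_new);
    if (R_finite(ll) && std::fabs(ll_new - ll) < tol * std::fabs(ll_new)) {
      ll = ll_new; converged = true; break;
    }
    ll = ll_new;
    if (iter >= max_iter) break;
  }
done:
  degenerate = clamped_iter;
  (void)pshape;
  return List::create(
    _["pro"] = pro, _["mean"] = mu, _["lambda"] = lambda,
    _["shape"] = shape, _["sigma2"] = sigma2, _["z"] = z,
    _["loglik"] = ll, _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["iter"] = iter, _["converged"] = converged,
    _["degenerate"] = degenerate, _["status"] = status);
}
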