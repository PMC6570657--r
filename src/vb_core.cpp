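#include <Rcpp.h>
using namespace Rcpp;

// Variational-Bayes EM for the diffusion HMM.
//
// Each displacement step t carries the scalar sufficient statistic
// sq[t] = |dx|^2 + |dy|^2 (um^2). Under state k the step is isotropic
// 2-D Gaussian with per-coordinate precision lambda_k, so the tilted
// (expected-log-parameter) emission weight is
//   log rho_tk = E[log lambda_k] - log(2*pi) - E[lambda_k] * sq[t] / 2 .
// Transitions use the tilted matrix exp(E[log A]) and initial weights
// exp(E[log pi]); the accumulated log-normalizer of the scaled recursion
// is the likelihood term of the evidence lower bound (ELBO).
//
// Priors (conjugate): gamma(a0, b0) on each lambda_k, symmetric
// Dirichlet(alpha0) on each transition row and the initial distribution.

static const double LOG2PI = 1.8378770664093453;

struct EStats {
  std::vector<double> Nk, Sk, Minit, Njk; // Njk row-major K x K
  double logZ;
};

// one scaled forward-backward sweep accumulating sufficient statistics
static void estep(const double* sq, const int* starts, const int* lens, int R,
                  int K, const std::vector<double>& Elam,
                  const std::vector<double>& Eloglam,
                  const std::vector<double>& Atil,   // row-major K x K
                  const std::vector<double>& pitil,
                  std::vector<double>& alpha, std::vector<double>& beta,
                  std::vector<double>& rho, std::vector<double>& cvec,
                  std::vector<double>& cvecTmp, EStats& st) {
  std::fill(st.Nk.begin(), st.Nk.end(), 0.0);
  std::fill(st.Sk.begin(), st.Sk.end(), 0.0);
  std::fill(st.Minit.begin(), st.Minit.end(), 0.0);
  std::fill(st.Njk.begin(), st.Njk.end(), 0.0);
  st.logZ = 0.0;

  for (int r = 0; r < R; ++r) {
    const int T = lens[r];
    const int off = starts[r];

    for (int t = 0; t < T; ++t) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double le = Eloglam[k] - LOG2PI - 0.5 * Elam[k] * sq[off + t];
        rho[t * K + k] = le;
        if (le > mx) mx = le;
      }
      for (int k = 0; k < K; ++k) rho[t * K + k] = std::exp(rho[t * K + k] - mx);
      st.logZ += mx;  // restore the per-step shift in the normalizer
    }

    double c0 = 0.0;
    for (int k = 0; k < K; ++k) { alpha[k] = pitil[k] * rho[k]; c0 += alpha[k]; }
    for (int k = 0; k < K; ++k) alpha[k] /= c0;
    cvec[0] = c0;
    for (int t = 1; t < T; ++t) {
      double ct = 0.0;
      const double* ap = &alpha[(t - 1) * K];
      double* an = &alpha[t * K];
      for (int j = 0; j < K; ++j) {
        double a = 0.0;
        for (int k = 0; k < K; ++k) a += ap[k] * Atil[k * K + j];
        a *= rho[t * K + j];
        an[j] = a;
        ct += a;
      }
      for (int j = 0; j < K; ++j) an[j] /= ct;
      cvec[t] = ct;
    }
    for (int t = 0; t < T; ++t) st.logZ += std::log(cvec[t]);

    // backward pass with fused accumulation of the transition counts:
    // tmp[j] = rho(t+1, j) * beta(t+1, j) / c(t+1) serves both the beta
    // recursion and xi(t, k, j) = alpha(t, k) * Atil[k, j] * tmp[j]
    std::vector<double>& tmp = cvecTmp;
    for (int k = 0; k < K; ++k) beta[(T - 1) * K + k] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      const double* bn = &beta[(t + 1) * K];
      const double* rn = &rho[(t + 1) * K];
      const double* ap = &alpha[t * K];
      double* bt = &beta[t * K];
      const double ic = 1.0 / cvec[t + 1];
      for (int j = 0; j < K; ++j) tmp[j] = rn[j] * bn[j] * ic;
      for (int k = 0; k < K; ++k) {
        double b = 0.0;
        const double* Ak = &Atil[k * K];
        double* Nk = &st.Njk[k * K];
        const double ak = ap[k];
        for (int j = 0; j < K; ++j) {
          const double w = Ak[j] * tmp[j];
          b += w;
          Nk[j] += ak * w;
        }
        bt[k] = b;
      }
    }

    for (int t = 0; t < T; ++t) {
      for (int k = 0; k < K; ++k) {
        double g = alpha[t * K + k] * beta[t * K + k];
        st.Nk[k] += g;
        st.Sk[k] += g * sq[off + t];
        if (t == 0) st.Minit[k] += g;
      }
    }
  }
}

static double klDirichlet(const double* a, int K, double a0) {
  double s = 0.0, s0 = K * a0, kl;
  for (int k = 0; k < K; ++k) s += a[k];
  kl = R::lgammafn(s) - R::lgammafn(s0);
  double dgs = R::digamma(s);
  for (int k = 0; k < K; ++k)
    kl += -R::lgammafn(a[k]) + R::lgammafn(a0) +
      (a[k] - a0) * (R::digamma(a[k]) - dgs);
  return kl;
}

static double klGamma(double a, double b, double a0, double b0) {
  return (a - a0) * R::digamma(a) - R::lgammafn(a) + R::lgammafn(a0) +
    a0 * (std::log(b) - std::log(b0)) + a * (b0 - b) / b;
}

// Full VBEM optimization from a given initialization of the expected
// log-parameters. Returns the conjugate posterior, the ELBO trace (one
// value per iteration from the second sweep on), the expected per-state
// step counts consistent with the final E-step, and a convergence flag.
// [[Rcpp::export]]
List vb_vbem_cpp(NumericVector sq, IntegerVector starts, IntegerVector lens,
                 NumericVector Elam0, NumericVector Eloglam0,
                 NumericMatrix ElogA0, NumericVector Elogpi0,
                 double a0, double b0, double alpha0,
                 int maxIter, double tol) {
  const int K = Elam0.size();
  const int R = starts.size();
  const int Tn = sq.size();
  int maxT = 0;
  for (int r = 0; r < R; ++r) if (lens[r] > maxT) maxT = lens[r];

  std::vector<double> Elam(Elam0.begin(), Elam0.end());
  std::vector<double> Eloglam(Eloglam0.begin(), Eloglam0.end());
  std::vector<double> Atil(K * K), pitil(K);
  for (int k = 0; k < K; ++k) {
    pitil[k] = std::exp(Elogpi0[k]);
    for (int j = 0; j < K; ++j) Atil[k * K + j] = std::exp(ElogA0(k, j));
  }

  std::vector<double> alpha(maxT * K), beta(maxT * K), rho(maxT * K), cvec(maxT);
  std::vector<double> tmpK(K);
  EStats st;
  st.Nk.resize(K); st.Sk.resize(K); st.Minit.resize(K); st.Njk.resize(K * K);

  std::vector<double> qa(K), qb(K), qA(K * K), qpi(K);
  bool haveQ = false, converged = false;
  std::vector<double> trace;
  trace.reserve(256);

  for (int iter = 0; iter < maxIter; ++iter) {
    estep(REAL(sq), INTEGER(starts), INTEGER(lens), R, K, Elam, Eloglam,
          Atil, pitil, alpha, beta, rho, cvec, tmpK, st);
    if (haveQ) {
      double kl = 0.0;
      for (int k = 0; k < K; ++k) kl += klGamma(qa[k], qb[k], a0, b0);
      for (int k = 0; k < K; ++k) kl += klDirichlet(&qA[k * K], K, alpha0);
      kl += klDirichlet(&qpi[0], K, alpha0);
      double el = st.logZ - kl;
      if (!trace.empty() &&
          std::fabs(el - trace.back()) <= tol * std::max(1.0, std::fabs(el)))
        converged = true;
      trace.push_back(el);
    }
    // M-step
    for (int k = 0; k < K; ++k) {
      qa[k] = a0 + st.Nk[k];
      qb[k] = b0 + st.Sk[k] / 2.0;
      qpi[k] = alpha0 + st.Minit[k];
      for (int j = 0; j < K; ++j) qA[k * K + j] = alpha0 + st.Njk[k * K + j];
    }
    haveQ = true;
    // refresh expectations
    double spi = 0.0;
    for (int k = 0; k < K; ++k) spi += qpi[k];
    double dgspi = R::digamma(spi);
    for (int k = 0; k < K; ++k) {
      Elam[k] = qa[k] / qb[k];
      Eloglam[k] = R::digamma(qa[k]) - std::log(qb[k]);
      pitil[k] = std::exp(R::digamma(qpi[k]) - dgspi);
      double srow = 0.0;
      for (int j = 0; j < K; ++j) srow += qA[k * K + j];
      double dgrow = R::digamma(srow);
      for (int j = 0; j < K; ++j)
        Atil[k * K + j] = std::exp(R::digamma(qA[k * K + j]) - dgrow);
    }
    if (converged) break;
  }

  NumericMatrix alphaA(K, K);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < K; ++j) alphaA(k, j) = qA[k * K + j];
  (void)Tn;
  return List::create(
    _["a"] = NumericVector(qa.begin(), qa.end()),
    _["b"] = NumericVector(qb.begin(), qb.end()),
    _["alphaA"] = alphaA,
    _["alphaPi"] = NumericVector(qpi.begin(), qpi.end()),
    _["Nk"] = NumericVector(st.Nk.begin(), st.Nk.end()),
    _["elbo"] = trace.empty() ? R_NegInf : trace.back(),
    _["elboTrace"] = NumericVector(trace.begin(), trace.end()),
    _["converged"] = converged);
}

// Viterbi decoding under fixed (posterior-mean) parameters.
// Returns 0-based state labels, one per step, trajectories concatenated.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericVector sq, IntegerVector starts, IntegerVector lens,
                          NumericVector lam, NumericVector loglam,
                          NumericMatrix logA, NumericVector logpi) {
  const int K = lam.size();
  const int R = starts.size();
  IntegerVector path(sq.size());

  for (int r = 0; r < R; ++r) {
    const int T = lens[r];
    const int off = starts[r];
    NumericMatrix delta(T, K);
    IntegerMatrix psi(T, K);

    for (int k = 0; k < K; ++k)
      delta(0, k) = logpi[k] + loglam[k] - LOG2PI - 0.5 * lam[k] * sq[off];
    for (int t = 1; t < T; ++t) {
      for (int j = 0; j < K; ++j) {
        double best = R_NegInf; int arg = 0;
        for (int k = 0; k < K; ++k) {
          double v = delta(t - 1, k) + logA(k, j);
          if (v > best) { best = v; arg = k; }
        }
        delta(t, j) = best + loglam[j] - LOG2PI - 0.5 * lam[j] * sq[off + t];
        psi(t, j) = arg;
      }
    }
    int arg = 0; double best = R_NegInf;
    for (int k = 0; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
    path[off + T - 1] = arg;
    for (int t = T - 1; t >= 1; --t) {
      arg = psi(t, arg);
      path[off + t - 1] = arg;
    }
  }
  return path;
}
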