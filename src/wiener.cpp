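#include <Rcpp.h>
using namespace Rcpp;

// Wiener first-passage-time density (Navarro & Fuss series, truncation error
// < 1e-7).  Convention: diffusion coefficient 1; boundaries at 0 (lower) and
// alpha (upper); the process starts at beta * alpha; drift delta; the
// likelihood of an upper-boundary hit is the lower-boundary formula under the
// reflection (delta, beta) -> (-delta, 1 - beta).

static const double ERR = 1e-7;

// Density of hitting the LOWER boundary at decision time t (t already has
// the non-decision time removed), for relative start w and drift v.
static double fpt_lower(double t, double alpha, double v, double w) {
  if (t <= 0) return 0.0;
  double tt = t / (alpha * alpha);  // normalized time

  double kl, ks;
  if (M_PI * tt * ERR < 1) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * ERR) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * ERR < 1) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * ERR));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }

  double p = 0.0;
  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    for (int k = -(K - 1) / 2; k <= (int)std::ceil((K - 1) / 2.0); ++k) {
      double a = w + 2.0 * k;
      p += a * std::exp(-a * a / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {        // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k)
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * w);
    p *= M_PI;
  }
  return p * std::exp(-v * alpha * w - v * v * t / 2.0) / (alpha * alpha);
}

// Vectorized log density at decision times dt (rt - tau already removed by
// the caller when tau enters); upper = 1 codes the upper boundary.
//' @noRd
// [[Rcpp::export(name = ".wiener_lpdf")]]
NumericVector wiener_lpdf(NumericVector dt, IntegerVector upper, double alpha,
                          double beta, double delta) {
  int n = dt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double f;
    if (upper[i] == 1) f = fpt_lower(dt[i], alpha, -delta, 1.0 - beta);
    else               f = fpt_lower(dt[i], alpha, delta, beta);
    out[i] = f > 0 ? std::log(f) : R_NegInf;
  }
  return out;
}

// Batched session log-likelihoods for the hierarchical sampler.
// params: rows of (alpha, beta, delta, tau); rt in seconds; choice 1 = upper.
//' @noRd
// [[Rcpp::export(name = ".ddm_loglik_batch")]]
NumericVector ddm_loglik_batch(NumericMatrix params, NumericVector rt,
                               IntegerVector choice, IntegerVector start,
                               IntegerVector len) {
  int S = params.nrow();
  NumericVector ll(S);
  for (int s = 0; s < S; ++s) {
    double alpha = params(s, 0), beta = params(s, 1), delta = params(s, 2),
           tau = params(s, 3);
    double acc = 0.0;
    for (int i = start[s]; i < start[s] + len[s]; ++i) {
      double t = rt[i] - tau;
      if (t <= 0) { acc = R_NegInf; break; }
      double f = choice[i] == 1 ? fpt_lower(t, alpha, -delta, 1.0 - beta)
                                : fpt_lower(t, alpha, delta, beta);
      if (f <= 0) { acc = R_NegInf; break; }
      acc += std::log(f);
    }
    ll[s] = acc;
  }
  return ll;
}
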