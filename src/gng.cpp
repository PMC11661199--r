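#include <Rcpp.h>
using namespace Rcpp;

// Pavlovian-bias RL model for the orthogonalized go/no-go task.
// Cue coding: 1 = go_to_win, 2 = nogo_to_win, 3 = go_to_avoid, 4 = nogo_to_avoid.
// Choice coding: 1 = go, 0 = nogo.  Outcome coding: r in {-1, 0, +1}.
// Parameter vector (native scale): eps, b, pi_app, pi_av, rho_rew, rho_pun, xi.

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// One session's log-likelihood given native parameters; states start at 0.
static double gng_session_ll(const double* par,
                             const int* cue, const int* choice, const int* out,
                             int n) {
  const double eps = par[0], b = par[1], pi_app = par[2], pi_av = par[3],
               rho_rew = par[4], rho_pun = par[5], xi = par[6];
  double Qgo[4] = {0, 0, 0, 0}, Qng[4] = {0, 0, 0, 0}, V[4] = {0, 0, 0, 0};
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int c = cue[t] - 1;
    double pav = (c < 2) ? pi_app : pi_av;          // win cues vs avoid cues
    double wdiff = Qgo[c] + b + pav * V[c] - Qng[c];
    double pgo = xi / 2.0 + (1.0 - xi) * logistic(wdiff);
    double p = choice[t] == 1 ? pgo : 1.0 - pgo;
    ll += std::log(std::max(p, 1e-300));
    double u = out[t] > 0 ? rho_rew : (out[t] < 0 ? -rho_pun : 0.0);
    if (choice[t] == 1) Qgo[c] += eps * (u - Qgo[c]); else Qng[c] += eps * (u - Qng[c]);
    V[c] += eps * (u - V[c]);
  }
  return ll;
}

//' @noRd
// [[Rcpp::export(name = ".gng_loglik_batch")]]
NumericVector gng_loglik_batch(NumericMatrix params, IntegerVector cue,
                               IntegerVector choice, IntegerVector outcome,
                               IntegerVector start, IntegerVector len) {
  int S = params.nrow();
  if (start.size() != S || len.size() != S)
    stop("offsets must match the number of parameter rows");
  NumericVector ll(S);
  for (int s = 0; s < S; ++s) {
    double par[7];
    for (int j = 0; j < 7; ++j) par[j] = params(s, j);
    ll[s] = gng_session_ll(par, &cue[start[s]], &choice[start[s]],
                           &outcome[start[s]], len[s]);
  }
  return ll;
}

// Per-trial probability of the observed choice (used for trialwise WAIC
// pointwise likelihoods and posterior-predictive transfer).
//' @noRd
// [[Rcpp::export(name = ".gng_trialwise_p")]]
NumericVector gng_trialwise_p(NumericVector par, IntegerVector cue,
                              IntegerVector choice, IntegerVector outcome) {
  int n = cue.size();
  const double eps = par[0], b = par[1], pi_app = par[2], pi_av = par[3],
               rho_rew = par[4], rho_pun = par[5], xi = par[6];
  double Qgo[4] = {0, 0, 0, 0}, Qng[4] = {0, 0, 0, 0}, V[4] = {0, 0, 0, 0};
  NumericVector p(n);
  for (int t = 0; t < n; ++t) {
    int c = cue[t] - 1;
    double pav = (c < 2) ? pi_app : pi_av;
    double pgo = xi / 2.0 +
      (1.0 - xi) * logistic(Qgo[c] + b + pav * V[c] - Qng[c]);
    p[t] = choice[t] == 1 ? pgo : 1.0 - pgo;
    double u = outcome[t] > 0 ? rho_rew : (outcome[t] < 0 ? -rho_pun : 0.0);
    if (choice[t] == 1) Qgo[c] += eps * (u - Qgo[c]); else Qng[c] += eps * (u - Qng[c]);
    V[c] += eps * (u - V[c]);
  }
  return p;
}

// Forward simulation of one agent on a schedule.  Uniform draws are supplied
// by the caller so all randomness flows through R's seeded RNG.
//' @noRd
// [[Rcpp::export(name = ".gng_simulate")]]
List gng_simulate(NumericVector par, IntegerVector cue, IntegerVector veridical,
                  NumericVector unif) {
  int n = cue.size();
  const double eps = par[0], b = par[1], pi_app = par[2], pi_av = par[3],
               rho_rew = par[4], rho_pun = par[5], xi = par[6];
  double Qgo[4] = {0, 0, 0, 0}, Qng[4] = {0, 0, 0, 0}, V[4] = {0, 0, 0, 0};
  IntegerVector choice(n), outcome(n);
  for (int t = 0; t < n; ++t) {
    int c = cue[t] - 1;
    double pav = (c < 2) ? pi_app : pi_av;
    double pgo = xi / 2.0 +
      (1.0 - xi) * logistic(Qgo[c] + b + pav * V[c] - Qng[c]);
    int a = unif[t] < pgo ? 1 : 0;
    // correct action: go for cues 1,3; the better outcome within the cue's
    // pair is delivered iff (action correct) XOR (trial not veridical)
    int correct_go = (c == 0 || c == 2) ? 1 : 0;
    bool assoc = (a == correct_go) != (veridical[t] == 0);
    int r;
    if (c < 2) r = assoc ? 1 : 0;   // win cues: {+1, 0}
    else       r = assoc ? 0 : -1;  // avoid cues: {0, -1}
    choice[t] = a;
    outcome[t] = r;
    double u = r > 0 ? rho_rew : (r < 0 ? -rho_pun : 0.0);
    if (a == 1) Qgo[c] += eps * (u - Qgo[c]); else Qng[c] += eps * (u - Qng[c]);
    V[c] += eps * (u - V[c]);
  }
  return List::create(_["choice"] = choice, _["outcome"] = outcome);
}
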