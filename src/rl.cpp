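#include <Rcpp.h>
using namespace Rcpp;

// Two-armed Q-learning with forgetting: chosen option i is updated by
// V(i) += alpha * (r - V(i)); the unchosen option j decays towards the
// default value, V(j) += phi * (mu - V(j)).  The standard model is the
// special case phi = 0.  Choice follows a two-option softmax with
// inverse temperature beta_it.  All three entry points share the same
// update so fitted and simulated latents are guaranteed to agree.

static inline double softmax_p1(double v1, double v2, double beta_it) {
  return 1.0 / (1.0 + std::exp(-beta_it * (v1 - v2)));
}

// Latent values and prediction errors implied by a fixed sequence of
// choices and rewards.  Values are recorded *before* the trial-t update
// (the regressor convention).
// [[Rcpp::export]]
List rl_latents_cpp(IntegerVector choice, NumericVector reward,
                    double alpha, double phi, double mu) {
  int T = choice.size();
  NumericMatrix V(T, 2);
  NumericVector delta(T), v_chosen(T);
  double v1 = mu, v2 = mu;
  for (int t = 0; t < T; ++t) {
    V(t, 0) = v1;
    V(t, 1) = v2;
    double vc = (choice[t] == 1) ? v1 : v2;
    double d = reward[t] - vc;
    v_chosen[t] = vc;
    delta[t] = d;
    if (choice[t] == 1) {
      v1 += alpha * d;
      v2 += phi * (mu - v2);
    } else {
      v2 += alpha * d;
      v1 += phi * (mu - v1);
    }
  }
  return List::create(_["V"] = V, _["delta"] = delta,
                      _["v_chosen"] = v_chosen);
}

// Negative log-likelihood of the observed choices.  Probabilities are
// floored at 1e-30 so the objective stays finite at extreme parameters.
// [[Rcpp::export]]
double rl_nll_cpp(IntegerVector choice, NumericVector reward,
                  double alpha, double beta_it, double phi, double mu) {
  int T = choice.size();
  double v1 = mu, v2 = mu, nll = 0.0;
  for (int t = 0; t < T; ++t) {
    double p1 = softmax_p1(v1, v2, beta_it);
    double p = (choice[t] == 1) ? p1 : 1.0 - p1;
    if (p < 1e-30) p = 1e-30;
    nll -= std::log(p);
    double vc = (choice[t] == 1) ? v1 : v2;
    double d = reward[t] - vc;
    if (choice[t] == 1) {
      v1 += alpha * d;
      v2 += phi * (mu - v2);
    } else {
      v2 += alpha * d;
      v1 += phi * (mu - v1);
    }
  }
  return nll;
}

// Simulate choices and outcomes online: at each trial the agent picks
// an option through the softmax, then the reward is drawn with that
// option's scheduled probability.  Uses R's RNG so runs are seedable.
// [[Rcpp::export]]
List rl_simulate_cpp(NumericMatrix probs, double alpha, double beta_it,
                     double phi, double mu) {
  int T = probs.nrow();
  IntegerVector choice(T), reward(T);
  NumericMatrix V(T, 2);
  NumericVector delta(T), v_chosen(T);
  double v1 = mu, v2 = mu;
  for (int t = 0; t < T; ++t) {
    V(t, 0) = v1;
    V(t, 1) = v2;
    double p1 = softmax_p1(v1, v2, beta_it);
    int c = (unif_rand() < p1) ? 1 : 2;
    int r = (unif_rand() < probs(t, c - 1)) ? 1 : 0;
    choice[t] = c;
    reward[t] = r;
    double vc = (c == 1) ? v1 : v2;
    double d = r - vc;
    v_chosen[t] = vc;
    delta[t] = d;
    if (c == 1) {
      v1 += alpha * d;
      v2 += phi * (mu - v2);
    } else {
      v2 += alpha * d;
      v1 += phi * (mu - v1);
    }
  }
  return List::create(_["choice"] = choice, _["reward"] = reward,
                      _["V"] = V, _["delta"] = delta,
                      _["v_chosen"] = v_chosen);
}
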