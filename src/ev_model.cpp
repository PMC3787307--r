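#include <Rcpp.h>
using namespace Rcpp;

// One-step-ahead log-likelihood of the rEV model on a session.
// deck is 1..4; theta is a per-trial sensitivity vector (length T);
// expectancies start at 0 so the first choice is uniform. The probability
// of the observed choice at trial t is computed from expectancies built
// from trials 1..t-1, then the chosen deck's expectancy is updated with
// the trial-t valence v = w*win - (1-w)*loss.
// [[Rcpp::export]]
double ev_loglik_cpp(IntegerVector deck, NumericVector win, NumericVector loss,
                     double w, double phi, NumericVector theta,
                     double prob_floor) {
  int T = deck.size();
  double E[4] = {0.0, 0.0, 0.0, 0.0};
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double th = theta[t];
    double m = th * E[0];
    for (int j = 1; j < 4; ++j) if (th * E[j] > m) m = th * E[j];
    double denom = 0.0, num = 0.0;
    int ch = deck[t] - 1;
    for (int j = 0; j < 4; ++j) {
      double e = std::exp(th * E[j] - m);
      denom += e;
      if (j == ch) num = e;
    }
    double p = num / denom;
    if (p < prob_floor) p = prob_floor;
    ll += std::log(p);
    double v = w * win[t] - (1.0 - w) * loss[t];
    E[ch] += phi * (v - E[ch]);
  }
  return ll;
}

// Per-trial one-step-ahead choice probabilities (T x 4) and the expectancy
// trajectory AFTER each update (T x 4), for predict()/plot() methods.
// [[Rcpp::export]]
List ev_trace_cpp(IntegerVector deck, NumericVector win, NumericVector loss,
                  double w, double phi, NumericVector theta) {
  int T = deck.size();
  NumericMatrix P(T, 4), Em(T, 4);
  double E[4] = {0.0, 0.0, 0.0, 0.0};
  for (int t = 0; t < T; ++t) {
    double th = theta[t];
    double m = th * E[0];
    for (int j = 1; j < 4; ++j) if (th * E[j] > m) m = th * E[j];
    double denom = 0.0, ex[4];
    for (int j = 0; j < 4; ++j) { ex[j] = std::exp(th * E[j] - m); denom += ex[j]; }
    for (int j = 0; j < 4; ++j) P(t, j) = ex[j] / denom;
    int ch = deck[t] - 1;
    double v = w * win[t] - (1.0 - w) * loss[t];
    E[ch] += phi * (v - E[ch]);
    for (int j = 0; j < 4; ++j) Em(t, j) = E[j];
  }
  return List::create(_["prob"] = P, _["expectancy"] = Em);
}

// Generative simulation of a session: choices sampled from the softmax,
// outcomes drawn from the cyclic deck schedules at each deck's next
// within-deck position. Uses R's RNG so set.seed() governs reproducibility.
// gains: length 4; losses: 4 x 10 matrix (rows A..D).
// [[Rcpp::export]]
List ev_simulate_cpp(int n_trials, double w, double phi, NumericVector theta,
                     NumericVector gains, NumericMatrix losses) {
  IntegerVector deck(n_trials);
  NumericVector win(n_trials), loss(n_trials);
  double E[4] = {0.0, 0.0, 0.0, 0.0};
  int pos[4] = {0, 0, 0, 0};
  for (int t = 0; t < n_trials; ++t) {
    double th = theta[t];
    double m = th * E[0];
    for (int j = 1; j < 4; ++j) if (th * E[j] > m) m = th * E[j];
    double p[4], denom = 0.0;
    for (int j = 0; j < 4; ++j) { p[j] = std::exp(th * E[j] - m); denom += p[j]; }
    double u = R::unif_rand() * denom, cum = 0.0;
    int ch = 3;
    for (int j = 0; j < 4; ++j) { cum += p[j]; if (u <= cum) { ch = j; break; } }
    int k = pos[ch] % 10;
    pos[ch] += 1;
    double wn = gains[ch], ls = losses(ch, k);
    deck[t] = ch + 1;
    win[t] = wn;
    loss[t] = ls;
    double v = w * wn - (1.0 - w) * ls;
    E[ch] += phi * (v - E[ch]);
  }
  return List::create(_["deck"] = deck, _["win"] = win, _["loss"] = loss);
}
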