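#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequential likelihood of the action-prediction observer models.
//
// Per trial: the goal-inference probabilities (precomputed, parameter-free)
// and the current policy-learning estimate are each min-max rescaled over the
// available actions, mixed with weight W, and renormalized to a categorical
// distribution; the participant's predicted action is scored against it and
// the policy estimate is then updated from the agent's observed action with
// learning rate alpha * n^-lambda (kernel-smoothed target for the
// generalization learner). Policy values persist across games, so the caller
// passes one subject's trials in task order.
//
// learner: 0 none (goal only), 1 recency-weighted, 2 kernel-generalized,
//          3 repeat-previous-action.
// [[Rcpp::export]]
List prediction_loglik_cpp(NumericMatrix goal, IntegerMatrix avail,
                           IntegerVector obs, IntegerVector pred,
                           int learner, double alpha, double lambda,
                           double W, double lscale) {
  const int T = goal.nrow();
  const double floor_p = 1e-10;
  double pi_hat[6] = {0, 0, 0, 0, 0, 0};
  int prev_obs = -1;
  // circular squared-exponential kernel over the action ring (angles
  // normalized to [0,1)), rows normalized to unit mass
  double K[6][6];
  if (learner == 2) {
    for (int i = 0; i < 6; ++i) {
      double rowsum = 0.0;
      for (int j = 0; j < 6; ++j) {
        double d = std::abs(i - j) / 6.0;
        if (d > 0.5) d = 1.0 - d;
        K[i][j] = std::exp(-(d * d) / (2.0 * lscale * lscale));
        rowsum += K[i][j];
      }
      for (int j = 0; j < 6; ++j) K[i][j] /= rowsum;
    }
  }
  double nll = 0.0, acc = 0.0;
  int n_obs = 0;
  NumericMatrix probs(T, 6);
  for (int t = 0; t < T; ++t) {
    double pol[6];
    if (learner == 3) {
      for (int a = 0; a < 6; ++a) pol[a] = (a == prev_obs) ? 1.0 : 0.0;
    } else {
      for (int a = 0; a < 6; ++a) pol[a] = pi_hat[a];
    }
    // min-max rescale each component over available actions (Eq. 9 style);
    // constant vectors rescale to zero
    double gmin = R_PosInf, gmax = R_NegInf, pmin = R_PosInf, pmax = R_NegInf;
    for (int a = 0; a < 6; ++a) {
      if (!avail(t, a)) continue;
      double g = goal(t, a);
      if (g < gmin) gmin = g;
      if (g > gmax) gmax = g;
      if (pol[a] < pmin) pmin = pol[a];
      if (pol[a] > pmax) pmax = pol[a];
    }
    double comb[6], total = 0.0;
    int n_avail = 0;
    for (int a = 0; a < 6; ++a) {
      if (!avail(t, a)) { comb[a] = 0.0; continue; }
      ++n_avail;
      double g = (gmax > gmin) ? (goal(t, a) - gmin) / (gmax - gmin) : 0.0;
      double p = (pmax > pmin) ? (pol[a] - pmin) / (pmax - pmin) : 0.0;
      comb[a] = W * g + (1.0 - W) * p;
      total += comb[a];
    }
    if (total <= 0.0) {
      for (int a = 0; a < 6; ++a) comb[a] = avail(t, a) ? 1.0 / n_avail : 0.0;
    } else {
      for (int a = 0; a < 6; ++a) comb[a] /= total;
    }
    for (int a = 0; a < 6; ++a) probs(t, a) = comb[a];
    int pa = pred[t] - 1;
    double pr = (pa >= 0 && pa < 6) ? comb[pa] : 0.0;
    if (pr < floor_p) pr = floor_p;
    nll -= std::log(pr);
    // modal-prediction accuracy against the agent's actual action; ties share
    // credit equally
    double mx = -1.0;
    int ties = 0;
    for (int a = 0; a < 6; ++a) {
      if (!avail(t, a)) continue;
      if (comb[a] > mx + 1e-12) { mx = comb[a]; ties = 1; }
      else if (comb[a] > mx - 1e-12) ++ties;
    }
    int oa = obs[t] - 1;
    if (oa >= 0 && oa < 6 && avail(t, oa) && comb[oa] > mx - 1e-12)
      acc += 1.0 / ties;
    // learner update from the observed action
    ++n_obs;
    if (learner == 1 || learner == 2) {
      double at = alpha * std::pow((double)n_obs, -lambda);
      for (int a = 0; a < 6; ++a) {
        double target = (learner == 2) ? K[oa][a] : (a == oa ? 1.0 : 0.0);
        pi_hat[a] += at * (target - pi_hat[a]);
      }
    }
    prev_obs = oa;
  }
  return List::create(_["neg_loglik"] = nll, _["accuracy"] = acc / T,
                      _["probs"] = probs);
}
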