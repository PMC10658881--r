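#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
using namespace Rcpp;

// Upper Confidence Bound for Trees (UCT) planner for the prey on the joint
// prey-predator gridworld MDP.
//
// The search tree is built over the prey's own future actions (one tree level
// per prey move); the predator's moves inside simulations are treated as
// environment stochasticity, sampled according to the opponent model:
//   opponent 0 - predator absent from simulations (non-interactive MCTS)
//   opponent 1 - uniform random over the predator's legal moves (MCTS-Rand)
//   opponent 2 - sampled from a supplied stationary policy matrix (MCTS-RW,
//                value-iteration policy under the agent's true reward weights)
// Rollouts use a uniform random prey policy. Simulated returns are 100 per
// coin collected minus 1000 * theta on capture; the exploitation term is
// min-max normalized to [0,1] within the tree so a single exploration
// constant works across threat sensitivities.
//
// schedule: vector of 0 (prey move) / 1 (predator move) covering the
// remaining moves of the game, starting with the decision being made.
// [[Rcpp::export]]
List mcts_choose_cpp(IntegerMatrix nbr, int prey, int pred,
                     IntegerVector coins, IntegerVector schedule,
                     int opponent, NumericMatrix opp_policy,
                     double theta, int n_sim, double c_uct, int seed,
                     bool capture_symmetric) {
  if (n_sim < 1) stop("n_sim must be >= 1");
  const int ncell = nbr.nrow();
  const int depth_total = schedule.size();
  if (depth_total < 1 || schedule[0] != 0) stop("schedule must start with a prey move");
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<bool> coin0(ncell + 1, false);
  for (int i = 0; i < coins.size(); ++i) coin0[coins[i]] = true;

  // flat tree storage: per node, 6 child ids / visit counts / value sums
  std::vector<int> child, n_sa;
  std::vector<double> w_sa;
  std::vector<int> n_s;
  auto new_node = [&]() {
    int id = n_s.size();
    n_s.push_back(0);
    for (int a = 0; a < 6; ++a) { child.push_back(-1); n_sa.push_back(0); w_sa.push_back(0.0); }
    return id;
  };
  new_node(); // root = 0

  double ret_min = R_PosInf, ret_max = R_NegInf;

  auto legal_moves = [&](int cell, int* acts) {
    int k = 0;
    for (int a = 0; a < 6; ++a) if (nbr(cell - 1, a) > 0) acts[k++] = a;
    return k;
  };

  auto predator_step = [&](int& pcell) {
    int acts[6];
    int k = legal_moves(pcell, acts);
    if (k == 0) return;
    int a;
    if (opponent == 1) {
      a = acts[(int)(unif(rng) * k) % k];
    } else {
      double u = unif(rng), cum = 0.0;
      a = acts[k - 1];
      for (int i = 0; i < k; ++i) {
        cum += opp_policy(pcell - 1, acts[i]);
        if (u <= cum) { a = acts[i]; break; }
      }
    }
    pcell = nbr(pcell - 1, a);
  };

  std::vector<int> path_node, path_act;
  std::vector<bool> coin(coin0);

  for (int sim = 0; sim < n_sim; ++sim) {
    int pr = prey, pd = pred;
    coin = coin0;
    double ret = 0.0;
    bool done = false;
    path_node.clear(); path_act.clear();
    int node = 0;
    bool in_tree = true;

    for (int pos = 0; pos < depth_total && !done; ++pos) {
      if (schedule[pos] == 0) { // prey move
        int acts[6];
        int k = legal_moves(pr, acts);
        if (k == 0) break;
        int a;
        if (in_tree) {
          // pick among unvisited uniformly first, else UCT
          int unvisited[6], ku = 0;
          for (int i = 0; i < k; ++i)
            if (n_sa[node * 6 + acts[i]] == 0) unvisited[ku++] = acts[i];
          if (ku > 0) {
            a = unvisited[(int)(unif(rng) * ku) % ku];
          } else {
            double span = (ret_max > ret_min) ? (ret_max - ret_min) : 1.0;
            double best = -1e300;
            a = acts[0];
            for (int i = 0; i < k; ++i) {
              int ia = node * 6 + acts[i];
              double exploit = (w_sa[ia] / n_sa[ia] - ret_min) / span;
              double explore = c_uct * std::sqrt(std::log((double)n_s[node] + 1.0) / n_sa[ia]);
              double u = exploit + explore + 1e-9 * unif(rng);
              if (u > best) { best = u; a = acts[i]; }
            }
          }
          path_node.push_back(node); path_act.push_back(a);
          int ia = node * 6 + a;
          if (child[ia] < 0) {
            child[ia] = new_node();
            in_tree = false; // expanded a leaf: switch to rollout after this move
          }
          node = child[ia];
        } else {
          a = acts[(int)(unif(rng) * k) % k];
        }
        pr = nbr(pr - 1, a);
        if (coin[pr]) { coin[pr] = false; ret += 100.0; }
        if (opponent != 0 && capture_symmetric && pr == pd) {
          ret -= 1000.0 * theta; done = true;
        }
      } else { // predator move
        if (opponent == 0) continue;
        predator_step(pd);
        if (pd == pr) { ret -= 1000.0 * theta; done = true; }
      }
    }

    if (ret < ret_min) ret_min = ret;
    if (ret > ret_max) ret_max = ret;
    for (size_t i = 0; i < path_node.size(); ++i) {
      int ia = path_node[i] * 6 + path_act[i];
      n_sa[ia] += 1;
      w_sa[ia] += ret;
      n_s[path_node[i]] += 1;
    }
  }

  // choose the root action with the most visits (ties broken by the RNG)
  IntegerVector visits(6);
  NumericVector value(6, NA_REAL);
  int best = -1, best_n = -1, ties = 0;
  for (int a = 0; a < 6; ++a) {
    visits[a] = n_sa[a];
    if (n_sa[a] > 0) value[a] = w_sa[a] / n_sa[a];
    if (nbr(prey - 1, a) > 0) {
      if (n_sa[a] > best_n) { best_n = n_sa[a]; best = a; ties = 1; }
      else if (n_sa[a] == best_n && unif(rng) < 1.0 / ++ties) best = a;
    }
  }
  return List::create(_["action"] = best + 1, _["visits"] = visits,
                      _["value"] = value);
}
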