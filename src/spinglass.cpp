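#include <Rcpp.h>
using namespace Rcpp;

// Spin-glass (Potts-model) community detection on a positively weighted
// graph by Metropolis simulated annealing. Minimizes the configuration-null
// Hamiltonian
//   H(sigma) = - sum_{i<j} (a_ij - gamma * s_i s_j / (2m)) * delta(sigma_i, sigma_j)
// with a_ij >= 0, s_i = sum_j a_ij, m = sum a_ij / 2.
//
// Schedule: at each temperature, p * spins single-node label-change
// proposals, accepted with probability min(1, exp(-dH / T)); T is multiplied
// by `cooling` until it drops below `t_stop`. The best state ever visited is
// tracked and returned, over `nrestart` independent restarts. Uses R's RNG,
// so results are reproducible under set.seed().

static double hamiltonian_full(const NumericMatrix &A, const NumericVector &s,
                               double m, double gamma,
                               const std::vector<int> &lab) {
  int p = A.nrow();
  double H = 0.0;
  for (int i = 0; i < p; i++)
    for (int j = i + 1; j < p; j++)
      if (lab[i] == lab[j]) H -= A(i, j) - gamma * s[i] * s[j] / (2.0 * m);
  return H;
}

// [[Rcpp::export]]
List spinglass_anneal_cpp(NumericMatrix A, double gamma, int spins,
                          double t_start, double t_stop, double cooling,
                          int nrestart) {
  int p = A.nrow();
  NumericVector s(p);
  double total = 0.0;
  for (int i = 0; i < p; i++) {
    double si = 0.0;
    for (int j = 0; j < p; j++)
      if (j != i) si += A(i, j);
    s[i] = si;
    total += si;
  }
  double m = total / 2.0;
  if (m <= 0) stop("no community structure estimable: network has no edges");

  std::vector<int> best_lab(p);
  double best_H = R_PosInf;

  for (int rs = 0; rs < nrestart; rs++) {
    std::vector<int> lab(p);
    for (int i = 0; i < p; i++)
      lab[i] = (int)std::floor(unif_rand() * spins);
    double H = hamiltonian_full(A, s, m, gamma, lab);
    if (H < best_H) { best_H = H; best_lab = lab; }

    for (double T = t_start; T >= t_stop; T *= cooling) {
      int nprop = p * spins;
      for (int it = 0; it < nprop; it++) {
        int v = (int)std::floor(unif_rand() * p);
        int newlab = (int)std::floor(unif_rand() * spins);
        if (newlab == lab[v]) continue;
        double dH = 0.0;
        for (int u = 0; u < p; u++) {
          if (u == v) continue;
          double contrib = A(u, v) - gamma * s[u] * s[v] / (2.0 * m);
          if (lab[u] == newlab) dH -= contrib;
          if (lab[u] == lab[v]) dH += contrib;
        }
        if (dH <= 0.0 || unif_rand() < std::exp(-dH / T)) {
          lab[v] = newlab;
          H += dH;
          if (H < best_H) { best_H = H; best_lab = lab; }
        }
      }
    }
  }

  return List::create(_["labels"] = wrap(best_lab), _["H"] = best_H);
}

// Hamiltonian of a given labelling (exported for scoring / oracles).
// [[Rcpp::export]]
double spinglass_hamiltonian_cpp(NumericMatrix A, IntegerVector labels,
                                 double gamma) {
  int p = A.nrow();
  NumericVector s(p);
  double total = 0.0;
  for (int i = 0; i < p; i++) {
    double si = 0.0;
    for (int j = 0; j < p; j++)
      if (j != i) si += A(i, j);
    s[i] = si;
    total += si;
  }
  double m = total / 2.0;
  if (m <= 0) return 0.0;  // edgeless: every pair term vanishes
  double H = 0.0;
  for (int i = 0; i < p; i++)
    for (int j = i + 1; j < p; j++)
      if (labels[i] == labels[j])
        H -= A(i, j) - gamma * s[i] * s[j] / (2.0 * m);
  return H;
}
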