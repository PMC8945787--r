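#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Metropolis sampling of conformer microstates.  One sweep attempts one
// single-conformer flip per flexible fragment (fragment with >= 2
// conformers).  Occupancies are visit fractions over the sampling sweeps;
// the standard error comes from batch means.  Uses R's RNG so that
// set.seed() upstream makes runs bit-identical.
//
// u        : per-conformer self energy (kcal/mol) at this condition
// G        : M x M pairwise energies, same-fragment entries must be 0
// fragConfs: list of integer vectors, 0-based conformer ids per fragment
// [[Rcpp::export]]
List mc_run_cpp(NumericVector u, NumericMatrix G, List fragConfs,
                double kT, int burnin, int nsweep, int nbatch) {
  const int M = u.size();
  const int nf = fragConfs.size();
  std::vector<std::vector<int> > confs(nf);
  std::vector<int> flex;
  for (int f = 0; f < nf; f++) {
    IntegerVector cf = fragConfs[f];
    confs[f].assign(cf.begin(), cf.end());
    if (confs[f].size() > 1) flex.push_back(f);
  }
  std::vector<int> sel(nf);
  for (int f = 0; f < nf; f++) sel[f] = confs[f][0];

  const int nflex = (int)flex.size();
  long accepted = 0, attempted = 0;

  auto dE = [&](int f, int cnew) -> double {
    int cold = sel[f];
    double d = u[cnew] - u[cold];
    for (int g = 0; g < nf; g++) {
      if (g == f) continue;
      d += G(cnew, sel[g]) - G(cold, sel[g]);
    }
    return d;
  };
  auto attempt = [&](void) {
    if (nflex == 0) return;
    int f = flex[(int)(R::unif_rand() * nflex) % nflex];
    int nc = (int)confs[f].size();
    int pos = (int)(R::unif_rand() * (nc - 1)) % (nc - 1);
    // pick a conformer other than the current one
    int cur_pos = 0;
    for (int p = 0; p < nc; p++) if (confs[f][p] == sel[f]) { cur_pos = p; break; }
    if (pos >= cur_pos) pos++;
    int cnew = confs[f][pos];
    double d = dE(f, cnew);
    attempted++;
    if (d <= 0.0 || R::unif_rand() < std::exp(-d / kT)) {
      sel[f] = cnew;
      accepted++;
    }
  };

  for (int s = 0; s < burnin; s++)
    for (int m = 0; m < std::max(nflex, 1); m++) attempt();

  NumericMatrix batch(nbatch, M);
  std::fill(batch.begin(), batch.end(), 0.0);
  int per_batch = nsweep / nbatch;
  if (per_batch < 1) per_batch = 1;
  int total = per_batch * nbatch;
  for (int s = 0; s < total; s++) {
    for (int m = 0; m < std::max(nflex, 1); m++) attempt();
    int b = s / per_batch;
    for (int f = 0; f < nf; f++) batch(b, sel[f]) += 1.0;
  }
  NumericVector occ(M), se(M);
  for (int c = 0; c < M; c++) {
    double tot = 0.0;
    for (int b = 0; b < nbatch; b++) tot += batch(b, c);
    occ[c] = tot / total;
    double meanb = occ[c];
    double ss = 0.0;
    for (int b = 0; b < nbatch; b++) {
      double x = batch(b, c) / per_batch - meanb;
      ss += x * x;
    }
    se[c] = nbatch > 1 ? std::sqrt(ss / (nbatch - 1) / nbatch) : 0.0;
  }
  double acc = attempted > 0 ? (double)accepted / (double)attempted : 1.0;
  return List::create(_["occupancy"] = occ, _["mc_error"] = se,
                      _["acceptance"] = acc, _["sweeps"] = total);
}
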