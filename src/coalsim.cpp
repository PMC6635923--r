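// Coalescent simulation of unlinked microsatellite loci on a
// three-population divergence history with stepwise (or generalized
// stepwise) mutation. Time runs backwards in generations (continuous);
// a population of diploid size N coalesces pairs at rate 1/(2N).
//
// Epochs: [0, t1) -> sizes column 0; [t1, t2) -> column 1; [t2, inf)
// -> column 2. At t1 lineage merge1[0] merges into merge1[1]; at t2
// merge2[0] into merge2[1]. Alleles are net step offsets from the
// ancestral state, reflected at +/- maxStep repeats.

#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Sim {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};

  explicit Sim(uint64_t seed) : eng(seed) {}

  double rexp(double rate) {
    std::exponential_distribution<double> d(rate);
    return d(eng);
  }
  int rpois(double lambda) {
    std::poisson_distribution<int> d(lambda);
    return d(eng);
  }
  int runifInt(int n) {  // 0..n-1
    std::uniform_int_distribution<int> d(0, n - 1);
    return d(eng);
  }
};

}  // namespace

// [[Rcpp::export(name = ".sim_msat_cpp")]]
IntegerMatrix sim_msat_cpp(double t1, double t2, NumericMatrix sizes,
                           IntegerVector merge1, IntegerVector merge2,
                           IntegerVector nCopies, double mu, int nLoci,
                           double seed, int maxStep, double gsmP) {
  const int ntot = nCopies[0] + nCopies[1] + nCopies[2];
  if (ntot < 2) stop("need at least 2 sampled gene copies");
  IntegerMatrix out(ntot, nLoci);
  Sim sim(static_cast<uint64_t>(seed));

  const int nNodes = 2 * ntot - 1;
  std::vector<int> parent(nNodes);
  std::vector<double> ntime(nNodes);
  std::vector<int> allele(nNodes);

  for (int locus = 0; locus < nLoci; ++locus) {
    std::vector<std::vector<int> > act(3);
    int leaf = 0;
    for (int p = 0; p < 3; ++p) {
      for (int c = 0; c < nCopies[p]; ++c) {
        act[p].push_back(leaf);
        ntime[leaf] = 0.0;
        ++leaf;
      }
    }
    int nextNode = ntot;
    double t = 0.0;
    const double bounds[3] = {t1, t2, R_PosInf};
    for (int epoch = 0; epoch < 3; ++epoch) {
      const double thi = bounds[epoch];
      while (true) {
        double rate[3], total = 0.0;
        for (int p = 0; p < 3; ++p) {
          const double N = sizes(p, epoch);
          const int k = static_cast<int>(act[p].size());
          rate[p] = (k >= 2 && N > 0) ? k * (k - 1) / 2.0 / (2.0 * N)
                                      : 0.0;
          total += rate[p];
        }
        if (total <= 0.0) { t = thi; break; }
        const double dt = sim.rexp(total);
        if (t + dt >= thi) { t = thi; break; }
        t += dt;
        double u = sim.unif(sim.eng) * total;
        int p = 0;
        while (p < 2 && u > rate[p]) { u -= rate[p]; ++p; }
        std::vector<int>& a = act[p];
        const int k = static_cast<int>(a.size());
        const int i = sim.runifInt(k);
        int j = sim.runifInt(k - 1);
        if (j >= i) ++j;
        const int node = nextNode++;
        ntime[node] = t;
        parent[a[i]] = node;
        parent[a[j]] = node;
        a[i] = node;
        a.erase(a.begin() + j);
        if (nextNode == nNodes) break;
      }
      if (nextNode == nNodes) break;
      if (epoch == 0) {  // merge at t1
        std::vector<int>& src = act[merge1[0] - 1];
        std::vector<int>& dst = act[merge1[1] - 1];
        dst.insert(dst.end(), src.begin(), src.end());
        src.clear();
      } else if (epoch == 1) {  // merge at t2
        std::vector<int>& src = act[merge2[0] - 1];
        std::vector<int>& dst = act[merge2[1] - 1];
        dst.insert(dst.end(), src.begin(), src.end());
        src.clear();
      }
    }
    // mutations: parents always have larger ids than children
    allele[nNodes - 1] = 0;
    for (int i = nNodes - 2; i >= 0; --i) {
      const double len = ntime[parent[i]] - ntime[i];
      int m = (mu > 0 && len > 0) ? sim.rpois(mu * len) : 0;
      int a = allele[parent[i]];
      for (int s = 0; s < m; ++s) {
        int size = 1;
        if (gsmP > 0) {
          // geometric step size: P(size = k) = (1 - p) p^(k-1)
          while (sim.unif(sim.eng) < gsmP) ++size;
        }
        const int dir = (sim.unif(sim.eng) < 0.5) ? -1 : 1;
        a += dir * size;
        while (a > maxStep || a < -maxStep) {
          if (a > maxStep) a = 2 * maxStep - a;
          if (a < -maxStep) a = -2 * maxStep - a;
        }
      }
      allele[i] = a;
    }
    for (int c = 0; c < ntot; ++c) out(c, locus) = allele[c];
  }
  return out;
}
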