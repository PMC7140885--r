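#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Forward Wright-Fisher evolution of a haplotype pool with recombination.
//
// haps: L x 2N integer matrix of 0/1 alleles, one haplotype per column,
//       consecutive column pairs forming diploid individuals.
// ne_path: diploid population size of each generation to simulate.
// rec: L-1 per-interval recombination probabilities per meiosis.
//
// mu: per-locus symmetric allele-flip probability per transmitted gamete
//     (0 for pure drift).
//
// Random mating with random union of gametes (selfing allowed). Uses R's
// RNG, so set.seed() in R makes runs reproducible. When all intervals share
// one recombination probability, the per-gamete crossover count is drawn
// binomially and placed uniformly (exact and fast for the sparse maps used
// here); otherwise each interval is visited.
// [[Rcpp::export]]
IntegerMatrix wf_evolve(IntegerMatrix haps, IntegerVector ne_path,
                        NumericVector rec, double mu = 0.0) {
  const int L = haps.nrow();
  if (rec.size() != L - 1)
    stop("rec must have length nloci - 1");
  if (haps.ncol() < 2 || haps.ncol() % 2 != 0)
    stop("haplotype pool must hold an even number of haplotypes");

  bool uniform = true;
  for (int i = 1; i < rec.size(); ++i)
    if (rec[i] != rec[0]) { uniform = false; break; }
  const double r0 = (L > 1) ? rec[0] : 0.0;

  IntegerMatrix cur = clone(haps);
  int n_prev = cur.ncol() / 2;
  std::vector<int> cross;

  for (int g = 0; g < ne_path.size(); ++g) {
    const int n_new = ne_path[g];
    if (n_new < 1) stop("population size must be >= 1 in every generation");
    IntegerMatrix nxt(L, 2 * n_new);
    for (int k = 0; k < 2 * n_new; ++k) {
      const int parent = (int)(unif_rand() * n_prev) % n_prev;
      const int h = (unif_rand() < 0.5) ? 0 : 1;
      const int ca = 2 * parent + h, cb = 2 * parent + 1 - h;

      cross.clear();
      if (L > 1) {
        if (uniform) {
          const int nx = (int)R::rbinom(L - 1, r0);
          while ((int)cross.size() < nx) {
            int pos = (int)(unif_rand() * (L - 1)) % (L - 1);
            bool dup = false;
            for (size_t t = 0; t < cross.size(); ++t)
              if (cross[t] == pos) { dup = true; break; }
            if (!dup) cross.push_back(pos);
          }
          std::sort(cross.begin(), cross.end());
        } else {
          for (int i = 0; i < L - 1; ++i)
            if (unif_rand() < rec[i]) cross.push_back(i);
        }
      }

      int* out = &nxt(0, k);
      if (cross.empty()) {
        std::memcpy(out, &cur(0, ca), L * sizeof(int));
      } else {
        int src = ca;
        size_t cx = 0;
        for (int l = 0; l < L; ++l) {
          if (cx < cross.size() && l > 0 && cross[cx] == l - 1) {
            src = (src == ca) ? cb : ca;
            ++cx;
          }
          out[l] = cur(l, src);
        }
      }
      if (mu > 0.0) {
        const int nm = (int)R::rbinom(L, mu);
        for (int t = 0; t < nm; ++t) {
          const int pos = (int)(unif_rand() * L) % L;
          out[pos] = 1 - out[pos];
        }
      }
    }
    cur = nxt;
    n_prev = n_new;
  }
  return cur;
}
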