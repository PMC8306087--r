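#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Drift phase of one subline: constant-size random mating within the
// line for a given number of generations.  Meioses sample crossovers as
// a Poisson process on the physical map (Haldane, no interference),
// matching the R-level meiosis() used for small pedigrees.  Uses R's
// RNG, so results are reproducible under set.seed().
//
// Haplotypes are held transposed (m x 2n, one column per haplotype) so
// that a crossover-free transmission is a contiguous copy.
//
// fhaps: 2n x m founder haplotype matrix (0/1); returns the 2n x m
// haplotypes of the final generation.
// [[Rcpp::export(name = ".drift_line_cpp")]]
IntegerMatrix drift_line_cpp(int n, int gens, IntegerMatrix fhaps,
                             NumericVector positions, double morgans,
                             double length_bp) {
  const int m = positions.size();
  const int nh = 2 * n;
  std::vector<int> cur((size_t) m * nh), nxt((size_t) m * nh);
  for (int h = 0; h < nh; ++h)
    for (int j = 0; j < m; ++j)
      cur[(size_t) h * m + j] = fhaps(h, j);
  const double *pos = REAL(positions);
  std::vector<double> xo;
  for (int g = 0; g < gens; ++g) {
    for (int i = 0; i < n; ++i) {
      int sire = (int)(unif_rand() * n);
      if (sire == n) --sire;
      int off = 1 + (int)(unif_rand() * (n - 1));
      if (off == n) --off;
      int dam = (sire + off) % n;
      for (int par = 0; par < 2; ++par) {
        const int p = (par == 0) ? sire : dam;
        int *out = &nxt[(size_t)(2 * i + par) * m];
        const int nx = (int) R::rpois(morgans);
        int h = (unif_rand() < 0.5) ? 0 : 1;
        const int *h0 = &cur[(size_t)(2 * p) * m];
        const int *h1 = &cur[(size_t)(2 * p + 1) * m];
        if (nx == 0) {
          std::memcpy(out, h == 0 ? h0 : h1, sizeof(int) * m);
        } else {
          xo.assign(nx, 0.0);
          for (int k = 0; k < nx; ++k)
            xo[k] = 1.0 + unif_rand() * (length_bp - 1.0);
          std::sort(xo.begin(), xo.end());
          int j0 = 0;
          for (int k = 0; k <= nx; ++k) {
            // SNPs in [j0, j1) lie before crossover k (or chromosome end)
            int j1 = (k == nx) ? m :
              (int)(std::lower_bound(pos + j0, pos + m, xo[k]) - pos);
            if (j1 > j0)
              std::memcpy(out + j0, (h == 0 ? h0 : h1) + j0,
                          sizeof(int) * (j1 - j0));
            j0 = j1;
            h ^= 1;
          }
        }
      }
    }
    cur.swap(nxt);
  }
  IntegerMatrix res(nh, m);
  for (int h = 0; h < nh; ++h)
    for (int j = 0; j < m; ++j)
      res(h, j) = cur[(size_t) h * m + j];
  return res;
}
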