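// Brute-force grid-search reference for the K=2 admixture likelihood on a
// tiny 4-sample instance.  Exhaustively scans ancestry proportions q_i and
// per-SNP component frequency pairs (pA, pB) on a regular grid and returns
// the maximum log-likelihood.  Used only to validate the EM optimizer on
// desk-size problems; it shares no code with the EM.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// log-likelihood contribution of one genotype g at mixture frequency f
static inline double cell_ll(int g, double f, double eps) {
  if (f < eps) f = eps;
  if (f > 1.0 - eps) f = 1.0 - eps;
  return g * std::log(f) + (2 - g) * std::log(1.0 - f);
}

// [[Rcpp::export(name = ".grid_loglik_max")]]
double grid_loglik_max(IntegerMatrix G, double step = 0.02,
                       double eps = 1e-6) {
  const int n = G.nrow(), m = G.ncol();
  if (n != 4) stop("grid oracle supports exactly 4 samples");
  const int nq = (int) std::lround(1.0 / step) + 1;
  const int npp = nq * nq;  // (pA, pB) pairs

  // lookup: L[g][q * npp + pp] for g in {0,1,2}; NA genotype contributes 0
  std::vector< std::vector<float> > L(4, std::vector<float>((size_t) nq * npp));
  for (int g = 0; g < 3; ++g) {
    for (int qi = 0; qi < nq; ++qi) {
      const double q = qi * step;
      size_t base = (size_t) qi * npp;
      for (int a = 0; a < nq; ++a) {
        const double pa = a * step;
        for (int b = 0; b < nq; ++b) {
          const double f = q * pa + (1.0 - q) * (b * step);
          L[g][base + (size_t) a * nq + b] = (float) cell_ll(g, f, eps);
        }
      }
    }
  }
  // L[3] stays zero for missing genotypes

  std::vector<int> gidx((size_t) n * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      gidx[(size_t) i * m + j] =
        IntegerMatrix::is_na(G(i, j)) ? 3 : G(i, j);

  // precompute partial sums for samples 3+4 over all (q3, q4)
  std::vector<float> B34((size_t) nq * nq * m * npp);
  for (int q3 = 0; q3 < nq; ++q3) {
    for (int q4 = 0; q4 < nq; ++q4) {
      size_t base = (((size_t) q3 * nq) + q4) * m * npp;
      for (int j = 0; j < m; ++j) {
        const float* l3 = &L[gidx[(size_t) 2 * m + j]][(size_t) q3 * npp];
        const float* l4 = &L[gidx[(size_t) 3 * m + j]][(size_t) q4 * npp];
        float* dst = &B34[base + (size_t) j * npp];
        for (int pp = 0; pp < npp; ++pp) dst[pp] = l3[pp] + l4[pp];
      }
    }
  }

  // component labels are exchangeable: (q -> 1-q, pA <-> pB) leaves the
  // likelihood unchanged, so restricting sample 1 to q1 <= 1/2 is exact
  const int q1_max = nq / 2;
  double best = -std::numeric_limits<double>::infinity();
  std::vector<float> A12((size_t) m * npp);
  for (int q1 = 0; q1 <= q1_max; ++q1) {
    for (int q2 = 0; q2 < nq; ++q2) {
      for (int j = 0; j < m; ++j) {
        const float* l1 = &L[gidx[j]][(size_t) q1 * npp];
        const float* l2 = &L[gidx[(size_t) m + j]][(size_t) q2 * npp];
        float* dst = &A12[(size_t) j * npp];
        for (int pp = 0; pp < npp; ++pp) dst[pp] = l1[pp] + l2[pp];
      }
      for (int q3 = 0; q3 < nq; ++q3) {
        for (int q4 = 0; q4 < nq; ++q4) {
          size_t base = (((size_t) q3 * nq) + q4) * m * npp;
          double total = 0.0;
          for (int j = 0; j < m; ++j) {
            const float* a = &A12[(size_t) j * npp];
            const float* b = &B34[base + (size_t) j * npp];
            float mx = -std::numeric_limits<float>::infinity();
            for (int pp = 0; pp < npp; ++pp) {
              const float v = a[pp] + b[pp];
              if (v > mx) mx = v;
            }
            total += mx;
          }
          if (total > best) best = total;
        }
      }
    }
  }
  return best;
}
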