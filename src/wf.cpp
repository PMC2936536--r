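// Forward-time Wright-Fisher core: evolves a pool of haplotypes
// (markers x 2N integer matrix, haplotype pair 2i, 2i+1 = individual i)
// for a number of discrete generations with crossover recombination and
// optional additive selection at one focal marker. Uses R's RNG, so runs
// are reproducible under set.seed().
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline int weighted_pick(const std::vector<double>& cumw) {
  double u = unif_rand() * cumw.back();
  int i = std::upper_bound(cumw.begin(), cumw.end(), u) - cumw.begin();
  if (i >= (int)cumw.size()) i = cumw.size() - 1;
  return i;
}

// [[Rcpp::export]]
List wf_evolve_cpp(IntegerMatrix H0, int gens, double cx_mean,
                   NumericVector pos, double len, double s, int focal) {
  const int L = H0.nrow(), M = H0.ncol();
  const int N = M / 2;
  IntegerMatrix A = clone(H0), B(L, M);
  bool lost = false;
  const bool sel = (s > 0.0 && focal >= 0);
  std::vector<double> cumw(N);
  std::vector<double> cx;
  for (int g = 0; g < gens; ++g) {
    if (sel) {
      long tot = 0;
      double acc = 0.0;
      for (int i = 0; i < N; ++i) {
        int dos = A(focal, 2 * i) + A(focal, 2 * i + 1);
        tot += dos;
        acc += 1.0 + s * dos;
        cumw[i] = acc;
      }
      if (tot == 0) { lost = true; break; }
    }
    for (int c = 0; c < N; ++c) {
      for (int gam = 0; gam < 2; ++gam) {
        int parent = sel ? weighted_pick(cumw) : (int)(unif_rand() * N);
        if (parent >= N) parent = N - 1;
        int lead = (unif_rand() < 0.5) ? 0 : 1;
        int k = (int)R::rpois(cx_mean);
        int* dst = &B(0, 2 * c + gam);
        if (k == 0) {
          const int* src = &A(0, 2 * parent + lead);
          std::copy(src, src + L, dst);
        } else {
          cx.resize(k);
          for (int t = 0; t < k; ++t) cx[t] = unif_rand() * len;
          std::sort(cx.begin(), cx.end());
          const int* h0 = &A(0, 2 * parent + lead);
          const int* h1 = &A(0, 2 * parent + (1 - lead));
          int t = 0;
          for (int j = 0; j < L; ++j) {
            while (t < k && cx[t] < pos[j]) ++t;
            dst[j] = (t % 2 == 0) ? h0[j] : h1[j];
          }
        }
      }
    }
    std::swap(A, B);
  }
  if (sel && !lost) {
    long tot = 0;
    for (int i = 0; i < M; ++i) tot += A(focal, i);
    lost = (tot == 0);
  }
  return List::create(_["H"] = A, _["lost"] = lost);
}
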