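// Monte-Carlo two-locus coalescent sampler used to build likelihood lookup
// tables. For each rho-grid value, simulates `reps` two-locus ancestral
// histories for n haplotypes under a piecewise-constant demography, drops a
// single mutation per locus uniformly over the marginal tree (the low-theta
// conditional on both loci being biallelic), and returns the haplotype count
// configuration (n00, n01, n10, n11) per replicate.
//
// Conventions: diploid sizes, coalescence rate k(k-1)/2 / (2N(t)) per
// generation; rho = 4 * n_ref * r_gen where r_gen is the per-generation
// recombination probability between the two loci and n_ref the present-day
// (first-epoch) diploid size.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int popcount32(unsigned int x) {
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
}

// [[Rcpp::export]]
IntegerMatrix cpp_two_locus_configs(int n, NumericVector rho, int reps,
                                    NumericVector sizes, NumericVector times,
                                    double n_ref) {
  if (n < 2 || n > 30) stop("n must be in [2, 30]");
  const int G = rho.size();
  const int nep = sizes.size();
  const unsigned int full = (n == 32) ? 0xffffffffu : ((1u << n) - 1u);
  IntegerMatrix out(G * reps, 5);

  std::vector<unsigned int> A(2 * n), B(2 * n);

  int row = 0;
  for (int g = 0; g < G; ++g) {
    const double r_gen = rho[g] / (4.0 * n_ref);
    for (int rep = 0; rep < reps; ++rep) {
      int k = n;
      for (int i = 0; i < n; ++i) { A[i] = (1u << i); B[i] = (1u << i); }
      bool doneA = false, doneB = false;
      double lenA = 0.0, lenB = 0.0;
      unsigned int sampA = 0u, sampB = 0u;
      double t = 0.0;
      int ep = 0;

      while (!(doneA && doneB)) {
        while (ep + 1 < nep && t >= times[ep + 1]) ++ep;
        int kA = 0, kB = 0, kBoth = 0;
        for (int i = 0; i < k; ++i) {
          if (A[i]) ++kA;
          if (B[i]) ++kB;
          if (A[i] && B[i]) ++kBoth;
        }
        const double N = sizes[ep];
        const double coal = k * (k - 1) / 2.0 / (2.0 * N);
        const double rec = kBoth * r_gen;
        const double rate = coal + rec;
        if (rate <= 0.0) stop("degenerate two-locus state (zero event rate)");
        double dt = R::exp_rand() / rate;
        bool boundary = false;
        if (ep + 1 < nep && t + dt > times[ep + 1]) {
          dt = times[ep + 1] - t;
          boundary = true;
        }
        // reservoir sampling of a uniform point on each marginal tree
        if (!doneA && kA > 0) {
          lenA += kA * dt;
          if (unif_rand() < kA * dt / lenA) {
            int pick = (int)(unif_rand() * kA);
            for (int i = 0; i < k; ++i) {
              if (A[i]) { if (pick-- == 0) { sampA = A[i]; break; } }
            }
          }
        }
        if (!doneB && kB > 0) {
          lenB += kB * dt;
          if (unif_rand() < kB * dt / lenB) {
            int pick = (int)(unif_rand() * kB);
            for (int i = 0; i < k; ++i) {
              if (B[i]) { if (pick-- == 0) { sampB = B[i]; break; } }
            }
          }
        }
        t += dt;
        if (boundary) { ++ep; continue; }

        if (unif_rand() * rate < rec) {
          // recombination: split a random both-carrying lineage
          int pick = (int)(unif_rand() * kBoth);
          for (int i = 0; i < k; ++i) {
            if (A[i] && B[i]) {
              if (pick-- == 0) {
                B[k] = B[i]; A[k] = 0u;  // new B-only lineage
                B[i] = 0u;               // old lineage keeps A only
                ++k;
                break;
              }
            }
          }
        } else {
          // coalescence of a random pair; merge into the lower slot
          int i = (int)(unif_rand() * k);
          int j = (int)(unif_rand() * (k - 1));
          if (j >= i) ++j;
          const int lo = i < j ? i : j, hi = i < j ? j : i;
          unsigned int a = A[lo] | A[hi], b = B[lo] | B[hi];
          if (a == full) { doneA = true; a = 0u; }
          if (b == full) { doneB = true; b = 0u; }
          A[lo] = a; B[lo] = b;
          A[hi] = A[k - 1]; B[hi] = B[k - 1];
          --k;
          if (A[lo] == 0u && B[lo] == 0u) {
            // merged lineage ancestral to nothing: drop it
            A[lo] = A[k - 1]; B[lo] = B[k - 1];
            --k;
          }
          if (k < 1) break;
        }
      }

      const int n11 = popcount32(sampA & sampB);
      const int n1A = popcount32(sampA);
      const int n1B = popcount32(sampB);
      out(row, 0) = g + 1;
      out(row, 1) = n - n1A - n1B + n11;  // n00
      out(row, 2) = n1B - n11;            // n01
      out(row, 3) = n1A - n11;            // n10
      out(row, 4) = n11;
      ++row;
    }
  }
  return out;
}
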