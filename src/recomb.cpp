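#include <Rcpp.h>
using namespace Rcpp;

// Marginal frequency of the pattern of x on markers u..v (1-based):
// sum of f over support haplotypes that agree with x on those bits.
static inline double marg(int x, int u, int v,
                          const IntegerVector& support,
                          const NumericVector& f) {
  const int mask = (((1 << (v - u + 1)) - 1) << (u - 1));
  const int pat = x & mask;
  double s = 0.0;
  const int H = support.size();
  for (int h = 0; h < H; ++h) {
    if ((support[h] & mask) == pat) s += f[h];
  }
  return s;
}

// Likelihood of a recombinant haplotype x: sum over the 2^L ancestry states
// z of f(x|z) * Q(z|d,r). Computed by dynamic programming over the maximal
// constant-ancestry segments of z: S(v,p) accumulates all segmentations of
// markers 1..v whose last segment ends at v in population p; each segment
// [u,v] contributes the product of no-change probabilities on its internal
// intervals times the population-p marginal frequency of x on [u,v], and a
// change probability at its left boundary. Exactly equal to the explicit
// 2^L enumeration.
static double recomb_lik_one(int x, int L,
                             const IntegerVector& support,
                             const NumericVector& fA,
                             const NumericVector& fB,
                             const NumericVector& P) {
  // P[j] (0-based, length L-1) = ancestry change probability on the
  // interval between markers j+1 and j+2 (1-based).
  std::vector<double> S0(L + 1, 0.0), S1(L + 1, 0.0);
  for (int v = 1; v <= L; ++v) {
    double s0 = 0.0, s1 = 0.0, keep = 1.0;
    for (int u = v; u >= 1; --u) {
      const double mA = marg(x, u, v, support, fA);
      const double mB = marg(x, u, v, support, fB);
      if (u == 1) {
        s0 += keep * mA;
        s1 += keep * mB;
      } else {
        const double pchg = P[u - 2];
        s0 += keep * mA * pchg * S1[u - 1];
        s1 += keep * mB * pchg * S0[u - 1];
        keep *= (1.0 - P[u - 2]);
      }
    }
    S0[v] = s0;
    S1[v] = s1;
  }
  return 0.5 * (S0[L] + S1[L]);
}

// [[Rcpp::export(name = ".recombLikBatch")]]
NumericVector recomb_lik_batch(IntegerVector xs, int L,
                               IntegerVector support,
                               NumericVector fA, NumericVector fB,
                               NumericVector P) {
  if (L < 1) stop("L must be at least 1");
  if (P.size() != L - 1) stop("need one change probability per interval");
  if (fA.size() != support.size() || fB.size() != support.size())
    stop("frequency vectors must match the support");
  const int n = xs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = recomb_lik_one(xs[i], L, support, fA, fB, P);
  }
  return out;
}

// [[Rcpp::export(name = ".segProbBatch")]]
NumericVector seg_prob_batch(IntegerVector xs, IntegerVector zs, int L,
                             IntegerVector support,
                             NumericVector fA, NumericVector fB) {
  // f(x|z): product over maximal constant segments of z of the matching
  // population's marginal frequency of x on the segment.
  const int n = xs.size();
  if (zs.size() != n) stop("xs and zs must have equal length");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const int x = xs[i], z = zs[i];
    double p = 1.0;
    int u = 1;
    int cur = z & 1;
    for (int j = 2; j <= L; ++j) {
      const int b = (z >> (j - 1)) & 1;
      if (b != cur) {
        p *= marg(x, u, j - 1, support, cur == 0 ? fA : fB);
        u = j;
        cur = b;
      }
    }
    p *= marg(x, u, L, support, cur == 0 ? fA : fB);
    out[i] = p;
  }
  return out;
}
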