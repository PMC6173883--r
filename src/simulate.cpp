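// Forward-time recurrence core for independent haploid SNPs on a deme grid.
// Per generation and occupied deme: (1) migration as a truncated, discretized
// Gaussian kernel average over occupied source demes, (2) haploid selection
// p' = p(1+s_d) / (1 + p s_d) with s_d = s * surface, (3) binomial drift with
// K haploids (skipped when K <= 0, the deterministic mode).
// Expansion demographies are encoded by occ_gen: the generation at which each
// deme becomes occupied (0 = occupied from the start); newly colonized demes
// are founded by the kernel-weighted average of previously occupied demes.

#include <Rcpp.h>
using namespace Rcpp;

// Binomial draw from R's RNG stream; inversion with mirroring for small K,
// falling back to R::rbinom for large K.
static inline int draw_binom(int K, double p) {
  if (p <= 0.0) return 0;
  if (p >= 1.0) return K;
  if (K > 64) return (int) R::rbinom((double) K, p);
  bool flip = p > 0.5;
  double pp = flip ? 1.0 - p : p;
  double q = 1.0 - pp;
  double pr = std::pow(q, K);
  double u = unif_rand();
  double cum = pr;
  int x = 0;
  double ratio = pp / q;
  while (u > cum && x < K) {
    pr *= ratio * (double)(K - x) / (double)(x + 1);
    ++x;
    cum += pr;
  }
  return flip ? K - x : x;
}

static inline int wrap(int x, int n) {
  x %= n;
  return x < 0 ? x + n : x;
}

static inline int reflect(int x, int n) {
  // mirror about the edges, repeatedly: a single bounce is not enough when
  // the kernel radius exceeds the grid extent
  while (x < 0 || x >= n) {
    if (x < 0) x = -x - 1;
    if (x >= n) x = 2 * n - 1 - x;
  }
  return x;
}

// [[Rcpp::export]]
NumericMatrix cpp_run_landscape(NumericMatrix freq,   // loci x demes
                                IntegerVector occ_gen, // per deme
                                int width, int height,
                                IntegerVector kdx, IntegerVector kdy,
                                NumericVector kw,
                                bool torus,
                                NumericVector s,       // per locus
                                NumericVector surface, // per deme
                                int K,                 // <= 0: deterministic
                                int generations) {
  const int L = freq.nrow();
  const int D = freq.ncol();
  if (D != width * height) stop("freq columns must equal width * height");
  const int nk = kdx.size();

  NumericMatrix cur = clone(freq);
  NumericMatrix nxt(L, D);

  std::vector<int> src_idx(nk);
  std::vector<double> src_w(nk);

  for (int t = 1; t <= generations; ++t) {
    // --- migration (and colonization of newly occupied demes)
    for (int d = 0; d < D; ++d) {
      if (occ_gen[d] > t) {  // not yet occupied: carries no frequency
        for (int l = 0; l < L; ++l) nxt(l, d) = NA_REAL;
        continue;
      }
      int x = d % width, y = d / width;
      int m = 0;
      double wsum = 0.0;
      for (int k = 0; k < nk; ++k) {
        int sx = x + kdx[k], sy = y + kdy[k];
        if (torus) { sx = wrap(sx, width); sy = wrap(sy, height); }
        else       { sx = reflect(sx, width); sy = reflect(sy, height); }
        int sd = sy * width + sx;
        if (occ_gen[sd] >= t) continue;  // source must be occupied last gen
        src_idx[m] = sd;
        src_w[m] = kw[k];
        wsum += kw[k];
        ++m;
      }
      if (m == 0 || wsum <= 0.0) {
        // isolated newly founded deme: impossible under ring expansion with
        // kernel radius >= 1, but keep previous state defensively
        for (int l = 0; l < L; ++l)
          nxt(l, d) = occ_gen[d] < t ? cur(l, d) : NA_REAL;
        continue;
      }
      double *out = &nxt(0, d);
      for (int l = 0; l < L; ++l) out[l] = 0.0;
      for (int k = 0; k < m; ++k) {
        const double w = src_w[k] / wsum;
        const double *in = &cur(0, src_idx[k]);
        for (int l = 0; l < L; ++l) out[l] += w * in[l];
      }
    }
    // --- selection and drift
    for (int d = 0; d < D; ++d) {
      if (occ_gen[d] > t) continue;
      const double sv = surface[d];
      double *col = &nxt(0, d);
      for (int l = 0; l < L; ++l) {
        double p = col[l];
        if (!R_finite(p)) stop("non-finite frequency at generation %d", t);
        if (s[l] != 0.0) {
          const double sd_ = s[l] * sv;
          p = p * (1.0 + sd_) / (1.0 + p * sd_);
        }
        if (K > 0) p = (double) draw_binom(K, p) / (double) K;
        if (p < 0.0) p = 0.0; else if (p > 1.0) p = 1.0;
        col[l] = p;
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}
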