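// Core gene-dropping engine: meiosis with Poisson-distributed crossovers on a
// continuous cM map, generation advance for the historical population
// (recurrent symmetric mutation), and mating of arbitrary parent pairs.
//
// Haplotypes are stored as a raw matrix with loci in rows and haplotypes in
// columns; individual i (0-based) owns columns 2i and 2i+1. Loci are grouped
// by chromosome (chromStart gives 0-based offsets, length nChrom + 1) and
// sorted by map position within chromosome. All randomness comes from R's
// RNG so that set.seed() makes every run reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

namespace {

// Copy one recombinant gamete of the parent haplotypes h0/h1 into out.
void sample_gamete(const Rbyte* h0, const Rbyte* h1, Rbyte* out,
                   const int* chromStart, int nChrom,
                   const double* pos, double chromLen) {
  for (int c = 0; c < nChrom; ++c) {
    const int s = chromStart[c];
    const int e = chromStart[c + 1];
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    const int k = static_cast<int>(R::rpois(1.0));
    if (k == 0) {
      std::memcpy(out + s, cur == 0 ? h0 + s : h1 + s, e - s);
      continue;
    }
    std::vector<double> cx(k);
    for (int i = 0; i < k; ++i) cx[i] = unif_rand() * chromLen;
    std::sort(cx.begin(), cx.end());
    int idx = s;
    for (int i = 0; i < k && idx < e; ++i) {
      const double* brk = std::upper_bound(pos + idx, pos + e, cx[i]);
      const int j = static_cast<int>(brk - pos);
      if (j > idx)
        std::memcpy(out + idx, cur == 0 ? h0 + idx : h1 + idx, j - idx);
      cur = 1 - cur;
      idx = j;
    }
    if (idx < e)
      std::memcpy(out + idx, cur == 0 ? h0 + idx : h1 + idx, e - idx);
  }
}

// Symmetric allele flips at rate mu per locus on one gamete.
void mutate_gamete(Rbyte* g, int nLoci, double mu) {
  const int nMut = static_cast<int>(R::rbinom(static_cast<double>(nLoci), mu));
  for (int i = 0; i < nMut; ++i) {
    int j = static_cast<int>(unif_rand() * nLoci);
    if (j >= nLoci) j = nLoci - 1;
    g[j] = 1 - g[j];
  }
}

}  // namespace

// Advance a population through successive generations of random mating with
// replacement (monoecious, selfing possible), applying recurrent mutation to
// every transmitted gamete. sizes[g] is the population size of generation
// g + 1; the returned matrix holds the final generation.
// [[Rcpp::export]]
RawMatrix cpp_drop_generations(RawMatrix founders, IntegerVector sizes,
                               IntegerVector chromStart, NumericVector pos,
                               double chromLen, double mu) {
  const int nLoci = founders.nrow();
  const int nChrom = chromStart.size() - 1;
  RNGScope scope;

  int maxN = founders.ncol() / 2;
  for (int g = 0; g < sizes.size(); ++g)
    if (sizes[g] > maxN) maxN = sizes[g];

  std::vector<Rbyte> cur(founders.begin(), founders.end());
  int nCur = founders.ncol() / 2;
  std::vector<Rbyte> nxt(static_cast<size_t>(nLoci) * 2 * maxN);

  for (int g = 0; g < sizes.size(); ++g) {
    const int n = sizes[g];
    if (n < 1) stop("population size must be positive (generation %d)", g + 1);
    for (int i = 0; i < n; ++i) {
      const int mo = static_cast<int>(unif_rand() * nCur) % nCur;
      const int fa = static_cast<int>(unif_rand() * nCur) % nCur;
      Rbyte* g0 = nxt.data() + static_cast<size_t>(nLoci) * (2 * i);
      Rbyte* g1 = g0 + nLoci;
      sample_gamete(cur.data() + static_cast<size_t>(nLoci) * (2 * mo),
                    cur.data() + static_cast<size_t>(nLoci) * (2 * mo + 1), g0,
                    chromStart.begin(), nChrom, pos.begin(), chromLen);
      sample_gamete(cur.data() + static_cast<size_t>(nLoci) * (2 * fa),
                    cur.data() + static_cast<size_t>(nLoci) * (2 * fa + 1), g1,
                    chromStart.begin(), nChrom, pos.begin(), chromLen);
      if (mu > 0) {
        mutate_gamete(g0, nLoci, mu);
        mutate_gamete(g1, nLoci, mu);
      }
    }
    cur.swap(nxt);
    nCur = n;
  }

  RawMatrix out(nLoci, 2 * nCur);
  std::memcpy(out.begin(), cur.data(), static_cast<size_t>(nLoci) * 2 * nCur);
  return out;
}

// Offspring of explicit parent pairs (0-based individual indices), one
// gamete from each parent, no mutation (breeding phase).
// [[Rcpp::export]]
RawMatrix cpp_mate(RawMatrix haplo, IntegerVector mothers,
                   IntegerVector fathers, IntegerVector chromStart,
                   NumericVector pos, double chromLen) {
  const int nLoci = haplo.nrow();
  const int nChrom = chromStart.size() - 1;
  const int nPar = haplo.ncol() / 2;
  const int n = mothers.size();
  if (fathers.size() != n) stop("mothers and fathers differ in length");
  RNGScope scope;

  RawMatrix out(nLoci, 2 * n);
  const Rbyte* H = haplo.begin();
  for (int i = 0; i < n; ++i) {
    const int mo = mothers[i], fa = fathers[i];
    if (mo < 0 || mo >= nPar || fa < 0 || fa >= nPar)
      stop("parent index out of range");
    sample_gamete(H + static_cast<size_t>(nLoci) * (2 * mo),
                  H + static_cast<size_t>(nLoci) * (2 * mo + 1),
                  out.begin() + static_cast<size_t>(nLoci) * (2 * i),
                  chromStart.begin(), nChrom, pos.begin(), chromLen);
    sample_gamete(H + static_cast<size_t>(nLoci) * (2 * fa),
                  H + static_cast<size_t>(nLoci) * (2 * fa + 1),
                  out.begin() + static_cast<size_t>(nLoci) * (2 * i + 1),
                  chromStart.begin(), nChrom, pos.begin(), chromLen);
  }
  return out;
}

// One gamete from one individual; exposed for unit-level meiosis.
// [[Rcpp::export]]
RawVector cpp_gamete(RawMatrix haplo, int individual, IntegerVector chromStart,
                     NumericVector pos, double chromLen) {
  const int nLoci = haplo.nrow();
  const int nPar = haplo.ncol() / 2;
  if (individual < 0 || individual >= nPar) stop("individual out of range");
  RNGScope scope;
  RawVector out(nLoci);
  sample_gamete(haplo.begin() + static_cast<size_t>(nLoci) * (2 * individual),
                haplo.begin() + static_cast<size_t>(nLoci) * (2 * individual + 1),
                out.begin(), chromStart.begin(), chromStart.size() - 1,
                pos.begin(), chromLen);
  return out;
}

// Genotype dosage (0/1/2) matrix, individuals in rows.
// [[Rcpp::export]]
IntegerMatrix cpp_dosage(RawMatrix haplo) {
  const int nLoci = haplo.nrow();
  const int n = haplo.ncol() / 2;
  IntegerMatrix out(n, nLoci);
  const Rbyte* H = haplo.begin();
  for (int i = 0; i < n; ++i) {
    const Rbyte* h0 = H + static_cast<size_t>(nLoci) * (2 * i);
    const Rbyte* h1 = h0 + nLoci;
    for (int j = 0; j < nLoci; ++j) out(i, j) = h0[j] + h1[j];
  }
  return out;
}

// Per-locus frequency of the "1" allele across all haplotypes.
// [[Rcpp::export]]
NumericVector cpp_allele_freq(RawMatrix haplo) {
  const int nLoci = haplo.nrow();
  const int nHap = haplo.ncol();
  NumericVector out(nLoci);
  const Rbyte* H = haplo.begin();
  for (int h = 0; h < nHap; ++h) {
    const Rbyte* col = H + static_cast<size_t>(nLoci) * h;
    for (int j = 0; j < nLoci; ++j) out[j] += col[j];
  }
  for (int j = 0; j < nLoci; ++j) out[j] /= nHap;
  return out;
}

// Proportion of heterozygous genotypes over individuals x loci.
// [[Rcpp::export]]
double cpp_het(RawMatrix haplo) {
  const int nLoci = haplo.nrow();
  const int n = haplo.ncol() / 2;
  double het = 0.0;
  const Rbyte* H = haplo.begin();
  for (int i = 0; i < n; ++i) {
    const Rbyte* h0 = H + static_cast<size_t>(nLoci) * (2 * i);
    const Rbyte* h1 = h0 + nLoci;
    for (int j = 0; j < nLoci; ++j) het += (h0[j] != h1[j]);
  }
  return het / (static_cast<double>(n) * nLoci);
}
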