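#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Haplotypes are bit-packed: a haploid genome of L biallelic sites is a
// column of W = ceil(L/32) unsigned 32-bit words (stored in an
// IntegerMatrix), bit s%32 of word s/32 holding the allele at site s. Bits
// at positions >= L are always zero. Mendelian gamete construction is then
// (A & mask) | (B & ~mask) with random mask words, and allele-sharing
// dissimilarities reduce to popcounts.

namespace {

// splitmix64 stream for Mendelian masks; seeded from R's RNG so that
// set.seed() governs everything.
struct MaskStream {
  uint64_t state;
  explicit MaskStream(uint64_t seed) : state(seed) {}
  inline uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
};

inline uint64_t seed_from_R() {
  uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t s = (hi << 32) ^ lo;
  return s ? s : 0x106689D45497FDB5ULL;
}

inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Parent {
  const uint32_t *hapA;
  const uint32_t *hapB;
  const uint32_t *ancA;
  const uint32_t *ancB;
  int anc_const; // -1: per-site ancestry; 0/1: constant source label
  int pid, gp1, gp2;
};

inline void make_gamete(uint32_t *out, const uint32_t *A, const uint32_t *B,
                        int W, MaskStream &rng) {
  int w = 0;
  while (w + 1 < W) {
    uint64_t m64 = rng.next();
    uint32_t m1 = (uint32_t)m64, m2 = (uint32_t)(m64 >> 32);
    out[w] = (A[w] & m1) | (B[w] & ~m1);
    out[w + 1] = (A[w + 1] & m2) | (B[w + 1] & ~m2);
    w += 2;
  }
  if (w < W) {
    uint32_t m = (uint32_t)rng.next();
    out[w] = (A[w] & m) | (B[w] & ~m);
  }
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix pack_columns_cpp(IntegerMatrix haps) {
  const int L = haps.nrow(), N = haps.ncol();
  const int W = (L + 31) / 32;
  IntegerMatrix out(W, N);
  for (int j = 0; j < N; ++j) {
    uint32_t *col = (uint32_t *)&out(0, j);
    const int *h = &haps(0, j);
    for (int s = 0; s < L; ++s) {
      if (h[s]) col[s >> 5] |= (1u << (s & 31));
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix unpack_columns_cpp(IntegerMatrix packed, IntegerVector idx,
                                 int L) {
  const int n = idx.size();
  IntegerMatrix out(L, n);
  for (int j = 0; j < n; ++j) {
    const uint32_t *col = (const uint32_t *)&packed(0, idx[j] - 1);
    int *o = &out(0, j);
    for (int s = 0; s < L; ++s) o[s] = (col[s >> 5] >> (s & 31)) & 1u;
  }
  return out;
}

// One Wright-Fisher generation of the admixed population (see R wrapper).
// Source parents pair two *different* reservoir gametes; admixed parents
// are drawn with replacement from the previous generation. Each offspring
// draws two parents with distinct individual ids (no selfing; pairs are
// returned to the pool after each draw) and receives one Mendelian gamete
// from each.
// [[Rcpp::export]]
List wf_generation_cpp(IntegerMatrix afr_res, IntegerMatrix eur_res, int L,
                       Nullable<IntegerMatrix> prevA_, Nullable<IntegerMatrix> prevB_,
                       Nullable<IntegerVector> prev_ids_,
                       Nullable<IntegerMatrix> prev_parents_,
                       int n_afr, int n_eur, int n_h,
                       int n_offspring, int id_start, bool track,
                       Nullable<IntegerMatrix> prev_ancA_,
                       Nullable<IntegerMatrix> prev_ancB_) {
  const int W = afr_res.nrow();
  const int R_afr = afr_res.ncol(), R_eur = eur_res.ncol();
  const int P = n_afr + n_eur + n_h;
  if (P < 2) stop("parental pool must contain at least 2 parents");
  if (n_afr > 0 && R_afr < 2) stop("African reservoir too small to pair gametes");
  if (n_eur > 0 && R_eur < 2) stop("European reservoir too small to pair gametes");

  IntegerMatrix prevA, prevB, prev_parents, prev_ancA, prev_ancB;
  IntegerVector prev_ids;
  int n_prev = 0;
  if (n_h > 0) {
    if (prevA_.isNull()) stop("h_g > 0 but there is no previous admixed generation");
    prevA = prevA_.get(); prevB = prevB_.get();
    prev_ids = prev_ids_.get(); prev_parents = prev_parents_.get();
    n_prev = prevA.ncol();
    if (n_prev < 1) stop("h_g > 0 but there is no previous admixed generation");
    if (prevA.nrow() != W) stop("word count mismatch between reservoirs and population");
    if (track) { prev_ancA = prev_ancA_.get(); prev_ancB = prev_ancB_.get(); }
  }

  // constant-ancestry template columns (all-African / all-European alleles)
  std::vector<uint32_t> ones(W, 0u), zeros(W, 0u);
  for (int s = 0; s < L; ++s) ones[s >> 5] |= (1u << (s & 31));

  int id = id_start;
  std::vector<Parent> pool(P);
  for (int p = 0; p < P; ++p) {
    Parent &par = pool[p];
    if (p < n_afr + n_eur) {
      bool afr = p < n_afr;
      const IntegerMatrix &res = afr ? afr_res : eur_res;
      int Rn = afr ? R_afr : R_eur;
      int g1 = rand_below(Rn), g2 = g1;
      while (g2 == g1) g2 = rand_below(Rn);
      par.hapA = (const uint32_t *)&res(0, g1);
      par.hapB = (const uint32_t *)&res(0, g2);
      par.ancA = par.ancB = nullptr;
      par.anc_const = afr ? 1 : 0; // 1 = African-origin allele
      par.pid = id++; par.gp1 = id++; par.gp2 = id++;
    } else {
      int j = rand_below(n_prev);
      par.hapA = (const uint32_t *)&prevA(0, j);
      par.hapB = (const uint32_t *)&prevB(0, j);
      par.anc_const = -1;
      if (track) {
        par.ancA = (const uint32_t *)&prev_ancA(0, j);
        par.ancB = (const uint32_t *)&prev_ancB(0, j);
      } else par.ancA = par.ancB = nullptr;
      par.pid = prev_ids[j];
      par.gp1 = prev_parents(j, 0);
      par.gp2 = prev_parents(j, 1);
    }
  }

  bool two_distinct = false;
  for (int p = 1; p < P; ++p) if (pool[p].pid != pool[0].pid) { two_distinct = true; break; }
  if (!two_distinct)
    stop("cannot pick two distinct parents without selfing: parental pool holds a single individual");

  IntegerMatrix hapA(W, n_offspring), hapB(W, n_offspring);
  IntegerMatrix ancA, ancB;
  if (track) { ancA = IntegerMatrix(W, n_offspring); ancB = IntegerMatrix(W, n_offspring); }
  IntegerVector ids(n_offspring);
  IntegerMatrix parents(n_offspring, 2), grandparents(n_offspring, 4);

  MaskStream rng(seed_from_R());

  for (int i = 0; i < n_offspring; ++i) {
    int p1 = rand_below(P), p2 = p1;
    int tries = 0;
    while (pool[p2].pid == pool[p1].pid) {
      p2 = rand_below(P);
      if (++tries > 10000) stop("cannot pick two distinct parents without selfing");
    }
    const Parent &pa = pool[p1], &pb = pool[p2];
    if (track) {
      // reuse the identical mask stream state for alleles and labels by
      // regenerating the same masks: draw masks once into a buffer
      std::vector<uint32_t> mbuf(W);
      for (int w = 0; w < W; w += 2) {
        uint64_t m64 = rng.next();
        mbuf[w] = (uint32_t)m64;
        if (w + 1 < W) mbuf[w + 1] = (uint32_t)(m64 >> 32);
      }
      uint32_t *oA = (uint32_t *)&hapA(0, i), *aA = (uint32_t *)&ancA(0, i);
      for (int w = 0; w < W; ++w) {
        oA[w] = (pa.hapA[w] & mbuf[w]) | (pa.hapB[w] & ~mbuf[w]);
        aA[w] = pa.anc_const >= 0
          ? (pa.anc_const ? ones[w] : 0u)
          : ((pa.ancA[w] & mbuf[w]) | (pa.ancB[w] & ~mbuf[w]));
      }
      for (int w = 0; w < W; w += 2) {
        uint64_t m64 = rng.next();
        mbuf[w] = (uint32_t)m64;
        if (w + 1 < W) mbuf[w + 1] = (uint32_t)(m64 >> 32);
      }
      uint32_t *oB = (uint32_t *)&hapB(0, i), *aB = (uint32_t *)&ancB(0, i);
      for (int w = 0; w < W; ++w) {
        oB[w] = (pb.hapA[w] & mbuf[w]) | (pb.hapB[w] & ~mbuf[w]);
        aB[w] = pb.anc_const >= 0
          ? (pb.anc_const ? ones[w] : 0u)
          : ((pb.ancA[w] & mbuf[w]) | (pb.ancB[w] & ~mbuf[w]));
      }
    } else {
      make_gamete((uint32_t *)&hapA(0, i), pa.hapA, pa.hapB, W, rng);
      make_gamete((uint32_t *)&hapB(0, i), pb.hapA, pb.hapB, W, rng);
    }
    ids[i] = id++;
    parents(i, 0) = pa.pid; parents(i, 1) = pb.pid;
    grandparents(i, 0) = pa.gp1; grandparents(i, 1) = pa.gp2;
    grandparents(i, 2) = pb.gp1; grandparents(i, 3) = pb.gp2;
  }

  List out = List::create(
    _["hapA"] = hapA, _["hapB"] = hapB,
    _["ids"] = ids, _["parents"] = parents, _["grandparents"] = grandparents,
    _["id_next"] = id);
  if (track) { out["ancA"] = ancA; out["ancB"] = ancB; }
  return out;
}

// Per-column count of set bits (e.g. African-origin alleles per haplotype).
// [[Rcpp::export]]
NumericVector popcount_columns_cpp(IntegerMatrix packed) {
  const int W = packed.nrow(), N = packed.ncol();
  NumericVector out(N);
  for (int j = 0; j < N; ++j) {
    const uint32_t *col = (const uint32_t *)&packed(0, j);
    long c = 0;
    for (int w = 0; w < W; ++w) c += __builtin_popcount(col[w]);
    out[j] = (double)c;
  }
  return out;
}

// ASD between diploid individuals given their two packed haplotypes.
// For one site with haplotype alleles (x1, x2) vs (y1, y2):
//   |g_i - g_j| = u + v - 2*(u & v) + 2*(u & v & eq)
// with u = x1^y1, v = x2^y2, eq = ~(x1^x2); ASD = Manhattan / (2 L).
// [[Rcpp::export]]
NumericMatrix asd_packed_cpp(IntegerMatrix hap1, IntegerMatrix hap2, int L) {
  const int W = hap1.nrow(), n = hap1.ncol();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    const uint32_t *x1 = (const uint32_t *)&hap1(0, i);
    const uint32_t *x2 = (const uint32_t *)&hap2(0, i);
    for (int j = i + 1; j < n; ++j) {
      const uint32_t *y1 = (const uint32_t *)&hap1(0, j);
      const uint32_t *y2 = (const uint32_t *)&hap2(0, j);
      long manhattan = 0;
      for (int w = 0; w < W; ++w) {
        uint32_t u = x1[w] ^ y1[w];
        uint32_t v = x2[w] ^ y2[w];
        uint32_t uv = u & v;
        manhattan += __builtin_popcount(u) + __builtin_popcount(v)
          - 2 * __builtin_popcount(uv)
          + 2 * __builtin_popcount(uv & ~(x1[w] ^ x2[w]));
      }
      double d = (double)manhattan / (2.0 * (double)L);
      out(i, j) = d; out(j, i) = d;
    }
  }
  return out;
}

// Pairwise ASD from an individuals-in-columns genotype matrix (values
// 0/1/2, na_code for missing): mean over sites non-missing in both of
// |g_i - g_j| / 2. General entry point for observed data.
// [[Rcpp::export]]
NumericMatrix asd_pairwise_cpp(IntegerMatrix geno, int na_code) {
  const int L = geno.nrow(), n = geno.ncol();
  bool any_na = false;
  for (int i = 0; i < L * n && !any_na; ++i) any_na = geno[i] == na_code;
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    const int *gi = &geno(0, i);
    for (int j = i + 1; j < n; ++j) {
      const int *gj = &geno(0, j);
      long diff = 0;
      double d;
      if (!any_na) {
        for (int s = 0; s < L; ++s) {
          int t = gi[s] - gj[s];
          diff += t > 0 ? t : -t;
        }
        d = (double)diff / (2.0 * (double)L);
      } else {
        long shared = 0;
        for (int s = 0; s < L; ++s) {
          int a = gi[s], b = gj[s];
          if (a == na_code || b == na_code) continue;
          shared++;
          diff += a > b ? a - b : b - a;
        }
        if (shared == 0)
          stop("individuals %d and %d share no non-missing site", i + 1, j + 1);
        d = (double)diff / (2.0 * (double)shared);
      }
      out(i, j) = d; out(j, i) = d;
    }
  }
  return out;
}

// Null replicates of the ancestry-in-ROH proportion for one individual:
// re-places the given ROH lengths uniformly on the individual's map
// (non-overlap by rejection, longest first), intersects with the
// individual's ancestry intervals, and returns per-replicate
// anc / (anc + other) length proportions.
// [[Rcpp::export]]
NumericVector roh_perm_props_cpp(NumericVector lengths, NumericVector map_len,
                                 List anc_iv, List oth_iv, int n_perm,
                                 bool within_chrom, IntegerVector orig_chrom,
                                 int max_tries) {
  const int k = lengths.size(), C = map_len.size();
  std::vector<std::vector<double>> anc_lo(C), anc_hi(C), oth_lo(C), oth_hi(C);
  for (int c = 0; c < C; ++c) {
    NumericMatrix a = anc_iv[c], o = oth_iv[c];
    for (int i = 0; i < a.nrow(); ++i) { anc_lo[c].push_back(a(i,0)); anc_hi[c].push_back(a(i,1)); }
    for (int i = 0; i < o.nrow(); ++i) { oth_lo[c].push_back(o(i,0)); oth_hi[c].push_back(o(i,1)); }
  }
  NumericVector out(n_perm);
  std::vector<int> pc(k);
  std::vector<double> ps(k), pe(k);
  for (int b = 0; b < n_perm; ++b) {
    double anc_tot = 0.0, oth_tot = 0.0;
    for (int j = 0; j < k; ++j) {
      double l = lengths[j];
      bool ok = false;
      for (int tr = 0; tr < max_tries; ++tr) {
        int cc;
        if (within_chrom) {
          cc = orig_chrom[j] - 1;
          if (map_len[cc] < l) stop("ROH does not fit on its chromosome");
        } else {
          double wsum = 0.0;
          for (int c = 0; c < C; ++c) if (map_len[c] >= l) wsum += map_len[c] - l + 1e-9;
          if (wsum <= 0) stop("ROH longer than every chromosome");
          double u = unif_rand() * wsum;
          cc = -1;
          for (int c = 0; c < C; ++c) {
            if (map_len[c] < l) continue;
            u -= map_len[c] - l + 1e-9;
            if (u <= 0) { cc = c; break; }
          }
          if (cc < 0) cc = C - 1;
        }
        double a = unif_rand() * (map_len[cc] - l);
        double bnd = a + l;
        bool clash = false;
        for (int q = 0; q < j; ++q) {
          if (pc[q] == cc && bnd > ps[q] && a < pe[q]) { clash = true; break; }
        }
        if (clash) continue;
        pc[j] = cc; ps[j] = a; pe[j] = bnd;
        for (size_t i = 0; i < anc_lo[cc].size(); ++i) {
          double lo = anc_lo[cc][i] > a ? anc_lo[cc][i] : a;
          double hi = anc_hi[cc][i] < bnd ? anc_hi[cc][i] : bnd;
          if (hi > lo) anc_tot += hi - lo;
        }
        for (size_t i = 0; i < oth_lo[cc].size(); ++i) {
          double lo = oth_lo[cc][i] > a ? oth_lo[cc][i] : a;
          double hi = oth_hi[cc][i] < bnd ? oth_hi[cc][i] : bnd;
          if (hi > lo) oth_tot += hi - lo;
        }
        ok = true;
        break;
      }
      if (!ok) stop("could not re-place ROH without overlap");
    }
    double den = anc_tot + oth_tot;
    out[b] = den > 0 ? anc_tot / den : NA_REAL;
  }
  return out;
}
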