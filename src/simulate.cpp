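#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Breeding core for a two-founder RI strain: F1 (B x D) followed by
// repeated sib-mating, with crossovers placed as a Poisson process on the
// cM scale (Haldane, no interference) and a stepwise, length-dependent
// STR mutation process applied at every parent -> gamete transmission.
//
// Locus layout: all loci (SNP markers and STRs) concatenated in
// (chromosome, position) order. chromOffsets gives 0-based start offsets
// per chromosome plus a final sentinel. strIdx maps a locus to its row in
// the STR arrays (-1 for SNP markers). Labels: 0 = B founder, 1 = D.
//
// Mutation sampling uses binomial thinning at the per-gamete maximum rate;
// the per-locus acceptance ratio reproduces the per-locus law
// min(rateCap, baseRate * exp(lengthSlope * len_bp)) up to O(rate^2).

namespace {

struct Haplo {
  std::vector<int> lab;   // founder label per locus
  std::vector<int> len;   // repeat-unit length per STR
};

struct MutModel {
  double baseRate, lengthSlope, rateCap, stepP, pExpB, pExpD;
};

inline double locusRate(const MutModel& m, int ru, int mlen) {
  double r = m.baseRate * std::exp(m.lengthSlope * (double)ru * (double)mlen);
  return r > m.rateCap ? m.rateCap : r;
}

// expansion probability given the transmitting parent's diploid genotype
// at the mutator locus (0/0 -> B, 1/1 -> D, het -> mean)
inline double parentPExp(const MutModel& m, const Haplo& h1, const Haplo& h2,
                         int mutatorLocus) {
  if (mutatorLocus < 0) return 0.5 * (m.pExpB + m.pExpD);
  int g = h1.lab[mutatorLocus] + h2.lab[mutatorLocus];
  if (g == 0) return m.pExpB;
  if (g == 2) return m.pExpD;
  return 0.5 * (m.pExpB + m.pExpD);
}

void makeGamete(const Haplo& h1, const Haplo& h2, Haplo& gam,
                const IntegerVector& chromOffsets, const NumericVector& cmPos,
                const IntegerVector& strIdx, const IntegerVector& motifLen,
                const MutModel& m, double pExp, int nStr) {
  int nChrom = chromOffsets.size() - 1;
  int maxLenBp = 0;
  for (int c = 0; c < nChrom; ++c) {
    int lo = chromOffsets[c], hi = chromOffsets[c + 1];
    if (lo >= hi) continue;
    double cmLo = cmPos[lo], cmHi = cmPos[hi - 1];
    double L = cmHi - cmLo;
    int nCo = (L > 0) ? (int)R::rpois(L / 100.0) : 0;
    std::vector<double> xo(nCo);
    for (int k = 0; k < nCo; ++k) xo[k] = cmLo + L * unif_rand();
    std::sort(xo.begin(), xo.end());
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int p = 0;
    for (int i = lo; i < hi; ++i) {
      while (p < nCo && xo[p] <= cmPos[i]) { cur ^= 1; ++p; }
      const Haplo& src = cur == 0 ? h1 : h2;
      gam.lab[i] = src.lab[i];
      int s = strIdx[i];
      if (s >= 0) {
        int ru = src.len[s];
        gam.len[s] = ru;
        int bp = ru * motifLen[s];
        if (bp > maxLenBp) maxLenBp = bp;
      }
    }
  }
  // stepwise mutation pass over the gamete's STRs
  if (m.baseRate <= 0.0 || nStr == 0) return;
  double rMax = m.baseRate * std::exp(m.lengthSlope * (double)maxLenBp);
  if (rMax > m.rateCap) rMax = m.rateCap;
  if (rMax <= 0.0) return;
  int K = (int)R::rbinom((double)nStr, rMax);
  for (int k = 0; k < K; ++k) {
    int s = (int)(unif_rand() * nStr);
    if (s >= nStr) s = nStr - 1;
    double r = locusRate(m, gam.len[s], motifLen[s]);
    if (unif_rand() * rMax > r) continue;
    int step = 1 + (int)R::rgeom(m.stepP);
    int sign = (unif_rand() < pExp) ? 1 : -1;
    int nl = gam.len[s] + sign * step;
    gam.len[s] = nl < 1 ? 1 : nl;
  }
}

} // namespace

// [[Rcpp::export(name = ".simulate_strain_cpp")]]
List simulate_strain_cpp(IntegerVector chromOffsets, NumericVector cmPos,
                         IntegerVector strIdx, IntegerVector motifLen,
                         IntegerVector stockLenB, IntegerVector stockLenD,
                         int nGenerations, int mutatorLocus,
                         double baseRate, double lengthSlope, double rateCap,
                         double stepP, double pExpB, double pExpD) {
  int nLoci = cmPos.size();
  int nStr = stockLenB.size();
  if (nGenerations < 1) stop("nGenerations must be >= 1");
  MutModel m{baseRate, lengthSlope, rateCap, stepP, pExpB, pExpD};

  // founder stock individuals (fully inbred): B/B and D/D
  Haplo fB, fD;
  fB.lab.assign(nLoci, 0); fD.lab.assign(nLoci, 1);
  fB.len.assign(stockLenB.begin(), stockLenB.end());
  fD.len.assign(stockLenD.begin(), stockLenD.end());

  // generation 1: the F1 cross (one transmission from each founder)
  std::vector<Haplo> cur(4), nxt(4);
  for (int i = 0; i < 4; ++i) {
    cur[i].lab.assign(nLoci, 0); cur[i].len.assign(nStr, 0);
    nxt[i].lab.assign(nLoci, 0); nxt[i].len.assign(nStr, 0);
  }
  for (int child = 0; child < 2; ++child) {
    makeGamete(fB, fB, cur[2 * child], chromOffsets, cmPos, strIdx, motifLen,
               m, m.pExpB, nStr);
    makeGamete(fD, fD, cur[2 * child + 1], chromOffsets, cmPos, strIdx,
               motifLen, m, m.pExpD, nStr);
  }

  // generations 2..nGenerations: sib-mating of the previous two sibs
  for (int g = 2; g <= nGenerations; ++g) {
    double pExpMom = parentPExp(m, cur[0], cur[1], mutatorLocus);
    double pExpDad = parentPExp(m, cur[2], cur[3], mutatorLocus);
    for (int child = 0; child < 2; ++child) {
      makeGamete(cur[0], cur[1], nxt[2 * child], chromOffsets, cmPos, strIdx,
                 motifLen, m, pExpMom, nStr);
      makeGamete(cur[2], cur[3], nxt[2 * child + 1], chromOffsets, cmPos,
                 strIdx, motifLen, m, pExpDad, nStr);
    }
    std::swap(cur, nxt);
  }

  IntegerMatrix lab(nLoci, 2);
  IntegerMatrix len(nStr, 2);
  for (int i = 0; i < nLoci; ++i) { lab(i, 0) = cur[0].lab[i]; lab(i, 1) = cur[1].lab[i]; }
  for (int s = 0; s < nStr; ++s) { len(s, 0) = cur[0].len[s]; len(s, 1) = cur[1].len[s]; }
  return List::create(_["label"] = lab, _["strLen"] = len);
}

// One transmission of the founder-stock mutation process applied to a single
// haploid stock (used to model ancestral-stock drift between epochs).
// [[Rcpp::export(name = ".stock_transmissions_cpp")]]
IntegerVector stock_transmissions_cpp(IntegerVector lens, IntegerVector motifLen,
                                      int nTransmissions, double baseRate,
                                      double lengthSlope, double rateCap,
                                      double stepP, double pExp) {
  MutModel m{baseRate, lengthSlope, rateCap, stepP, pExp, pExp};
  IntegerVector out = clone(lens);
  int nStr = out.size();
  for (int t = 0; t < nTransmissions; ++t) {
    for (int s = 0; s < nStr; ++s) {
      double r = locusRate(m, out[s], motifLen[s]);
      if (unif_rand() < r) {
        int step = 1 + (int)R::rgeom(stepP);
        int sign = (unif_rand() < pExp) ? 1 : -1;
        int nl = out[s] + sign * step;
        out[s] = nl < 1 ? 1 : nl;
      }
    }
  }
  return out;
}
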