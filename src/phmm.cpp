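#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Profile-HMM forward and Viterbi scores in odds space against the
// background model. Architecture: free N/C flanking insert states
// (background emission, no transition cost) around a global core of
// match/insert/delete states; see the R-level docs for the recursions.
//
// The forward pass runs in scaled linear space: state values are kept
// relative to an accumulated log scale, with rescaling triggered only when
// the row maximum approaches the double overflow range. This keeps the
// arithmetic in mul/add form; a log-sum-exp recursion is numerically
// equivalent but an order of magnitude slower at proteome scale. The N
// flank has absolute value 1, so its scaled value exp(-cum) underflows only
// once a path ~1000 bits above background has been found, at which point
// late core entries are negligible in the forward sum.

// [[Rcpp::export]]
double phmm_forward_bits_cpp(IntegerVector seq, NumericMatrix em_odds,
                             NumericVector tmm, NumericVector tmi,
                             NumericVector tmd, NumericVector tim,
                             NumericVector tii, NumericVector tdm,
                             NumericVector tdd) {
  const int K = em_odds.nrow();
  const int L = seq.size();
  const double RESCALE_AT = 1e250;
  std::vector<double> Mv(K + 1, 0.0), Iv(K + 1, 0.0), Dv(K + 1, 0.0);
  std::vector<double> Mn(K + 1, 0.0), In(K + 1, 0.0), Dn(K + 1, 0.0);
  double cum = 0.0;  // accumulated log scale
  double N = 1.0;    // scaled N-flank value (absolute value is always 1)
  const double *pmm = &tmm[0], *pmi = &tmi[0], *pmd = &tmd[0];
  const double *pim = &tim[0], *pii = &tii[0], *pdm = &tdm[0];
  const double *pdd = &tdd[0];

  // row 0: nothing emitted; the all-delete core path.
  // tdm/tdd have length K; 0-based entry k-1 holds the transition out of D_k.
  Dv[1] = N * pmd[0];
  for (int k = 2; k <= K; ++k) Dv[k] = Dv[k - 1] * pdd[k - 2];
  double C = Dv[K] * pdm[K - 1];

  for (int i = 0; i < L; ++i) {
    const double *eo = &em_odds(0, seq[i]); // emission odds column, k = 1..K
    double rowmax = 0.0;
    double Mprev_new = 0.0; // Mn[k-1] within the running row
    // k = 1: entry from the begin state (N) and core insert I_0
    In[0] = N * pmi[0] + Iv[0] * pii[0];
    {
      const double m = eo[0] * (N * pmm[0] + Iv[0] * pim[0]);
      Mn[1] = m;
      Dn[1] = N * pmd[0];
      In[1] = Mv[1] * pmi[1] + Iv[1] * pii[1];
      Mprev_new = m;
      rowmax = m;
      if (In[1] > rowmax) rowmax = In[1];
      if (Dn[1] > rowmax) rowmax = Dn[1];
    }
    for (int k = 2; k <= K; ++k) {
      const double m = eo[k - 1] *
        (Mv[k - 1] * pmm[k - 1] + Iv[k - 1] * pim[k - 1] +
         Dv[k - 1] * pdm[k - 2]);
      const double d = Mprev_new * pmd[k - 1] + Dn[k - 1] * pdd[k - 2];
      const double ins = Mv[k] * pmi[k] + Iv[k] * pii[k];
      Mn[k] = m; Dn[k] = d; In[k] = ins;
      Mprev_new = m;
      if (m > rowmax) rowmax = m;
      if (d > rowmax) rowmax = d;
      if (ins > rowmax) rowmax = ins;
    }
    C += Mn[K] * pmm[K] + In[K] * pim[K] + Dn[K] * pdm[K - 1];

    if (rowmax > RESCALE_AT || C > RESCALE_AT) {
      const double s = (rowmax > C) ? rowmax : C;
      const double inv = 1.0 / s;
      for (int k = 0; k <= K; ++k) { Mn[k] *= inv; In[k] *= inv; Dn[k] *= inv; }
      C *= inv;
      cum += std::log(s);
      N = std::exp(-cum); // absolute value 1 in the new scale
    }
    Mv.swap(Mn); Iv.swap(In); Dv.swap(Dn);
  }
  if (C <= 0.0) return R_NegInf;
  return (std::log(C) + cum) / M_LN2;
}

static inline double lg(double x) {
  return x > 0.0 ? std::log(x) : R_NegInf;
}

// [[Rcpp::export]]
double phmm_viterbi_bits_cpp(IntegerVector seq, NumericMatrix em_odds,
                             NumericVector tmm, NumericVector tmi,
                             NumericVector tmd, NumericVector tim,
                             NumericVector tii, NumericVector tdm,
                             NumericVector tdd) {
  const int K = em_odds.nrow();
  const int L = seq.size();
  const double NEG = R_NegInf;
  std::vector<double> M(K + 1, NEG), I(K + 1, NEG), D(K + 1, NEG);
  std::vector<double> Mn(K + 1, NEG), In(K + 1, NEG), Dn(K + 1, NEG);
  const double N = 0.0; // log odds of the free N flank
  D[1] = N + lg(tmd[0]);
  for (int k = 2; k <= K; ++k) D[k] = D[k - 1] + lg(tdd[k - 2]);
  double best = D[K] + lg(tdm[K - 1]);

  for (int i = 0; i < L; ++i) {
    const int a = seq[i];
    In[0] = std::max(N + lg(tmi[0]), I[0] + lg(tii[0]));
    Mn[1] = lg(em_odds(0, a)) + std::max(N + lg(tmm[0]), I[0] + lg(tim[0]));
    Dn[1] = N + lg(tmd[0]);
    In[1] = std::max(M[1] + lg(tmi[1]), I[1] + lg(tii[1]));
    for (int k = 2; k <= K; ++k) {
      double in = std::max(M[k - 1] + lg(tmm[k - 1]),
                           I[k - 1] + lg(tim[k - 1]));
      in = std::max(in, D[k - 1] + lg(tdm[k - 2]));
      Mn[k] = lg(em_odds(k - 1, a)) + in;
      Dn[k] = std::max(Mn[k - 1] + lg(tmd[k - 1]), Dn[k - 1] + lg(tdd[k - 2]));
      In[k] = std::max(M[k] + lg(tmi[k]), I[k] + lg(tii[k]));
    }
    double E = std::max(Mn[K] + lg(tmm[K]), In[K] + lg(tim[K]));
    E = std::max(E, Dn[K] + lg(tdm[K - 1]));
    if (E > best) best = E; // remaining residues ride the free C flank
    M.swap(Mn); I.swap(In); D.swap(Dn);
  }
  return best / M_LN2;
}
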