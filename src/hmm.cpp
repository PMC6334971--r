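#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log2-space sum: log2(2^a + 2^b)
static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  const double m = (a > b) ? a : b;
  const double d = (a > b) ? (b - a) : (a - b);
  if (d < -60.0) return m;               // below double log2 resolution
  return m + std::log2(1.0 + std::exp2(d));
}

// Local-mode profile HMM dynamic programming.
//
// States: match M_1..M_m, insert I_1..I_{m-1}, delete D_2..D_m (interior
// only: paths enter at an M state and exit from an M state, so deletes never
// border the aligned region).  All scores are log2-odds against the
// background null; insert emissions typically equal the background so their
// log-odds are ~0.
//
// lodM: L x m match emission log2-odds for the query sequence
// lodI: L x m insert emission log2-odds
// ltrM: m x 4 log2 transitions (MM, MI, MD, ME)
// ltrI: m x 2 log2 transitions (IM, II)
// ltrD: m x 2 log2 transitions (DM, DD)
// lentry: log2 entry probability B -> M_k (uniform over k)

// [[Rcpp::export(name = ".hmmForwardC")]]
double hmmForwardC(NumericMatrix lodM, NumericMatrix lodI,
                   NumericMatrix ltrM, NumericMatrix ltrI,
                   NumericMatrix ltrD, double lentry) {
  const int L = lodM.nrow(), m = lodM.ncol();
  const double NEG = R_NegInf;
  std::vector<double> FM(m, NEG), FI(m, NEG), FD(m, NEG);
  std::vector<double> PM(m), PI(m), PD(m);
  double total = NEG;
  for (int i = 0; i < L; ++i) {
    PM = FM; PI = FI; PD = FD;
    for (int k = 0; k < m; ++k) {
      // match: entry, or continue from previous column's k-1 states
      double acc = lentry;
      if (k > 0) {
        acc = lse2(acc, PM[k - 1] + ltrM(k - 1, 0));
        acc = lse2(acc, PI[k - 1] + ltrI(k - 1, 0));
        acc = lse2(acc, PD[k - 1] + ltrD(k - 1, 0));
      }
      FM[k] = lodM(i, k) + acc;
      // insert (I_k exists for k < m-1? I_1..I_{m-1} -> index k<m-1 ... keep k<m-1+1)
      if (k < m - 1) {
        double ai = lse2(PM[k] + ltrM(k, 1), PI[k] + ltrI(k, 1));
        FI[k] = lodI(i, k) + ai;
      } else {
        FI[k] = NEG;
      }
    }
    // deletes: same residue index, sequential over states
    for (int k = 0; k < m; ++k) {
      if (k == 0) { FD[k] = NEG; continue; }
      FD[k] = lse2(FM[k - 1] + ltrM(k - 1, 2), FD[k - 1] + ltrD(k - 1, 1));
    }
    // exits from any match state at position i
    for (int k = 0; k < m; ++k)
      total = lse2(total, FM[k] + ltrM(k, 3));
  }
  return total;
}

// [[Rcpp::export(name = ".hmmViterbiC")]]
List hmmViterbiC(NumericMatrix lodM, NumericMatrix lodI,
                 NumericMatrix ltrM, NumericMatrix ltrI,
                 NumericMatrix ltrD, double lentry) {
  const int L = lodM.nrow(), m = lodM.ncol();
  const double NEG = R_NegInf;
  std::vector<double> VM(m, NEG), VI(m, NEG), VD(m, NEG);
  std::vector<double> PM(m), PI(m), PD(m);
  // start-position bookkeeping per cell (1-based residue index of entry)
  std::vector<int> SM(m, 0), SI(m, 0), SD(m, 0), QM(m), QI(m), QD(m);
  double best = NEG;
  int bestStart = 0, bestEnd = 0;
  for (int i = 0; i < L; ++i) {
    PM = VM; PI = VI; PD = VD;
    QM = SM; QI = SI; QD = SD;
    for (int k = 0; k < m; ++k) {
      double v = lentry; int s = i + 1;
      if (k > 0) {
        double c;
        c = PM[k - 1] + ltrM(k - 1, 0); if (c > v) { v = c; s = QM[k - 1]; }
        c = PI[k - 1] + ltrI(k - 1, 0); if (c > v) { v = c; s = QI[k - 1]; }
        c = PD[k - 1] + ltrD(k - 1, 0); if (c > v) { v = c; s = QD[k - 1]; }
      }
      VM[k] = lodM(i, k) + v; SM[k] = s;
      if (k < m - 1) {
        double a = PM[k] + ltrM(k, 1); int sa = QM[k];
        double b = PI[k] + ltrI(k, 1);
        if (b > a) { a = b; sa = QI[k]; }
        VI[k] = lodI(i, k) + a; SI[k] = sa;
      } else { VI[k] = NEG; SI[k] = 0; }
    }
    for (int k = 0; k < m; ++k) {
      if (k == 0) { VD[k] = NEG; SD[k] = 0; continue; }
      double a = VM[k - 1] + ltrM(k - 1, 2); int sa = SM[k - 1];
      double b = VD[k - 1] + ltrD(k - 1, 1);
      if (b > a) { a = b; sa = SD[k - 1]; }
      VD[k] = a; SD[k] = sa;
    }
    for (int k = 0; k < m; ++k) {
      double sc = VM[k] + ltrM(k, 3);
      if (sc > best) { best = sc; bestStart = SM[k]; bestEnd = i + 1; }
    }
  }
  return List::create(_["score"] = best, _["start"] = bestStart,
                      _["end"] = bestEnd);
}
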