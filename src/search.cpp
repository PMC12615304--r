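// Fragment-matching core for the simplified open search.
//
// Score of a peptide-spectrum pair = (number of matched peaks) +
// (fraction of total peak intensity carried by matched peaks), where a
// peak is matched when it lies within the ppm tolerance of any
// theoretical b/y ion of the hypothesis. For a non-zero precursor delta
// the shift is attributed to a single residue position, chosen by
// matched-ion count in O(L) via prefix sums; the chosen hypothesis is
// then scored on distinct matched peaks.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// index range [lo, hi) of peaks within ppm tolerance of target
static inline void peak_range(const double* mz, int n, double target,
                              double tol_ppm, int& lo, int& hi) {
  double tol = tol_ppm * 1e-6 * target;
  lo = int(std::lower_bound(mz, mz + n, target - tol) - mz);
  hi = int(std::upper_bound(mz, mz + n, target + tol) - mz);
}

struct ScoreResult {
  int nmatch;      // distinct matched peaks
  double int_frac;
  int pos;         // best modification position (0-based), -1 if unmodified
  double score;
};

static ScoreResult score_candidate(const double* pmz, const double* pint,
                                   int npk, double total_int,
                                   const double* res, int L, double delta,
                                   double tol_ppm, bool unmod, double proton,
                                   double water) {
  ScoreResult r{0, 0.0, -1, 0.0};
  if (L < 2 || npk == 0) return r;
  int ni = L - 1;
  std::vector<double> pre(L + 1, 0.0);
  for (int i = 0; i < L; ++i) pre[i + 1] = pre[i] + res[i];
  double total = pre[L];
  // per-ion peak ranges: b_i = pre[i] + proton; y_j = total - pre[L-j] + water + proton
  std::vector<int> b0lo(ni), b0hi(ni), y0lo(ni), y0hi(ni);
  for (int i = 1; i <= ni; ++i) {
    peak_range(pmz, npk, pre[i] + proton, tol_ppm, b0lo[i - 1], b0hi[i - 1]);
    peak_range(pmz, npk, total - pre[L - i] + water + proton, tol_ppm,
               y0lo[i - 1], y0hi[i - 1]);
  }
  std::vector<char> used(npk, 0);
  auto mark = [&](int lo, int hi) { for (int k = lo; k < hi; ++k) used[k] = 1; };
  auto finish = [&](void) {
    int cnt = 0;
    double m = 0.0;
    for (int k = 0; k < npk; ++k) if (used[k]) { ++cnt; m += pint[k]; }
    r.nmatch = cnt;
    r.int_frac = total_int > 0 ? m / total_int : 0.0;
    r.score = cnt + r.int_frac;
  };
  if (unmod) {
    for (int i = 0; i < ni; ++i) { mark(b0lo[i], b0hi[i]); mark(y0lo[i], y0hi[i]); }
    finish();
    r.pos = -1;
    return r;
  }
  std::vector<int> b1lo(ni), b1hi(ni), y1lo(ni), y1hi(ni);
  for (int i = 1; i <= ni; ++i) {
    peak_range(pmz, npk, pre[i] + delta + proton, tol_ppm, b1lo[i - 1], b1hi[i - 1]);
    peak_range(pmz, npk, total - pre[L - i] + delta + water + proton, tol_ppm,
               y1lo[i - 1], y1hi[i - 1]);
  }
  // choose the shift position by matched-ion count via prefix sums
  std::vector<int> cb0(ni + 1, 0), cb1(ni + 1, 0), cy0(ni + 1, 0), cy1(ni + 1, 0);
  for (int i = 1; i <= ni; ++i) {
    cb0[i] = cb0[i - 1] + (b0hi[i - 1] > b0lo[i - 1]);
    cb1[i] = cb1[i - 1] + (b1hi[i - 1] > b1lo[i - 1]);
    cy0[i] = cy0[i - 1] + (y0hi[i - 1] > y0lo[i - 1]);
    cy1[i] = cy1[i - 1] + (y1hi[i - 1] > y1lo[i - 1]);
  }
  int bestp = 0, bestc = -1;
  for (int p = 0; p < L; ++p) {
    // b_i contains residue p iff i >= p+1 (shifted); y_j contains p iff j >= L-p
    int bp = std::min(p, ni);         // b_i unshifted for i <= p
    int yq = std::min(L - p - 1, ni); // y_j unshifted for j <= L-p-1
    int cnt = cb0[bp] + (cb1[ni] - cb1[bp]) + cy0[yq] + (cy1[ni] - cy1[yq]);
    if (cnt > bestc) { bestc = cnt; bestp = p; }
  }
  int bp = std::min(bestp, ni), yq = std::min(L - bestp - 1, ni);
  for (int i = 1; i <= ni; ++i) {
    if (i <= bp) mark(b0lo[i - 1], b0hi[i - 1]); else mark(b1lo[i - 1], b1hi[i - 1]);
    if (i <= yq) mark(y0lo[i - 1], y0hi[i - 1]); else mark(y1lo[i - 1], y1hi[i - 1]);
  }
  finish();
  r.pos = bestp;
  return r;
}

// Per-position scores for one spectrum/peptide/delta, used by score_match()
// and PTM site localization.
// [[Rcpp::export]]
List cpp_score_positions(NumericVector peak_mz, NumericVector peak_int,
                         NumericVector res_mass, double delta,
                         double tol_ppm, double proton, double water,
                         bool unshifted_only) {
  int npk = peak_mz.size(), L = res_mass.size();
  double total_int = 0.0;
  for (int k = 0; k < npk; ++k) total_int += peak_int[k];
  int np = unshifted_only ? 1 : L;
  IntegerVector nmatch(np);
  NumericVector ifrac(np);
  std::vector<double> pre(L + 1, 0.0);
  for (int i = 0; i < L; ++i) pre[i + 1] = pre[i] + res_mass[i];
  double total = pre[L];
  for (int p = 0; p < np; ++p) {
    std::vector<char> used(npk, 0);
    int ni = L - 1;
    for (int i = 1; i <= ni; ++i) {
      double bshift = (!unshifted_only && i >= p + 1) ? delta : 0.0;
      double yshift = (!unshifted_only && i >= L - p) ? delta : 0.0;
      int lo, hi;
      peak_range(peak_mz.begin(), npk, pre[i] + bshift + proton, tol_ppm, lo, hi);
      for (int k = lo; k < hi; ++k) used[k] = 1;
      peak_range(peak_mz.begin(), npk,
                 total - pre[L - i] + yshift + water + proton, tol_ppm, lo, hi);
      for (int k = lo; k < hi; ++k) used[k] = 1;
    }
    int cnt = 0;
    double m = 0.0;
    for (int k = 0; k < npk; ++k) if (used[k]) { ++cnt; m += peak_int[k]; }
    nmatch[p] = cnt;
    ifrac[p] = total_int > 0 ? m / total_int : 0.0;
  }
  return List::create(_["nmatch"] = nmatch, _["int_frac"] = ifrac);
}

// Best-scoring candidate peptide per spectrum.
// Peptides are passed as concatenated residue masses (pep_off: 0-based
// offsets, length npep+1) sorted by increasing pep_mass. Peaks are
// concatenated with spec_off offsets. Candidates for a spectrum are
// peptides with delta = spec_mass - pep_mass within [win_lo, win_hi] or
// |delta| within prec_tol_ppm of zero. Ties broken by smaller |delta|,
// then lexicographically smaller peptide sequence.
// [[Rcpp::export]]
DataFrame cpp_open_search(NumericVector spec_mass, NumericVector peak_mz,
                          NumericVector peak_int, IntegerVector spec_off,
                          NumericVector pep_mass, NumericVector res_mass,
                          IntegerVector pep_off, CharacterVector pep_seq,
                          double win_lo, double win_hi, double frag_tol_ppm,
                          double prec_tol_ppm, double proton, double water,
                          int min_matched_peaks) {
  int ns = spec_mass.size(), np = pep_mass.size();
  std::vector<int> out_spec, out_pep, out_nmatch;
  std::vector<double> out_delta, out_score, out_ifrac;
  const double eps = 1e-9;
  for (int s = 0; s < ns; ++s) {
    double M = spec_mass[s];
    const double* pmz = peak_mz.begin() + spec_off[s];
    const double* pint = peak_int.begin() + spec_off[s];
    int npk = spec_off[s + 1] - spec_off[s];
    double total_int = 0.0;
    for (int k = 0; k < npk; ++k) total_int += pint[k];
    double zero_tol = prec_tol_ppm * 1e-6 * M;
    double lo = std::min(M - win_hi, M - zero_tol);
    double hi = std::max(M - win_lo, M + zero_tol);
    int i0 = int(std::lower_bound(pep_mass.begin(), pep_mass.end(), lo) -
                 pep_mass.begin());
    int best = -1, best_nm = 0;
    double best_score = -1.0, best_delta = 0.0, best_ifrac = 0.0;
    for (int j = i0; j < np && pep_mass[j] <= hi; ++j) {
      double delta = M - pep_mass[j];
      bool unmod = std::fabs(delta) <= zero_tol;
      if (!unmod && (delta < win_lo || delta > win_hi)) continue;
      int L = pep_off[j + 1] - pep_off[j];
      ScoreResult r = score_candidate(pmz, pint, npk, total_int,
                                      res_mass.begin() + pep_off[j], L,
                                      delta, frag_tol_ppm, unmod, proton,
                                      water);
      bool take = false;
      if (r.score > best_score + eps) take = true;
      else if (std::fabs(r.score - best_score) <= eps && best >= 0) {
        double da = std::fabs(delta), db = std::fabs(best_delta);
        if (da < db - eps) take = true;
        else if (std::fabs(da - db) <= eps &&
                 std::strcmp(CHAR(pep_seq[j]), CHAR(pep_seq[best])) < 0)
          take = true;
      }
      if (take) {
        best = j; best_score = r.score; best_delta = delta;
        best_nm = r.nmatch; best_ifrac = r.int_frac;
      }
    }
    if (best >= 0 && best_nm >= std::max(1, min_matched_peaks)) {
      out_spec.push_back(s + 1);
      out_pep.push_back(best + 1);
      out_delta.push_back(best_delta);
      out_score.push_back(best_score);
      out_nmatch.push_back(best_nm);
      out_ifrac.push_back(best_ifrac);
    }
  }
  return DataFrame::create(
      _["spec"] = out_spec, _["pep"] = out_pep, _["delta_mass"] = out_delta,
      _["score"] = out_score, _["n_matched_ions"] = out_nmatch,
      _["intensity_fraction"] = out_ifrac);
}
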