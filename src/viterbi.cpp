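#include <Rcpp.h>
using namespace Rcpp;

// Uni-hit local Viterbi over a profile HMM, in bit (log2) space.
//
// mat, ins: M x 20 emission log-odds (bits) for match / insert states.
// tr:       M x 7 transition log2-probabilities out of node k (row k-1):
//           columns mm, mi, md, im, ii, dm, dd.
// x:        0-based residue indices into the alphabet; -1 emits background
//           (log-odds 0) in both match and insert states.
// entry:    log2 probability of starting a local alignment at any match
//           state (uniform over states); exit is free (probability 1).
//
// Ties are broken by preferring continuation from M, then D, then I, then
// a fresh local entry; the global end cell prefers the smallest target
// position, then the smallest match state. This makes the traceback fully
// deterministic.
// [[Rcpp::export]]
List viterbi_c(NumericMatrix mat, NumericMatrix ins, NumericMatrix tr,
               IntegerVector x, double entry) {
  const int M = mat.nrow();
  const int L = x.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  enum { MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6 };

  NumericMatrix vm(M + 1, L + 1), vi(M + 1, L + 1), vd(M + 1, L + 1);
  IntegerMatrix tm(M + 1, L + 1), ti(M + 1, L + 1), td(M + 1, L + 1);
  std::fill(vm.begin(), vm.end(), NEG);
  std::fill(vi.begin(), vi.end(), NEG);
  std::fill(vd.begin(), vd.end(), NEG);

  double best = NEG;
  int best_k = 0, best_i = 0;

  for (int i = 1; i <= L; ++i) {
    const int xi = x[i - 1];
    for (int k = 1; k <= M; ++k) {
      const double em = (xi < 0) ? 0.0 : mat(k - 1, xi);
      // match: candidates scanned in preference order M > D > I > entry,
      // strict > so the preferred candidate wins exact ties
      double sc; int choice;  // 0 entry, 1 from M, 2 from D, 3 from I
      if (k >= 2 && i >= 2) {
        sc = vm(k - 1, i - 1) + tr(k - 2, MM); choice = 1;
        const double fd = vd(k - 1, i - 1) + tr(k - 2, DM);
        const double fi = vi(k - 1, i - 1) + tr(k - 2, IM);
        if (fd > sc) { sc = fd; choice = 2; }
        if (fi > sc) { sc = fi; choice = 3; }
        if (entry > sc) { sc = entry; choice = 0; }
      } else {
        sc = entry; choice = 0;
      }
      vm(k, i) = em + sc;
      tm(k, i) = choice;
      if (vm(k, i) > best) { best = vm(k, i); best_k = k; best_i = i; }
      // insert (never before the first or after the last match in a
      // scoring path, but computed everywhere; useless cells stay -inf)
      if (i >= 2) {
        const double ei = (xi < 0) ? 0.0 : ins(k - 1, xi);
        const double fm = vm(k, i - 1) + tr(k - 1, MI);
        const double fi = vi(k, i - 1) + tr(k - 1, II);
        if (fm >= fi) { vi(k, i) = ei + fm; ti(k, i) = 1; }
        else          { vi(k, i) = ei + fi; ti(k, i) = 3; }
      }
      // delete (same column, previous state row)
      if (k >= 2) {
        const double fm = vm(k - 1, i) + tr(k - 2, MD);
        const double fd = vd(k - 1, i) + tr(k - 2, DD);
        if (fm >= fd) { vd(k, i) = fm; td(k, i) = 1; }
        else          { vd(k, i) = fd; td(k, i) = 2; }
      }
    }
  }

  if (!R_finite(best)) {
    return List::create(_["score"] = best,
                        _["state"] = IntegerVector(0),
                        _["k"] = IntegerVector(0),
                        _["i"] = IntegerVector(0));
  }

  // traceback from (best_k, best_i) in state M
  std::vector<int> pstate, pk, pi;  // state 1=M 2=D 3=I
  int st = 1, k = best_k, i = best_i;
  for (;;) {
    pstate.push_back(st); pk.push_back(k); pi.push_back(i);
    if (st == 1) {
      const int c = tm(k, i);
      if (c == 0) break;
      st = c; --k; --i;
    } else if (st == 3) {
      st = ti(k, i); --i;
    } else {  // delete
      st = td(k, i); --k;
    }
  }
  std::reverse(pstate.begin(), pstate.end());
  std::reverse(pk.begin(), pk.end());
  std::reverse(pi.begin(), pi.end());

  return List::create(_["score"] = best,
                      _["state"] = wrap(pstate),
                      _["k"] = wrap(pk),
                      _["i"] = wrap(pi));
}
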