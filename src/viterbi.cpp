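#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Single-hit local Viterbi over a plan7-style profile, log-odds scoring.
//
// lom, loi: L x M matrices of match / insert emission log-odds (natural
//           log of emission probability over the i.i.d. background), with
//           ambiguous residues already set to 0 by the caller.
// ltr:      M x 7 matrix of natural-log transition probabilities in column
//           order (m->m, m->i, m->d, i->m, i->i, d->m, d->d); row k holds
//           the transitions leaving node k (1-based), so inter-node moves
//           into node k use row k-1.
// entry:    log-probability of beginning at any given match node
//           (uniform entry, log(1/M)); exit from any match node is free.
//
// Returns the best score in nats plus the 1-based (residue, node)
// coordinates of the alignment start and end. Ties resolve to the
// alignment found first scanning residues then nodes, ascending.
// [[Rcpp::export]]
List viterbi_local_c(NumericMatrix lom, NumericMatrix loi,
                     NumericMatrix ltr, double entry) {
  const int L = lom.nrow(), M = lom.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();

  std::vector<double> vmPrev(M, NEG), viPrev(M, NEG), vdPrev(M, NEG);
  std::vector<double> vm(M), vi(M), vd(M);
  // start coordinates carried along each DP cell: (residue, node)
  std::vector<int> smR(M), smK(M), siR(M), siK(M), sdR(M), sdK(M);
  std::vector<int> smRp(M, 0), smKp(M, 0), siRp(M, 0), siKp(M, 0),
                   sdRp(M, 0), sdKp(M, 0);

  double best = NEG;
  int bR = 0, bK = 0, bSR = 0, bSK = 0;

  for (int i = 0; i < L; ++i) {
    for (int k = 0; k < M; ++k) {
      // match state
      double sc = entry; int sr = i + 1, sk = k + 1;
      if (k > 0) {
        double a = vmPrev[k - 1] + ltr(k - 1, 0);
        if (a > sc) { sc = a; sr = smRp[k - 1]; sk = smKp[k - 1]; }
        double b = viPrev[k - 1] + ltr(k - 1, 3);
        if (b > sc) { sc = b; sr = siRp[k - 1]; sk = siKp[k - 1]; }
        double c = vdPrev[k - 1] + ltr(k - 1, 5);
        if (c > sc) { sc = c; sr = sdRp[k - 1]; sk = sdKp[k - 1]; }
      }
      vm[k] = sc + lom(i, k); smR[k] = sr; smK[k] = sk;

      // insert state (no insert after the last node)
      double ii = NEG; int ir = 0, ik = 0;
      double a = vmPrev[k] + ltr(k, 1);
      if (a > ii) { ii = a; ir = smRp[k]; ik = smKp[k]; }
      double b = viPrev[k] + ltr(k, 4);
      if (b > ii) { ii = b; ir = siRp[k]; ik = siKp[k]; }
      vi[k] = (ii == NEG) ? NEG : ii + loi(i, k);
      siR[k] = ir; siK[k] = ik;

      if (vm[k] > best) {
        best = vm[k]; bR = i + 1; bK = k + 1; bSR = smR[k]; bSK = smK[k];
      }
    }
    // delete states, same residue index, left to right
    for (int k = 0; k < M; ++k) {
      double dd = NEG; int dr = 0, dk = 0;
      if (k > 0) {
        double a = vm[k - 1] + ltr(k - 1, 2);
        if (a > dd) { dd = a; dr = smR[k - 1]; dk = smK[k - 1]; }
        double b = vd[k - 1] + ltr(k - 1, 6);
        if (b > dd) { dd = b; dr = sdR[k - 1]; dk = sdK[k - 1]; }
      }
      vd[k] = dd; sdR[k] = dr; sdK[k] = dk;
    }
    vmPrev = vm; viPrev = vi; vdPrev = vd;
    smRp = smR; smKp = smK; siRp = siR; siKp = siK; sdRp = sdR; sdKp = sdK;
  }

  return List::create(_["score"] = best,
                      _["start_res"] = bSR, _["start_node"] = bSK,
                      _["end_res"] = bR, _["end_node"] = bK);
}
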