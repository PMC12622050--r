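// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <set>
using namespace Rcpp;

// Kabsch least-squares superposition (reflection corrected). Returns the
// rotation R and translation t mapping mobile onto target (x' = R x + t)
// together with the residual RMSD.
static void kabsch_core(const arma::mat& P, const arma::mat& Q,
                        arma::mat& R, arma::vec& t, double& rmsd) {
  const arma::rowvec cP = arma::mean(P, 0);
  const arma::rowvec cQ = arma::mean(Q, 0);
  const arma::mat Pc = P.each_row() - cP;
  const arma::mat Qc = Q.each_row() - cQ;
  const arma::mat H = Pc.t() * Qc;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  R = V * D * U.t();
  t = cQ.t() - R * cP.t();
  const arma::mat Pr = (R * Pc.t()).t();
  rmsd = std::sqrt(arma::accu(arma::square(Pr - Qc)) / (double)P.n_rows);
}

// [[Rcpp::export]]
List cpp_kabsch(NumericMatrix mobile, NumericMatrix target) {
  if (mobile.nrow() != target.nrow()) stop("coordinate sets differ in length");
  arma::mat P(mobile.begin(), mobile.nrow(), 3, false);
  arma::mat Q(target.begin(), target.nrow(), 3, false);
  arma::mat R;
  arma::vec t;
  double rmsd;
  kabsch_core(P, Q, R, t, rmsd);
  return List::create(_["rotation"] = wrap(R), _["translation"] = wrap(t),
                      _["rmsd"] = rmsd);
}

// TM-score for a fixed residue-i <-> residue-i correspondence, maximised
// over seed-fragment superpositions with iterative subset refinement
// (the standard fragment-seeded search: windows of length L, L/2, ... 4).
// [[Rcpp::export]]
double cpp_tm_fixed(NumericMatrix query, NumericMatrix templ, double d0,
                    int step_div = 4) {
  const int L = query.nrow();
  if (templ.nrow() != L) stop("structures differ in length");
  arma::mat Q(query.begin(), L, 3, false);   // mobile
  arma::mat T(templ.begin(), L, 3, false);   // fixed
  const double d02 = d0 * d0;
  const double dcut0 = std::min(std::max(d0, 4.5), 8.0);

  std::vector<int> lens;
  for (int l = L; l >= 4; l /= 2) lens.push_back(l);
  double best = 0.0;
  arma::mat R;
  arma::vec t;
  double rmsd;
  std::vector<double> di(L);

  for (size_t li = 0; li < lens.size(); ++li) {
    const int l = lens[li];
    const int step = std::max(l / std::max(step_div, 1), 1);
    for (int start = 0; start + l <= L; start += step) {
      std::vector<int> sel(l);
      for (int k = 0; k < l; ++k) sel[k] = start + k;
      std::vector<int> prev;
      for (int iter = 0; iter < 30; ++iter) {
        arma::mat Ps(sel.size(), 3), Qs(sel.size(), 3);
        for (size_t k = 0; k < sel.size(); ++k) {
          Ps.row(k) = Q.row(sel[k]);
          Qs.row(k) = T.row(sel[k]);
        }
        kabsch_core(Ps, Qs, R, t, rmsd);
        const arma::mat Qr = Q * R.t();  // rotated query, rows are points
        double score = 0.0;
        for (int i = 0; i < L; ++i) {
          const double dx = Qr(i, 0) + t(0) - T(i, 0);
          const double dy = Qr(i, 1) + t(1) - T(i, 1);
          const double dz = Qr(i, 2) + t(2) - T(i, 2);
          const double d2 = dx * dx + dy * dy + dz * dz;
          di[i] = std::sqrt(d2);
          score += 1.0 / (1.0 + d2 / d02);
        }
        score /= (double)L;
        if (score > best) best = score;
        double dcut = dcut0;
        std::vector<int> nsel;
        for (;;) {
          nsel.clear();
          for (int i = 0; i < L; ++i) if (di[i] < dcut) nsel.push_back(i);
          if ((int)nsel.size() >= 3) break;
          dcut += 0.5;
        }
        if (nsel == prev || nsel == sel) break;
        prev = sel;
        sel = nsel;
      }
    }
  }
  return best;
}
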