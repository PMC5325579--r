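// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Monthly integration of the eight-pool litter/SOM network.
//
// C0       : initial masses (8), pool order fixed by the R side
// kbase    : per-month base rate coefficients (k0/12 * texture * lignin), 8
// defac    : monthly abiotic factor, length n
// mult     : monthly management multiplier on active+slow decay, length n
// inputs   : n x 8 matrix of litter inputs (Mg C ha-1 mo-1), added with the
//            step, not decayed within the month they arrive
// flow     : 8 x 8 matrix, flow(i,j) = fraction of decomposed C from pool i
//            entering pool j
// co2frac  : respired fraction per source pool, 8
// method   : 0 = Euler, 1 = Crank-Nicolson
// mm       : if true, multiply active+slow rates by vmax*C_MR/(km+C_MR),
//            C_MR = soil metabolic mass at month start (lagged, keeps the
//            monthly step linear)
// ia,is,im : 0-based indices of active, slow and soil-metabolic pools
//
// Returns trajectory ((n+1) x 8) and monthly CO2 flux (n).
// [[Rcpp::export]]
List sim_pools_cpp(const arma::vec& C0, const arma::vec& kbase,
                   const arma::vec& defac, const arma::vec& mult,
                   const arma::mat& inputs, const arma::mat& flow,
                   const arma::vec& co2frac, int method,
                   bool mm, double vmax, double km,
                   int ia, int is, int im,
                   CharacterVector pool_names) {
  const int np = C0.n_elem;
  const int n = defac.n_elem;
  arma::mat traj(n + 1, np);
  arma::vec co2(n);
  arma::vec C = C0;
  traj.row(0) = C.t();
  arma::mat I = arma::eye(np, np);
  arma::mat M(np, np);

  for (int m = 0; m < n; ++m) {
    arma::vec k = kbase * defac(m);
    double g = mult(m);
    if (mm) {
      double cmr = C(im);
      g *= vmax * cmr / (km + cmr);
    }
    k(ia) *= g;
    k(is) *= g;

    // M(j,i) = flow(i,j)*k(i) for i != j, diagonal -k(j)
    M.zeros();
    for (int i = 0; i < np; ++i) {
      for (int j = 0; j < np; ++j) {
        if (i == j) continue;
        if (flow(i, j) != 0.0) M(j, i) = flow(i, j) * k(i);
      }
      M(i, i) = -k(i);
    }

    arma::vec u = inputs.row(m).t();
    arma::vec Cn;
    if (method == 0) {
      Cn = C + M * C + u;
      co2(m) = arma::dot(co2frac, k % C);
    } else {
      arma::mat A = I - 0.5 * M;
      arma::vec b = (I + 0.5 * M) * C + u;
      bool ok = arma::solve(Cn, A, b, arma::solve_opts::no_approx);
      if (!ok) stop("singular Crank-Nicolson system at month %d", m);
      co2(m) = arma::dot(co2frac, k % (0.5 * (C + Cn)));
    }
    for (int j = 0; j < np; ++j) {
      if (Cn(j) < -1e-10) {
        stop("integration instability: pool '%s' went negative (%.6g) at month %d; reduce rate coefficients or use the Crank-Nicolson integrator",
             std::string(pool_names[j]).c_str(), Cn(j), m);
      }
      if (Cn(j) < 0.0) Cn(j) = 0.0;
    }
    C = Cn;
    traj.row(m + 1) = C.t();
  }
  return List::create(_["trajectory"] = traj, _["co2"] = co2);
}
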