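// Forward simulation of the gene-expression SDE by Euler-Maruyama, with the
// running-mean convergence protocol, systematic knockout screens, and cell
// sampling.  The regulatory weights are passed as betaT (target x regulator),
// i.e. betaT(i, j) = beta[j -> i], so the synthesis input is alpha + betaT * x.

#include <RcppArmadillo.h>

#include "rng.h"

// [[Rcpp::depends(RcppArmadillo)]]

static ZigguratNormal zig;

struct Protocol {
  int burn_in;
  int check_every;
  int t_max;
  double tol;
};

static inline double sigmoid(double u) { return 1.0 / (1.0 + std::exp(-u)); }

// Advance one condition under the convergence protocol.  `ko_col` (-1 for
// none) drops regulator j's outgoing column of betaT, i.e. a gene knockout,
// without copying the matrix.  Returns the post-burn-in running mean.
//
// If `n_record > 0`, after the protocol finishes the trajectory is advanced
// a further n_record steps from the final state and each state is stored as
// a column of `record` (used for sampling "cells").
static void run_condition(const arma::sp_mat& betaT, const arma::vec& alpha,
                          const arma::vec& ell, double s, double dt,
                          const Protocol& pr, arma::vec x, Xoshiro256pp& rng,
                          arma::vec& xbar, bool& converged, int& iters,
                          int ko_col = -1, int n_record = 0,
                          arma::mat* record = nullptr) {
  const arma::uword n = alpha.n_elem;
  const double* vals = betaT.values;
  const arma::uword* rows = betaT.row_indices;
  const arma::uword* colp = betaT.col_ptrs;

  arma::vec u(n), sum(n, arma::fill::zeros), prev_mean(n), cur_mean(n);
  const double sq = s * std::sqrt(dt);
  bool have_prev = false;
  converged = false;

  auto do_step = [&](int t) {
    u = alpha;
    for (arma::uword j = 0; j < n; ++j) {
      if (static_cast<int>(j) == ko_col) continue;
      const double xj = x[j];
      if (xj == 0.0) continue;
      for (arma::uword k = colp[j]; k < colp[j + 1]; ++k) u[rows[k]] += vals[k] * xj;
    }
    if (s > 0.0) {
      for (arma::uword i = 0; i < n; ++i) {
        double xi = x[i] + dt * (sigmoid(u[i]) - ell[i] * x[i]) +
                    sq * std::sqrt(x[i]) * zig.draw(rng);
        if (xi < 0.0) xi = 0.0;
        x[i] = xi;
      }
    } else {
      for (arma::uword i = 0; i < n; ++i) {
        double xi = x[i] + dt * (sigmoid(u[i]) - ell[i] * x[i]);
        if (xi < 0.0) xi = 0.0;
        x[i] = xi;
      }
    }
    if (!x.is_finite())
      Rcpp::stop("non-finite expression state at iteration %d", t);
  };

  int t = 0;
  while (t < pr.t_max) {
    ++t;
    do_step(t);
    if (t > pr.burn_in) {
      sum += x;
      if ((t - pr.burn_in) % pr.check_every == 0) {
        cur_mean = sum / static_cast<double>(t - pr.burn_in);
        if (have_prev) {
          double maxlfc = 0.0;  // vacuous max (all-silent network) => converged
          for (arma::uword i = 0; i < n; ++i) {
            if (cur_mean[i] > s) {
              const double d = std::fabs(std::log2(cur_mean[i] / prev_mean[i]));
              if (d > maxlfc) maxlfc = d;
            }
          }
          if (maxlfc < pr.tol) {
            converged = true;
            break;
          }
        }
        prev_mean = cur_mean;
        have_prev = true;
      }
    }
  }
  iters = t;
  xbar = (t > pr.burn_in) ? arma::vec(sum / static_cast<double>(t - pr.burn_in))
                          : x;  // degenerate configs: no post-burn-in steps

  if (n_record > 0 && record != nullptr) {
    record->set_size(n, n_record);
    for (int m = 0; m < n_record; ++m) {
      do_step(pr.t_max + m + 1);
      record->col(m) = x;
    }
  }
}

// All entry points seed their generator as grn_stream_seed(seed, stream):
// stream 0 is the default; the screen assigns stream j to knockout j, so a
// one-at-a-time run with the matching stream reproduces a screen column.

// [[Rcpp::export]]
Rcpp::List cpp_simulate(const arma::sp_mat& betaT, const arma::vec& alpha,
                        const arma::vec& ell, double s, double dt, int burn_in,
                        int check_every, int t_max, double tol,
                        const arma::vec& init, double seed, double stream = 0,
                        int ko_col = -1) {
  Protocol pr{burn_in, check_every, t_max, tol};
  Xoshiro256pp rng(grn_stream_seed(static_cast<uint64_t>(seed),
                                   static_cast<uint64_t>(stream)));
  arma::vec xbar;
  bool conv;
  int iters;
  run_condition(betaT, alpha, ell, s, dt, pr, init, rng, xbar, conv, iters, ko_col);
  return Rcpp::List::create(Rcpp::Named("xbar") = xbar,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("iterations") = iters);
}

// Knockout screen: per gene j, re-equilibrate from `init` (the baseline
// steady state) with regulator j's outgoing effects nullified.  Column j of
// the returned matrix is the running-mean steady state under knockout of j.
// Each knockout uses an independent stream derived from (seed, j).
// [[Rcpp::export]]
Rcpp::List cpp_screen(const arma::sp_mat& betaT, const arma::vec& alpha,
                      const arma::vec& ell, double s, double dt, int burn_in,
                      int check_every, int t_max, double tol,
                      const arma::vec& init, double seed) {
  const int n = static_cast<int>(alpha.n_elem);
  Protocol pr{burn_in, check_every, t_max, tol};
  arma::mat xbar_ko(n, n);
  Rcpp::LogicalVector conv(n);
  Rcpp::IntegerVector iters(n);

  for (int j = 0; j < n; ++j) {
    Xoshiro256pp rng(grn_stream_seed(static_cast<uint64_t>(seed),
                                     static_cast<uint64_t>(j)));
    arma::vec xbar;
    bool cv;
    int it;
    run_condition(betaT, alpha, ell, s, dt, pr, init, rng, xbar, cv, it, j);
    xbar_ko.col(j) = xbar;
    conv[j] = cv;
    iters[j] = it;
    if (j % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("xbar_ko") = xbar_ko,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("iterations") = iters);
}

// Record `n_steps` consecutive states starting from `init` (one per column).
// [[Rcpp::export]]
arma::mat cpp_record_steps(const arma::sp_mat& betaT, const arma::vec& alpha,
                           const arma::vec& ell, double s, double dt,
                           const arma::vec& init, int n_steps, double seed,
                           double stream = 0, int ko_col = -1) {
  Protocol pr{0, 1, 0, 0.0};  // no equilibration phase
  Xoshiro256pp rng(grn_stream_seed(static_cast<uint64_t>(seed),
                                   static_cast<uint64_t>(stream)));
  arma::vec xbar;
  bool conv;
  int iters;
  arma::mat rec;
  run_condition(betaT, alpha, ell, s, dt, pr, init, rng, xbar, conv, iters,
                ko_col, n_steps, &rec);
  return rec;
}

// Re-equilibrate under an optional knockout, then record n_record further
// states from the converged trajectory (cells from stationary dynamics).
// [[Rcpp::export]]
Rcpp::List cpp_equilibrate_record(const arma::sp_mat& betaT,
                                  const arma::vec& alpha, const arma::vec& ell,
                                  double s, double dt, int burn_in,
                                  int check_every, int t_max, double tol,
                                  const arma::vec& init, double seed,
                                  double stream, int ko_col, int n_record) {
  Protocol pr{burn_in, check_every, t_max, tol};
  Xoshiro256pp rng(grn_stream_seed(static_cast<uint64_t>(seed),
                                   static_cast<uint64_t>(stream)));
  arma::vec xbar;
  bool conv;
  int iters;
  arma::mat rec;
  run_condition(betaT, alpha, ell, s, dt, pr, init, rng, xbar, conv, iters,
                ko_col, n_record, &rec);
  return Rcpp::List::create(
      Rcpp::Named("xbar") = xbar, Rcpp::Named("converged") = conv,
      Rcpp::Named("iterations") = iters, Rcpp::Named("cells") = rec);
}

// Raw standard-normal draws from the internal generator (for calibration
// tests of the noise source).
// [[Rcpp::export]]
arma::vec cpp_normal_draws(int n, double seed) {
  Xoshiro256pp rng(static_cast<uint64_t>(seed));
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z[i] = zig.draw(rng);
  return z;
}

// [[Rcpp::export]]
arma::vec cpp_uniform_draws(int n, double seed) {
  Xoshiro256pp rng(static_cast<uint64_t>(seed));
  arma::vec u(n);
  for (int i = 0; i < n; ++i) u[i] = rng.unif();
  return u;
}
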