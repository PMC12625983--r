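// Compiled trajectory runner for the restricted-diffusion drift step.
// Semantics mirror the R reference implementation in R/drift.R exactly:
// free columns get i.i.d. increments, inactive/saturated coordinates of
// stored conditions are clamped at their threshold with transitions into
// the engaged set, engaged coordinates move inside the kernel of the
// engaged readout submatrix with gamma-rescaling at threshold events, and
// the per-row weight-norm bound acts as a rejection boundary cascading to
// engaged blocks that contained a rejected row.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// orthonormal kernel basis of the Nz x ne engaged submatrix (ne > Nz)
static mat kernel_basis(const mat& Wmu) {
  mat Q, R;
  qr(Q, R, Wmu.t());
  return Q.cols(Wmu.n_rows, Wmu.n_cols - 1);
}

// [[Rcpp::export(name = ".drift_run_cpp")]]
Rcpp::List drift_run_cpp(arma::mat eta, arma::imat lab,
                         const arma::uvec& learned1,
                         const arma::mat& Xinv, const arma::vec& scales,
                         const arma::mat& W, const arma::vec& b,
                         const arma::mat& Zl, double alpha, double sigma,
                         double Umax, int n_steps,
                         const arma::uvec& rec_steps1, double cons_tol,
                         bool track_dU) {
  const uword Ny = eta.n_rows, Nx = eta.n_cols, Nz = W.n_rows;
  const uvec learned = learned1 - 1;  // 0-based
  const bool bounded = std::isfinite(Umax);
  const double Umax2 = Umax * Umax * (1.0 + 1e-12);

  std::vector<bool> is_learned(Nx, false);
  for (uword k = 0; k < learned.n_elem; ++k) is_learned[learned[k]] = true;
  uvec free_cols(Nx);
  uword nfree = 0;
  for (uword j = 0; j < Nx; ++j) if (!is_learned[j]) free_cols[nfree++] = j;
  free_cols.resize(nfree);

  // kernel cache per learned column
  std::vector<uvec> k_set(Nx);
  std::vector<mat> k_mat(Nx);
  std::vector<bool> k_valid(Nx, false);

  const uword n_rec = rec_steps1.n_elem + 1;  // step 0 plus requested steps
  cube snaps(Ny, Nx, n_rec);
  mat fractions(n_rec, 3);
  mat row_norms(n_rec, Ny);
  vec readout_error(n_rec, fill::zeros);
  vec zhat_drift(n_rec, fill::zeros);
  long long n_transitions = 0;
  double dU_sum = 0.0, dU_sumsq = 0.0;
  long long dU_n = 0;

  mat zhat0;
  auto zhat_of = [&](const mat& e) -> mat {
    if (learned.n_elem == 0) return mat(Nz, 0);
    mat C = e.cols(learned);
    C.each_col() += b;
    return W * clamp(C, 0.0, alpha);
  };
  zhat0 = zhat_of(eta);

  auto record = [&](uword k) {
    snaps.slice(k) = eta;
    double ni = 0, ne_ = 0, ns = 0;
    if (learned.n_elem > 0) {
      for (uword m = 0; m < learned.n_elem; ++m)
        for (uword i = 0; i < Ny; ++i) {
          int l = lab(i, learned[m]);
          if (l == 1) ++ni; else if (l == 2) ++ne_; else ++ns;
        }
      double tot = ni + ne_ + ns;
      fractions(k, 0) = ni / tot; fractions(k, 1) = ne_ / tot;
      fractions(k, 2) = ns / tot;
    } else {
      fractions.row(k).fill(datum::nan);
    }
    mat U = eta * Xinv;
    row_norms.row(k) = sqrt(sum(square(U), 1)).t();
    if (learned.n_elem > 0) {
      mat zh = zhat_of(eta);
      readout_error(k) = abs(zh - Zl).max();
      zhat_drift(k) = abs(zh - zhat0).max();
    }
  };

  mat U_prev;
  if (track_dU) U_prev = eta * Xinv;

  record(0);
  uword rec_idx = 0;

  mat eta0 = eta;
  imat lab0 = lab;
  std::vector<uvec> eng_sets(Nx);
  std::vector<bool> eng_updated(Nx, false);

  for (int step = 1; step <= n_steps; ++step) {
    eta0 = eta;
    lab0 = lab;
    for (uword j = 0; j < Nx; ++j) eng_updated[j] = false;

    for (uword f = 0; f < nfree; ++f) {
      uword j = free_cols[f];
      double s = sigma * scales[j];
      for (uword i = 0; i < Ny; ++i) eta(i, j) += R::rnorm(0.0, 1.0) * s;
    }

    for (uword m = 0; m < learned.n_elem; ++m) {
      uword mu = learned[m];
      double smu = sigma * scales[mu];
      // inactive set
      for (uword i = 0; i < Ny; ++i) {
        if (lab0(i, mu) != 1) continue;
        double newv = eta0(i, mu) + R::rnorm(0.0, 1.0) * smu;
        if (newv + b[i] > 0.0) { eta(i, mu) = -b[i]; lab(i, mu) = 2; }
        else eta(i, mu) = newv;
      }
      // saturated set
      for (uword i = 0; i < Ny; ++i) {
        if (lab0(i, mu) != 3) continue;
        double newv = eta0(i, mu) + R::rnorm(0.0, 1.0) * smu;
        if (newv + b[i] < alpha) { eta(i, mu) = alpha - b[i]; lab(i, mu) = 2; }
        else eta(i, mu) = newv;
      }
      // engaged set
      uvec ie = find(lab0.col(mu) == 2);
      uword ne = ie.n_elem;
      if (ne > Nz) {
        if (!k_valid[mu] || k_set[mu].n_elem != ne ||
            any(k_set[mu] != ie)) {
          k_set[mu] = ie;
          k_mat[mu] = kernel_basis(W.cols(ie));
          k_valid[mu] = true;
        }
        vec c(ne - Nz);
        for (uword q = 0; q < ne - Nz; ++q) c[q] = R::rnorm(0.0, 1.0) * smu;
        vec d = k_mat[mu] * c;
        // largest gamma in [0, 1] keeping all currents inside [0, alpha]
        double graw = datum::inf;
        for (uword q = 0; q < ne; ++q) {
          double cur = eta0(ie[q], mu) + b[ie[q]];
          double g;
          if (d[q] > 0) g = (alpha - cur) / d[q];
          else if (d[q] < 0) g = -cur / d[q];
          else continue;
          if (g < graw) graw = g;
        }
        double gamma;
        bool has_cross = std::isfinite(graw) && graw <= 1.0;
        gamma = has_cross ? std::max(0.0, graw) : 1.0;
        for (uword q = 0; q < ne; ++q)
          eta(ie[q], mu) = eta0(ie[q], mu) + gamma * d[q];
        if (has_cross) {
          double tie = graw + 1e-12 * std::max(1.0, gamma);
          for (uword q = 0; q < ne; ++q) {
            double g;
            if (d[q] > 0) g = (alpha - (eta0(ie[q], mu) + b[ie[q]])) / d[q];
            else if (d[q] < 0) g = -(eta0(ie[q], mu) + b[ie[q]]) / d[q];
            else continue;
            if (g <= tie) {
              if (d[q] > 0) { eta(ie[q], mu) = alpha - b[ie[q]]; lab(ie[q], mu) = 3; }
              else          { eta(ie[q], mu) = -b[ie[q]];        lab(ie[q], mu) = 1; }
            }
          }
        }
        eng_sets[mu] = ie;
        eng_updated[mu] = true;
      }
    }

    // per-row norm bound: reject rows, cascade to engaged blocks
    if (bounded) {
      std::vector<bool> rejected(Ny, false);
      for (;;) {
        mat U = eta * Xinv;
        vec rn2 = sum(square(U), 1);
        bool any_new = false;
        for (uword i = 0; i < Ny; ++i) {
          if (rejected[i] || rn2[i] <= Umax2) continue;
          rejected[i] = true;
          any_new = true;
          eta.row(i) = eta0.row(i);
          if (lab.n_cols > 0) lab.row(i) = lab0.row(i);
          for (uword m = 0; m < learned.n_elem; ++m) {
            uword mu = learned[m];
            if (!eng_updated[mu]) continue;
            const uvec& ie = eng_sets[mu];
            bool hit = false;
            for (uword q = 0; q < ie.n_elem; ++q)
              if (ie[q] == i) { hit = true; break; }
            if (hit) {
              for (uword q = 0; q < ie.n_elem; ++q) {
                eta(ie[q], mu) = eta0(ie[q], mu);
                lab(ie[q], mu) = lab0(ie[q], mu);
              }
              eng_updated[mu] = false;
            }
          }
        }
        if (!any_new) break;
      }
    }

    for (uword j = 0; j < lab.n_cols; ++j)
      for (uword i = 0; i < Ny; ++i)
        if (lab(i, j) != lab0(i, j)) ++n_transitions;

    if (track_dU) {
      mat U_now = eta * Xinv;
      mat dU = U_now - U_prev;
      dU_sum += accu(dU);
      dU_sumsq += accu(square(dU));
      dU_n += dU.n_elem;
      U_prev = U_now;
    }

    if (rec_idx < rec_steps1.n_elem &&
        (uword)step == rec_steps1[rec_idx]) {
      ++rec_idx;
      record(rec_idx);
      if (learned.n_elem > 0 && zhat_drift(rec_idx) > cons_tol)
        Rcpp::stop("readout conservation violated at step %d: cumulative readout change %g > %g",
                   step, zhat_drift(rec_idx), cons_tol);
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("eta") = eta,
    Rcpp::Named("labels") = lab,
    Rcpp::Named("snaps") = snaps,
    Rcpp::Named("fractions") = fractions,
    Rcpp::Named("row_norms") = row_norms,
    Rcpp::Named("readout_error") = readout_error,
    Rcpp::Named("zhat_drift") = zhat_drift,
    Rcpp::Named("n_transitions") = (double)n_transitions,
    Rcpp::Named("dU_n") = (double)dU_n,
    Rcpp::Named("dU_sum") = dU_sum,
    Rcpp::Named("dU_sumsq") = dU_sumsq);
}
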