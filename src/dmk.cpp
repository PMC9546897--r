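// Dynamical Monge-Kantorovich solver on complete bipartite transport problems.
//
// The system solved per edge of the input graph is
//   f_i = sum_e B_ie (mu_e / w_e) (B^T u)_e          (Kirchhoff)
//   mu' = ( (mu/w) |B^T u| )^beta - mu               (conductivity dynamics)
// discretized with explicit Euler.  The bipartite structure (all edges run
// left -> right) lets the Laplacian solve reduce, via the Schur complement of
// the diagonal left block, to a dense SPD system on the right side only; the
// caller orients the problem so that side is the smaller one.  The singular
// direction (constant potentials) is removed by a ground-node penalty on the
// first right node, which is exact because the forcing sums to zero.
//
// In the branched regime (beta > 1) most conductivities collapse to the
// floor and never recover (mu' ~ -mu there); edges sitting on the floor for
// 20 consecutive steps are frozen out of the solve, and once few edges
// remain active the Schur complement is accumulated sparsely.  An edge is
// never frozen if it is the last active edge of a node carrying mass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double MU_FLOOR = 1e-14;
static const int FREEZE_AFTER = 20;
static const double DENSE_FRAC = 0.4;

struct DMKWork {
  arma::mat t, M, S, q;
  arma::vec Da, Db, rhs, uL, uR;
  std::vector<uint16_t> floor_count;
  std::vector<uint8_t> inactive;
  std::vector<std::vector<int>> act;   // per left row: active column indices
  std::vector<int> row_active, col_active;
  int n_active;
  bool dirty;

  void init(arma::uword nL, arma::uword nR) {
    t.zeros(nL, nR); M.set_size(nL, nR); S.set_size(nR, nR);
    q.zeros(nL, nR);
    Da.set_size(nL); Db.set_size(nR); rhs.set_size(nR);
    uL.set_size(nL); uR.set_size(nR);
    floor_count.assign(nL * nR, 0);
    inactive.assign(nL * nR, 0);
    act.assign(nL, {});
    row_active.assign(nL, (int)nR);
    col_active.assign(nR, (int)nL);
    n_active = (int)(nL * nR);
    dirty = true;
  }
  void rebuild_act(arma::uword nL, arma::uword nR) {
    for (arma::uword k = 0; k < nL; ++k) {
      act[k].clear();
      for (arma::uword l = 0; l < nR; ++l)
        if (!inactive[l * nL + k]) act[k].push_back((int)l);
    }
    dirty = false;
  }
};

// Kirchhoff solve on the full dense conductance matrix ws.t.
static bool solve_dense(const arma::vec& fL, const arma::vec& fR, DMKWork& ws) {
  const arma::uword nL = ws.t.n_rows, nR = ws.t.n_cols;
  ws.Da.zeros(); ws.Db.zeros();
  const double* tp = ws.t.memptr();
  for (arma::uword l = 0; l < nR; ++l)
    for (arma::uword k = 0; k < nL; ++k) {
      double v = tp[l * nL + k];
      ws.Da(k) += v; ws.Db(l) += v;
    }
  for (arma::uword k = 0; k < nL; ++k)
    if (ws.Da(k) < 1e-300) ws.Da(k) = 1e-300;

  ws.M = ws.t.each_col() / ws.Da;
  ws.S = ws.t.t() * ws.M;          // symmetric; = T^T Da^{-1} T
  ws.S *= -1.0;
  ws.S.diag() += ws.Db;
  ws.rhs = fR + ws.M.t() * fL;
  ws.S(0, 0) += std::max(ws.Db.max(), 1.0);   // ground node
  for (arma::uword l = 0; l < nR; ++l)
    if (ws.Db(l) <= 1e-290) ws.S(l, l) += 1.0;

  if (!arma::solve(ws.uR, arma::symmatu(ws.S), ws.rhs,
                   arma::solve_opts::likely_sympd + arma::solve_opts::no_approx)) {
    ws.S.diag() += 1e-12 * (arma::trace(ws.S) / nR + 1.0);
    if (!arma::solve(ws.uR, arma::symmatu(ws.S), ws.rhs)) return false;
  }
  ws.uL = (fL + ws.t * ws.uR) / ws.Da;
  return true;
}

// Kirchhoff solve accumulating the Schur complement over active edges only.
static bool solve_sparse(const arma::vec& fL, const arma::vec& fR, DMKWork& ws) {
  const arma::uword nL = ws.t.n_rows, nR = ws.t.n_cols;
  if (ws.dirty) ws.rebuild_act(nL, nR);
  ws.Da.zeros(); ws.Db.zeros();
  ws.S.zeros();
  ws.rhs = fR;
  const double* tp = ws.t.memptr();
  for (arma::uword k = 0; k < nL; ++k) {
    double da = 0.0;
    for (int l : ws.act[k]) da += tp[(arma::uword)l * nL + k];
    if (da < 1e-300) da = 1e-300;
    ws.Da(k) = da;
    const double fk = fL(k) / da;
    for (int a : ws.act[k]) {
      const double ta = tp[(arma::uword)a * nL + k];
      ws.Db(a) += ta;
      ws.rhs(a) += fk * ta;
      const double ta_da = ta / da;
      for (int b : ws.act[k]) {
        ws.S(a, b) -= ta_da * tp[(arma::uword)b * nL + k];
      }
    }
  }
  ws.S.diag() += ws.Db;
  ws.S(0, 0) += std::max(ws.Db.max(), 1.0);
  for (arma::uword l = 0; l < nR; ++l)
    if (ws.Db(l) <= 1e-290) ws.S(l, l) += 1.0;

  if (!arma::solve(ws.uR, arma::symmatu(ws.S), ws.rhs,
                   arma::solve_opts::likely_sympd + arma::solve_opts::no_approx)) {
    ws.S.diag() += 1e-12 * (arma::trace(ws.S) / nR + 1.0);
    if (!arma::solve(ws.uR, arma::symmatu(ws.S), ws.rhs)) return false;
  }
  for (arma::uword k = 0; k < nL; ++k) {
    double s = fL(k);
    for (int l : ws.act[k]) s += tp[(arma::uword)l * nL + k] * ws.uR(l);
    ws.uL(k) = s / ws.Da(k);
  }
  return true;
}

// Core integrator.  mu (nL x nR) is the initial state and is overwritten
// with the steady state; ws.q holds the final flux (0 on frozen edges).
static bool dmk_core(const arma::mat& w, const arma::vec& fL,
                     const arma::vec& fR, double beta, double dt, double tol,
                     int max_steps, arma::mat& mu, DMKWork& ws,
                     int& steps_out, double& residual_out) {
  const arma::uword nL = mu.n_rows, nR = mu.n_cols;
  const arma::uword n_el = mu.n_elem;
  const bool can_prune = beta > 1.0;
  ws.init(nL, nR);
  bool converged = false;
  int stable = 0, step = 0;
  double cost_prev = -1.0, resid = arma::datum::inf;
  const double* wp = w.memptr();
  double* mup = mu.memptr();
  double* tp = ws.t.memptr();
  double* qp = ws.q.memptr();

  for (step = 0; step < max_steps; ++step) {
    const bool sparse = can_prune &&
      ws.n_active < DENSE_FRAC * (double)n_el;
    for (arma::uword e = 0; e < n_el; ++e)
      if (!ws.inactive[e]) tp[e] = mup[e] / wp[e];
      else tp[e] = 0.0;
    bool ok = sparse ? solve_sparse(fL, fR, ws) : solve_dense(fL, fR, ws);
    if (!ok) Rcpp::stop("DMK Laplacian solve failed at step %d", step + 1);

    double cost = 0.0, resid_max = 0.0, mu_max = 0.0;
    const double* uLp = ws.uL.memptr();
    const double* uRp = ws.uR.memptr();
    for (arma::uword l = 0; l < nR; ++l) {
      const double ur = uRp[l];
      for (arma::uword k = 0; k < nL; ++k) {
        const arma::uword e = l * nL + k;
        if (ws.inactive[e]) continue;
        double qv = tp[e] * std::fabs(uLp[k] - ur);
        qp[e] = qv;
        cost += qv * wp[e];
        double qb = (beta == 1.0) ? qv
                  : (beta == 2.0) ? qv * qv
                  : std::pow(qv, beta);
        double m = mup[e];
        if (m > mu_max) mu_max = m;
        double r = std::fabs(qb - m);
        if (r > resid_max) resid_max = r;
        double mn = m + dt * (qb - m);
        if (mn > MU_FLOOR) {
          mup[e] = mn;
          ws.floor_count[e] = 0;
        } else {
          mup[e] = MU_FLOOR;
          if (can_prune && ++ws.floor_count[e] >= FREEZE_AFTER) {
            // keep the last active edge of any node carrying mass
            bool keep = (fL(k) != 0.0 && ws.row_active[k] <= 1) ||
                        (fR(l) != 0.0 && ws.col_active[l] <= 1);
            if (!keep) {
              ws.inactive[e] = 1;
              ws.floor_count[e] = 0;
              --ws.row_active[k]; --ws.col_active[l]; --ws.n_active;
              qp[e] = 0.0;
              ws.dirty = true;
            }
          }
        }
      }
    }
    resid = resid_max / std::max(1.0, mu_max);
    bool cost_ok = cost_prev >= 0.0 &&
      std::fabs(cost - cost_prev) <= tol * std::max(cost_prev, 1e-30);
    cost_prev = cost;

    if (resid < tol && cost_ok) {
      if (++stable >= 10) { converged = true; ++step; break; }
    } else {
      stable = 0;
    }
  }

  // final flux from the settled conductivities
  {
    for (arma::uword e = 0; e < n_el; ++e)
      tp[e] = ws.inactive[e] ? 0.0 : mup[e] / wp[e];
    const bool sparse = can_prune &&
      ws.n_active < DENSE_FRAC * (double)n_el;
    bool ok = sparse ? solve_sparse(fL, fR, ws) : solve_dense(fL, fR, ws);
    if (!ok) Rcpp::stop("DMK Laplacian solve failed at final state");
    for (arma::uword l = 0; l < nR; ++l)
      for (arma::uword k = 0; k < nL; ++k) {
        const arma::uword e = l * nL + k;
        qp[e] = ws.inactive[e] ? 0.0
          : tp[e] * std::fabs(ws.uL(k) - ws.uR(l));
      }
  }
  steps_out = step;
  residual_out = resid;
  return converged;
}

// [[Rcpp::export]]
List dmk_solve_cpp(const arma::mat& cost_solver, const arma::mat& cost_true,
                   const arma::vec& source, const arma::vec& sink,
                   double beta, double dt, double tol, int max_steps,
                   Nullable<NumericMatrix> mu_init) {
  // orient so the dense solve runs on the smaller side
  const bool flip = cost_solver.n_cols > cost_solver.n_rows;
  arma::mat w = flip ? arma::mat(cost_solver.t()) : cost_solver;
  arma::vec fL = flip ? arma::vec(-sink) : arma::vec(source);
  arma::vec fR = flip ? arma::vec(source) : arma::vec(-sink);

  arma::mat mu(w.n_rows, w.n_cols, arma::fill::ones);
  if (mu_init.isNotNull()) {
    arma::mat m0 = as<arma::mat>(NumericMatrix(mu_init));
    if (flip) m0 = m0.t();
    mu = arma::clamp(m0, MU_FLOOR, arma::datum::inf);
  }
  DMKWork ws;
  int steps = 0;
  double residual = NA_REAL;
  bool conv = dmk_core(w, fL, fR, beta, dt, tol, max_steps, mu, ws,
                       steps, residual);

  // node balance of the signed flux against the forcing
  arma::mat grad = arma::repmat(ws.uL, 1, w.n_cols);
  grad.each_row() -= ws.uR.t();
  arma::mat signed_q = ws.t % grad;
  arma::vec balL = arma::sum(signed_q, 1) - fL;
  arma::vec balR = -arma::sum(signed_q, 0).t() - fR;
  double bal = std::max(arma::abs(balL).max(), arma::abs(balR).max());

  arma::mat flux = flip ? arma::mat(ws.q.t()) : ws.q;
  arma::mat mu_out = flip ? arma::mat(mu.t()) : mu;
  double cost = arma::accu(flux % cost_true);
  return List::create(_["flux"] = flux, _["cost"] = cost, _["converged"] = conv,
                      _["steps"] = steps, _["residual"] = residual,
                      _["balance_error"] = bal, _["mu"] = mu_out);
}

// Curvature sweep over many edges of a graph.  All indices 0-based.
// nbrs[v] lists the neighbors of v; dist is the (current) all-pairs
// shortest-path matrix; warm holds per-edge conductivity matrices from the
// previous Ricci-flow iteration (empty list or NULL entries = cold start).
// [[Rcpp::export]]
List dmk_wasserstein_batch_cpp(const IntegerMatrix& edges, const List& nbrs,
                               const arma::mat& dist, double alpha, double beta,
                               double dt, double tol, int max_steps,
                               double eps_cost, List warm) {
  const int m = edges.nrow();
  NumericVector wass(m);
  IntegerVector steps(m);
  LogicalVector conv(m);
  List warm_out(m);
  DMKWork ws;

  for (int e = 0; e < m; ++e) {
    int i = edges(e, 0), j = edges(e, 1);
    IntegerVector ni = nbrs[i], nj = nbrs[j];
    // orient so the left (eliminated) side is the larger one
    const bool flip = (nj.size() > ni.size());
    if (flip) std::swap(i, j);
    IntegerVector na = flip ? nj : ni, nb = flip ? ni : nj;

    std::vector<int> left(na.begin(), na.end());
    left.push_back(i);
    std::sort(left.begin(), left.end());
    std::vector<int> right(nb.begin(), nb.end());
    right.push_back(j);
    std::sort(right.begin(), right.end());
    const int nL = left.size(), nR = right.size();

    arma::vec src(nL), snk(nR);
    for (int k = 0; k < nL; ++k)
      src(k) = (left[k] == i) ? alpha : (1.0 - alpha) / na.size();
    for (int l = 0; l < nR; ++l)
      snk(l) = (right[l] == j) ? alpha : (1.0 - alpha) / nb.size();

    arma::mat ct(nL, nR), cs(nL, nR);
    for (int l = 0; l < nR; ++l)
      for (int k = 0; k < nL; ++k) {
        double d = dist(left[k], right[l]);
        ct(k, l) = d;
        cs(k, l) = (d > 0.0) ? d : eps_cost;
      }

    arma::mat mu(nL, nR, arma::fill::ones);
    if (warm.size() == m && !Rf_isNull(warm[e])) {
      arma::mat w0 = as<arma::mat>(warm[e]);
      if ((int)w0.n_rows == nL && (int)w0.n_cols == nR)
        mu = arma::clamp(w0, MU_FLOOR, arma::datum::inf);
    }

    int st = 0;
    double resid = 0.0;
    bool ok = dmk_core(cs, src, -snk, beta, dt, tol, max_steps, mu, ws,
                       st, resid);
    wass[e] = arma::accu(ws.q % ct);
    steps[e] = st;
    conv[e] = ok;
    warm_out[e] = wrap(mu);
  }
  return List::create(_["wasserstein"] = wass, _["steps"] = steps,
                      _["converged"] = conv, _["warm"] = warm_out);
}
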