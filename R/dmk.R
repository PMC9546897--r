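#' Configuration for the dynamical Monge-Kantorovich solver
#'
#' @param beta Traffic rate in `(0, 2]`.  `beta = 1` recovers the
#'   1-Wasserstein optimal transport; `beta < 1` spreads flux over many
#'   routes (congested transport), `beta > 1` consolidates it onto few
#'   (branched transport).
#' @param dt Explicit-Euler time step (must be `<= 0.5`).  For
#'   `beta >= 1.8` the solver internally halves it: the conductivity
#'   dynamics stiffen near the branched extreme.
#' @param tol Convergence tolerance: the stationarity residual of the
#'   conductivity dynamics, \eqn{\max_e |q_e^\beta - \mu_e|} scaled by the
#'   conductivity magnitude, must fall below `tol` while the relative cost
#'   change stays below `tol` for 10 consecutive steps.
#' @param max_steps Iteration cap; hitting it yields `converged = FALSE`
#'   with a warning, not an error.
#' @param mu0 Initial conductivity on every bipartite edge.
#' @param eps_cost Regularizer substituted for exactly-zero costs inside the
#'   solver (a zero length would sit in a denominator); reported costs
#'   always use the true zeros.
#' @return A list of class `dmk_config`.
#' @export
dmk_config <- function(beta = 1, dt = 0.1, tol = 1e-5, max_steps = 2000,
                       mu0 = 1, eps_cost = 1e-10) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0 || beta > 2) {
    stop("`beta` must be in (0, 2]", call. = FALSE)
  }
  stopifnot(dt > 0, dt <= 0.5, tol > 0, max_steps >= 1, mu0 > 0, eps_cost > 0)
  structure(list(beta = beta, dt = dt, tol = tol,
                 max_steps = as.integer(max_steps), mu0 = mu0,
                 eps_cost = eps_cost),
            class = "dmk_config")
}

as_dmk_config <- function(config) {
  if (inherits(config, "dmk_config")) return(config)
  do.call(dmk_config, as.list(config))
}

# time step actually used: halved in the stiff branched regime
effective_dt <- function(config) {
  if (config$beta >= 1.8) config$dt / 2 else config$dt
}

#' Solve a bipartite transport problem with the DMK dynamics
#'
#' Integrates the conductivity/potential system — Kirchhoff's law
#' \eqn{B \,\mathrm{diag}(\mu/w)\, B^T u = f} with forcing
#' \eqn{f = \text{source} - \text{sink}}, and the explicit-Euler update
#' \eqn{\mu \leftarrow \mu + dt\,(q^\beta - \mu)} with flux
#' \eqn{q_e = (\mu_e/w_e)|u_i - u_j|} — until the conductivities and the
#' transport cost stagnate.  At `beta = 1` the steady-state cost equals the
#' 1-Wasserstein optimum.
#'
#' @param problem A `bipartite_ot_problem` (see [build_local_ot_problem()]).
#' @param config A [dmk_config()].
#' @return A `transport_result`: list with `flux` (left x right matrix of
#'   nonnegative flux magnitudes), `cost` (the beta-Wasserstein cost
#'   \eqn{\sum_e q_e \omega_e} using the true costs), `converged`, `steps`,
#'   `residual`, and `balance_error` (worst node-balance violation).
#' @export
solve_dmk <- function(problem, config = dmk_config()) {
  stopifnot(inherits(problem, "bipartite_ot_problem"))
  config <- as_dmk_config(config)
  cost_true <- problem$cost
  cost_solver <- cost_true
  cost_solver[cost_solver == 0] <- config$eps_cost
  mu0 <- matrix(config$mu0, nrow = nrow(cost_true), ncol = ncol(cost_true))
  res <- dmk_solve_cpp(cost_solver, cost_true, problem$source, problem$sink,
                       config$beta, effective_dt(config), config$tol,
                       config$max_steps, mu0)
  if (!res$converged) {
    warning("DMK solver did not converge within ", config$max_steps,
            " steps (residual ", signif(res$residual, 3), ")", call. = FALSE)
  }
  flux <- res$flux
  dimnames(flux) <- dimnames(cost_true)
  structure(list(flux = flux, cost = res$cost, converged = res$converged,
                 steps = res$steps, residual = res$residual,
                 balance_error = res$balance_error,
                 left = problem$left, right = problem$right,
                 beta = config$beta),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat("<transport_result> beta =", x$beta, " cost =", signif(x$cost, 6),
      if (x$converged) "(converged," else "(NOT converged,",
      x$steps, "steps)\n")
  invisible(x)
}

#' Tidy the flux of a transport result
#'
#' @param x A `transport_result`.
#' @param ... Unused.
#' @return A tibble with columns `left`, `right`, `flux`.
#' @export
tidy.transport_result <- function(x, ...) {
  grid <- tidyr::expand_grid(left = x$left, right = x$right)
  grid$flux <- as.vector(t(x$flux))
  grid
}

#' Beta-Wasserstein cost of a transport result
#'
#' Inner product of the flux with the problem's true costs (exact zeros for
#' node-to-itself pairs, not the solver regularizer).
#'
#' @param result A `transport_result` produced from `problem`.
#' @param problem The `bipartite_ot_problem` it was solved on.
#' @return A nonnegative number.
#' @export
wasserstein_cost <- function(result, problem) {
  stopifnot(inherits(result, "transport_result"),
            inherits(problem, "bipartite_ot_problem"))
  if (!identical(result$left, problem$left) ||
      !identical(result$right, problem$right)) {
    stop("result and problem do not match", call. = FALSE)
  }
  sum(result$flux * problem$cost)
}

#' Exact optimal-transport cost by linear programming
#'
#' Solves the balanced transportation problem
#' \eqn{\min_q \sum_{k\ell} q_{k\ell} c_{k\ell}} subject to the marginal
#' constraints, by successive shortest augmenting paths on the residual
#' network (exact up to floating point; no regularization).  Used as the
#' reference optimum the DMK solver is checked against at `beta = 1`.
#'
#' @param problem A `bipartite_ot_problem`.
#' @return The minimum transport cost.
#' @export
lp_transport_cost <- function(problem) {
  stopifnot(inherits(problem, "bipartite_ot_problem"))
  transport_ssp(problem$cost, problem$source, problem$sink)$cost
}

# Successive-shortest-paths solver for the balanced transportation problem.
# Multi-source Bellman-Ford on the residual bipartite graph; each
# augmentation ships as much as the path allows.  Exact (no regularization).
transport_ssp <- function(cost, supply, demand, tol = 1e-12) {
  m <- length(supply); n <- length(demand)
  stopifnot(nrow(cost) == m, ncol(cost) == n)
  if (abs(sum(supply) - sum(demand)) > 1e-9) {
    stop("unbalanced transport problem: supplies and demands differ",
         call. = FALSE)
  }
  plan <- matrix(0, m, n)
  sup <- as.numeric(supply); dem <- as.numeric(demand)
  guard <- 0
  while (sum(sup) > tol) {
    guard <- guard + 1
    if (guard > 50 * (m + n) + 1000) {
      stop("transport LP failed to terminate (degenerate instance?)",
           call. = FALSE)
    }
    # Bellman-Ford from all supply nodes with remaining mass.
    # Node ids: 1..m supplies, m+1..m+n demands.
    dist <- rep(Inf, m + n)
    pred <- rep(NA_integer_, m + n)
    dist[seq_len(m)][sup > tol] <- 0
    for (pass in seq_len(m + n)) {
      changed <- FALSE
      for (k in seq_len(m)) {
        if (!is.finite(dist[k])) next
        nd <- dist[k] + cost[k, ]
        upd <- nd < dist[m + seq_len(n)] - 1e-15
        if (any(upd)) {
          dist[m + which(upd)] <- nd[upd]
          pred[m + which(upd)] <- k
          changed <- TRUE
        }
      }
      for (l in seq_len(n)) {
        if (!is.finite(dist[m + l])) next
        back <- which(plan[, l] > tol)
        if (length(back) == 0) next
        nd <- dist[m + l] - cost[back, l]
        upd <- nd < dist[back] - 1e-15
        if (any(upd)) {
          dist[back[upd]] <- nd[upd]
          pred[back[upd]] <- m + l
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    dests <- which(dem > tol)
    if (length(dests) == 0) break
    dl <- dests[which.min(dist[m + dests])]
    if (!is.finite(dist[m + dl])) {
      stop("infeasible transport problem: demand unreachable", call. = FALSE)
    }
    # walk the path back, find bottleneck
    path <- integer(0)
    cur <- m + dl
    while (!is.na(pred[cur])) {
      path <- c(cur, path)
      cur <- pred[cur]
    }
    path <- c(cur, path)          # starts at a supply node
    amt <- min(sup[path[1]], dem[dl])
    if (length(path) > 2) {
      for (s in seq(2, length(path) - 1, by = 2)) {
        # backward arcs demand -> supply carry existing flow
        l <- path[s] - m; k <- path[s + 1]
        amt <- min(amt, plan[k, l])
      }
    }
    for (s in seq(1, length(path) - 1, by = 2)) {
      k <- path[s]; l <- path[s + 1] - m
      plan[k, l] <- plan[k, l] + amt
      if (s + 2 <= length(path)) {
        k2 <- path[s + 2]
        plan[k2, l] <- plan[k2, l] - amt
      }
    }
    sup[path[1]] <- sup[path[1]] - amt
    dem[dl] <- dem[dl] - amt
  }
  list(cost = sum(plan * cost), plan = plan)
}

#' Entropically regularized transport cost (Sinkhorn)
#'
#' Log-domain Sinkhorn iterations for the regularized transport problem;
#' the returned cost is \eqn{\langle P, C\rangle} for the regularized plan
#' P and converges to [lp_transport_cost()] as `reg` shrinks.  Also the
#' transport engine of the `"sinkhorn"` flow baseline in [run_flow()].
#'
#' @param problem A `bipartite_ot_problem`.
#' @param reg Entropic regularization strength (> 0).
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the worst marginal violation.
#' @return The regularized transport cost; warns if not converged.
#' @export
sinkhorn_transport_cost <- function(problem, reg = 1e-2, max_iter = 5000,
                                    tol = 1e-9) {
  stopifnot(inherits(problem, "bipartite_ot_problem"), reg > 0)
  a <- problem$source; b <- problem$sink
  ki <- which(a > 0); kj <- which(b > 0)
  a <- a[ki]; b <- b[kj]
  C <- problem$cost[ki, kj, drop = FALSE]
  f <- rep(0, length(a)); g <- rep(0, length(b))
  lse <- function(x) {
    mx <- max(x)
    if (!is.finite(mx)) return(mx)
    mx + log(sum(exp(x - mx)))
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M <- (outer(f, g, "+") - C) / reg
    f <- f + reg * (log(a) - apply(M, 1, lse))
    M <- (outer(f, g, "+") - C) / reg
    g <- g + reg * (log(b) - apply(M, 2, lse))
    P <- exp((outer(f, g, "+") - C) / reg)
    err <- max(abs(rowSums(P) - a), abs(colSums(P) - b))
    if (err < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("Sinkhorn did not converge within ", max_iter,
            " iterations (marginal error ", signif(err, 3), ")",
            call. = FALSE)
  }
  sum(P * C)
}
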