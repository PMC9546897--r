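test_that("solver configuration is validated", {
  expect_error(dmk_config(beta = 0), "0, 2")
  expect_error(dmk_config(beta = 2.5), "0, 2")
  expect_error(dmk_config(dt = 0.6))
  expect_silent(dmk_config(beta = 2))
})

test_that("a single forced edge ships all mass at its cost, for every beta", {
  C <- matrix(2, 1, 1, dimnames = list("L", "R"))
  pb <- orcflow:::new_bipartite_problem("L", "R", C, 1, 1)
  for (b in c(0.1, 0.5, 1, 1.5, 2)) {
    r <- suppressWarnings(solve_dmk(pb, dmk_config(beta = b)))
    expect_equal(unname(r$flux[1, 1]), 1, tolerance = 1e-6)
    expect_equal(r$cost, 2, tolerance = 1e-6)
  }
  expect_equal(lp_transport_cost(pb), 2)
})

test_that("the 2x2 diagonal-optimal instance is solved exactly at beta = 1", {
  C <- matrix(c(1, 2, 2, 1), 2, 2)
  pb <- orcflow:::new_bipartite_problem(c("L1", "L2"), c("R1", "R2"), C,
                                        c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(lp_transport_cost(pb), 1)
  r <- suppressWarnings(solve_dmk(pb, dmk_config(beta = 1)))
  expect_equal(r$cost, 1, tolerance = 1e-3)
  expect_equal(wasserstein_cost(r, pb), r$cost)
})

test_that("DMK at beta = 1 matches the LP optimum on random metric problems", {
  withr::with_seed(19, {
    for (rep in 1:12) {
      pb <- random_metric_problem(sample(2:8, 1), sample(2:8, 1))
      lp <- lp_transport_cost(pb)
      r <- suppressWarnings(solve_dmk(pb, dmk_config(beta = 1)))
      expect_lt(abs(r$cost - lp) / lp, 1e-3)
      # feasibility: node balance of the returned flux
      expect_lt(r$balance_error, 10 * 1e-5)
    }
  })
})

test_that("every traffic rate respects the optimal-transport lower bound", {
  withr::with_seed(23, {
    for (rep in 1:8) {
      pb <- random_metric_problem(sample(2:6, 1), sample(2:6, 1))
      lp <- lp_transport_cost(pb)
      for (b in c(0.1, 0.5, 1.5, 2)) {
        r <- suppressWarnings(solve_dmk(pb, dmk_config(beta = b)))
        expect_gte(r$cost, lp - 1e-6)
      }
    }
  })
})

test_that("LP solver agrees with brute-force basis enumeration", {
  pb0 <- orcflow:::new_bipartite_problem(
    c("a", "b"), c("a", "b"),
    matrix(c(1e-6, 1, 1, 1e-6), 2, 2), c(0.3, 0.7), c(0.3, 0.7))
  expect_lt(lp_transport_cost(pb0), 1e-5)   # identical distributions

  withr::with_seed(31, {
    for (dims in list(c(3, 3), c(2, 3), c(3, 2), c(4, 3))) {
      C <- matrix(stats::runif(prod(dims), 0.1, 1), dims[1], dims[2])
      a <- sample(1:5, dims[1], TRUE); a <- a / sum(a)
      b <- sample(1:5, dims[2], TRUE); b <- b / sum(b)
      pb <- orcflow:::new_bipartite_problem(paste0("L", seq_len(dims[1])),
                                            paste0("R", seq_len(dims[2])),
                                            C, a, b)
      expect_equal(lp_transport_cost(pb), brute_force_lp(C, a, b),
                   tolerance = 1e-9)
    }
  })

  expect_error(orcflow:::transport_ssp(matrix(1, 2, 2), c(0.5, 0.5),
                                       c(0.3, 0.3)),
               "unbalanced")
})

test_that("Sinkhorn converges to the LP cost as regularization shrinks", {
  C <- matrix(c(1, 2, 2, 1), 2, 2)
  pb <- orcflow:::new_bipartite_problem(c("L1", "L2"), c("R1", "R2"), C,
                                        c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(sinkhorn_transport_cost(pb, reg = 1e-3), 1, tolerance = 1e-2)

  idn <- orcflow:::new_bipartite_problem(
    c("a", "b"), c("a", "b"),
    matrix(c(0, 1, 1, 0), 2, 2), c(0.5, 0.5), c(0.5, 0.5))
  expect_lt(sinkhorn_transport_cost(idn, reg = 1e-3), 1e-2)

  withr::with_seed(41, {
    for (rep in 1:5) {
      pb <- random_metric_problem(sample(2:5, 1), sample(2:5, 1))
      lp <- lp_transport_cost(pb)
      hi <- sinkhorn_transport_cost(pb, reg = 1e-1)
      lo <- sinkhorn_transport_cost(pb, reg = 1e-3)
      expect_gte(hi, lo - 1e-9)
      expect_gte(lo, lp - 1e-6)
    }
  })
})

test_that("congested spreading and branched consolidation across parallel routes", {
  # direct route s-t costs 1.2; relay route s-y, x-y, x-t totals 1.0
  C <- matrix(c(1.2, 0.4, 0.4, 0.2), 2, 2, byrow = TRUE,
              dimnames = list(c("s", "x"), c("t", "y")))
  pb <- orcflow:::new_bipartite_problem(c("s", "x"), c("t", "y"), C,
                                        c(1, 0), c(1, 0))
  lo <- suppressWarnings(solve_dmk(pb, dmk_config(beta = 0.5)))
  expect_gte(lo$flux["s", "t"], 0.01)   # congested: both routes used
  expect_gte(lo$flux["s", "y"], 0.01)
  hi <- suppressWarnings(solve_dmk(pb, dmk_config(beta = 1.5)))
  expect_gte(hi$flux["s", "y"], 0.99)   # branched: cheap route only
})

test_that("converged runs sit at the conductivity fixed point", {
  withr::with_seed(53, {
    found <- 0
    for (rep in 1:10) {
      pb <- random_metric_problem(3, 3)
      cfg <- dmk_config(beta = 1)
      r <- suppressWarnings(solve_dmk(pb, cfg))
      if (r$converged) {
        found <- found + 1
        expect_lte(r$residual, cfg$tol)
      }
    }
    expect_gte(found, 3)
  })
})
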