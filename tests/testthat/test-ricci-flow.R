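test_that("curvature worked examples match the transport-plan oracle", {
  # two nodes, one edge: everything ships across it, W = d, kappa = 0
  g2 <- make_two_node()
  expect_equal(1 - lp_transport_cost(build_local_ot_problem(g2, "A", "B")), 0)
  expect_equal(edge_curvature(g2, "A", "B", beta = 1), 0, tolerance = 1e-3)

  # triangle: the shared neighbor absorbs half the mass at zero cost
  tri <- make_triangle()
  expect_equal(lp_transport_cost(build_local_ot_problem(tri, "A", "B")), 0.5)
  expect_equal(edge_curvature(tri, "A", "B", beta = 1), 0.5, tolerance = 1e-3)

  # barbell bridge: W = 5/3 across the bottleneck, kappa = -2/3
  bb <- make_barbell()
  expect_equal(lp_transport_cost(build_local_ot_problem(bb, "c", "d")), 5 / 3,
               tolerance = 1e-12)
  expect_equal(edge_curvature(bb, "c", "d", beta = 1), -2 / 3,
               tolerance = 1e-3)

  expect_error(edge_curvature(tri, "A", "B", beta = 3), "0, 2")
})

test_that("curvature tables respect symmetry, components and the kappa <= 1 bound", {
  k4 <- as_orc_graph(igraph::make_full_graph(4))
  tb <- curvature_all_edges(k4, beta = 1)
  expect_lt(max(tb$kappa) - min(tb$kappa), 1e-5)   # automorphism symmetry

  bb <- curvature_all_edges(make_barbell(), beta = 1)
  idx <- which((bb$from == "c" & bb$to == "d") |
                 (bb$from == "d" & bb$to == "c"))
  expect_lt(bb$kappa[idx], 0)
  expect_gt(min(bb$kappa[-idx]), 0)

  two_tri <- igraph::disjoint_union(igraph::make_full_graph(3),
                                    igraph::make_full_graph(3))
  igraph::V(two_tri)$name <- letters[1:6]
  tb2 <- curvature_all_edges(as_orc_graph(two_tri), beta = 1)
  expect_equal(tb2$kappa, rep(0.5, 6), tolerance = 1e-3)

  withr::with_seed(7, {
    g <- igraph::sample_gnp(12, 0.35)
    igraph::V(g)$name <- as.character(1:12)
    igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.2, 1)
    g <- as_orc_graph(g)
    for (b in c(0.5, 1, 2)) {
      tb <- curvature_all_edges(g, beta = b)
      expect_true(all(tb$kappa <= 1 + 1e-9))
    }
  })
})

test_that("a flow step realizes the weight update identity and normalization", {
  # single edge: kappa = 0, post-normalization weight 1
  st <- ricci_flow_step(make_two_node(0.4))
  expect_equal(igraph::E(st$graph)$weight, 1)

  # triangle: symmetry forces equal thirds (up to solver tolerance)
  st2 <- ricci_flow_step(make_triangle())
  expect_equal(igraph::E(st2$graph)$weight, rep(1 / 3, 3), tolerance = 1e-5)

  # pre-normalization weight d(1 - kappa) equals the solver's W_beta
  withr::with_seed(13, {
    g <- igraph::sample_gnp(10, 0.4)
    igraph::V(g)$name <- as.character(1:10)
    igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.2, 1)
    st3 <- ricci_flow_step(as_orc_graph(g), beta = 1.5)
    expect_equal(st3$curvature$weight_new, st3$curvature$wasserstein,
                 tolerance = 1e-9)
  })
})

test_that("the iterated flow stretches bridges and shrinks clique edges", {
  expect_error(run_flow(make_triangle(), max_iter = 0), "at least 1")

  tr <- run_flow(make_two_k4(), beta = 1, max_iter = 15)
  expect_length(tr$snapshots, 16)
  tbl <- tidy(tr)
  expect_equal(nrow(tbl), 16 * 13)

  for (s in tr$snapshots) {
    expect_equal(sum(igraph::E(s$graph)$weight), 1, tolerance = 1e-12)
  }

  final <- tr$snapshots[[16]]$graph
  wfin <- igraph::E(final)$weight
  bridge_id <- igraph::get_edge_ids(final, c("d", "e"))
  expect_gt(wfin[bridge_id], max(wfin[-bridge_id]))

  # the bridge/intra gap opens early in the flow (barbell): the trend is
  # increasing, with a damped period-2 alternation from the normalization,
  # and the bridge is the longest edge from the first iteration on
  bb <- run_flow(make_barbell(), beta = 1, max_iter = 5)
  gaps <- vapply(bb$snapshots, function(s) {
    w <- igraph::E(s$graph)$weight
    bid <- igraph::get_edge_ids(s$graph, c("c", "d"))
    w[bid] - max(w[-bid])
  }, 0)
  expect_true(all(gaps[-1] > 0))
  expect_true(all(gaps[-(1:2)] >= gaps[seq_len(length(gaps) - 2)] - 1e-12))
  expect_gt(gaps[6], gaps[1])
})

test_that("the flow is deterministic and exportable", {
  g <- make_two_k4()
  t1 <- run_flow(g, beta = 1.5, max_iter = 3)
  t2 <- run_flow(g, beta = 1.5, max_iter = 3)
  expect_identical(tidy(t1), tidy(t2))

  f <- withr::local_tempfile(fileext = ".csv")
  write_curvature_csv(t1, f)
  out <- utils::read.csv(f)
  expect_named(out, c("u", "v", "weight", "kappa", "iteration"))
  expect_equal(nrow(out), 4 * 13)

  g1 <- glance(t1)
  expect_equal(g1$iteration, 0:3)
  expect_true(all(is.finite(g1$modularity)))
})
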