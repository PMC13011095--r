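test_that("complete and path graphs reproduce hand-enumerated metrics", {
  tri <- igraph::make_full_graph(3)
  ts <- topology_summary(tri)
  expect_equal(ts$avgCC, 1)
  expect_equal(ts$Trans, 1)
  expect_equal(ts$D, 1)
  expect_equal(ts$GD, 1)
  expect_equal(ts$HD, 1)
  expect_equal(ts$E, 1)
  path3 <- igraph::make_graph(~ a - b, b - c)
  tp <- topology_summary(path3)
  expect_equal(tp$avgK, 4 / 3)
  expect_equal(tp$GD, 4 / 3)
  expect_equal(tp$E, (1 + 1 + 0.5) / 3)
  expect_equal(tp$HD, 1 / tp$E)
  expect_error(topology_summary(igraph::make_empty_graph(0)), "empty")
})

test_that("avgK and density are exact arithmetic in nodes and links", {
  set.seed(3)
  g <- igraph::sample_gnm(80, 200)
  ts <- topology_summary(g, include = c("avgK", "D"))
  expect_equal(ts$avgK, 2 * 200 / 80)
  expect_equal(ts$D, 200 / choose(80, 2))
})

test_that("harmonic distance is exactly reciprocal to geodesic efficiency on random graphs", {
  set.seed(9)
  for (r in 1:25) {
    g <- igraph::sample_gnp(sample(10:40, 1), runif(1, 0.05, 0.4))
    if (igraph::ecount(g) == 0) next
    ts <- topology_summary(g, include = c("E", "HD"))
    if (!is.na(ts$HD)) expect_equal(ts$HD * ts$E, 1, tolerance = 1e-9)
  }
})

test_that("undirected graphs have degenerate hierarchy and lubness but real connectedness", {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_ring(5))
  ts <- topology_summary(g)
  expect_equal(ts$Hierarchy, 0)
  expect_equal(ts$Lubness, 1)
  # connectedness: reachable pairs / all pairs = (C(4,2)+C(5,2)) / C(9,2)
  expect_equal(ts$Con, (6 + 10) / 36)
  expect_true(ts$Trans >= 0 && ts$Trans <= 1)
  expect_true(ts$avgCC >= 0 && ts$avgCC <= 1)
  # unreachable ordered pairs reported alongside path metrics
  expect_equal(ts$unreachable_pairs, 36 - 16)
})

test_that("stress centrality counts geodesics through nodes", {
  path3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(stress_centrality(path3), c(0, 1, 0))
  star <- igraph::make_star(5, mode = "undirected")
  expect_equal(stress_centrality(star), c(choose(4, 2), 0, 0, 0, 0))
  clique <- igraph::make_full_graph(4)
  expect_equal(stress_centrality(clique), rep(0, 4))
})

test_that("the Erdos-Renyi ensemble forces density and mean degree, and matches the analytic clustering", {
  ne <- er_null_ensemble(60, 180, metrics = c("D", "avgK", "avgCC"),
                         n_replicates = 60, seed = 2)
  s <- ne$summary
  expect_equal(s$mean[s$metric == "D"], 180 / choose(60, 2))
  expect_equal(s$sd[s$metric == "D"], 0)
  expect_equal(s$mean[s$metric == "avgK"], 2 * 180 / 60)
  expect_equal(s$sd[s$metric == "avgK"], 0)
  p <- 180 / choose(60, 2)
  cc <- s[s$metric == "avgCC", ]
  expect_lt(abs(cc$mean - p), 3 * cc$sd / sqrt(60) + 0.01)
  expect_error(er_null_ensemble(5, 100), "infeasible")
  # determinism under seed
  ne2 <- er_null_ensemble(60, 180, metrics = c("avgCC"),
                          n_replicates = 10, seed = 7)
  ne3 <- er_null_ensemble(60, 180, metrics = c("avgCC"),
                          n_replicates = 10, seed = 7)
  expect_identical(ne2$summary, ne3$summary)
})

test_that("robustness curves anchor at the intact and empty graphs and cliques dominate paths", {
  g <- igraph::make_full_graph(8)
  rc <- robustness_curve(g, removal_fractions = c(0, 0.5, 1),
                         n_replicates = 10, seed = 1)
  expect_equal(rc$lcc_mean[1], 1)
  expect_equal(rc$lcc_mean[3], 0)
  expect_equal(rc$efficiency_mean[3], 0)
  expect_error(robustness_curve(g, removal_fractions = c(-0.1)), "\\[0, 1\\]")
  # clique >= path in largest-component fraction at every removal fraction
  pth <- igraph::make_ring(8, circular = FALSE)
  fr <- seq(0, 1, 0.25)
  rc_c <- robustness_curve(g, fr, n_replicates = 40, seed = 3)
  rc_p <- robustness_curve(pth, fr, n_replicates = 40, seed = 3)
  expect_true(all(rc_c$lcc_mean >= rc_p$lcc_mean - 1e-12))
  # monotone non-increasing in expectation
  expect_true(all(diff(rc_c$lcc_mean) <= 1e-12))
})
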