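# Centrality and eccentricity against closed forms, independent oracles
# (Floyd-Warshall, exhaustive path enumeration, dense eigendecomposition)
# and igraph as a cross-implementation check.

test_that("closed forms: star, triangle, path, 4-cycle, complete graph", {
  star <- net_from_edges("c-l1,c-l2,c-l3")
  eig <- eigenvector_centrality(star)
  expect_equal(unname(eig["c"]), 1)
  expect_equal(unname(eig[c("l1", "l2", "l3")]), rep(1 / sqrt(3), 3),
               tolerance = 1e-9)

  tri <- net_from_edges("a-b,b-c,a-c")
  expect_equal(unname(eigenvector_centrality(tri)), rep(1, 3))

  p3 <- net_from_edges("a-b,b-c")
  expect_equal(unname(betweenness_centrality(p3)), c(0, 1, 0))
  expect_equal(unname(eccentricity(p3)), c(2L, 1L, 2L))

  cyc4 <- net_from_edges("a-b,b-c,c-d,d-a")
  expect_equal(unname(betweenness_centrality(cyc4)), rep(0.5 / 3, 4),
               tolerance = 1e-12)

  k4 <- net_from_edges("a-b,a-c,a-d,b-c,b-d,c-d")
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))
})

test_that("weighted eigenvector on a path matches the dense eigensolver", {
  net <- net_from_edges("a-b:2,b-c:1")
  got <- eigenvector_centrality(net, weighted = TRUE)
  want <- oracle_eigenvector(net, weighted = TRUE)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("all three measures match independent oracles on 100 random graphs", {
  set.seed(42)
  for (k in 1:100) {
    n <- sample(3:8, 1L)
    net <- random_connected_net(n, extra = sample(0:3, 1L), weights = TRUE)
    expect_equal(unname(betweenness_centrality(net)),
                 unname(oracle_betweenness(net)), tolerance = 1e-9)
    expect_equal(unname(eccentricity(net)),
                 unname(as.integer(oracle_eccentricity(net))))
    expect_equal(unname(eigenvector_centrality(net)),
                 unname(oracle_eigenvector(net)), tolerance = 1e-6)
    expect_equal(unname(eigenvector_centrality(net, weighted = TRUE)),
                 unname(oracle_eigenvector(net, weighted = TRUE)),
                 tolerance = 1e-6)
  }
})

test_that("measures agree with igraph on a larger random graph", {
  set.seed(99)
  net <- random_connected_net(40, extra = 60L, weights = TRUE)
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  expect_equal(unname(betweenness_centrality(net)),
               unname(igraph::betweenness(g, weights = NA)) /
                 ((n - 1) * (n - 2) / 2),
               tolerance = 1e-12)
  expect_equal(unname(eccentricity(net)),
               as.integer(igraph::eccentricity(g, weights = NA)))
  expect_equal(unname(eigenvector_centrality(net)),
               unname(igraph::eigen_centrality(g, weights = NA)$vector),
               tolerance = 1e-6)
})

test_that("disconnected graphs are handled component-locally", {
  net <- net_from_edges("a-b,b-c,x-y", isolated = "z")
  eig <- eigenvector_centrality(net)
  expect_equal(unname(eig[c("x", "y")]), c(1, 1))  # per-component max = 1
  expect_equal(unname(eig["z"]), 0)
  expect_equal(unname(eig["b"]), 1)

  ecc <- eccentricity(net)
  expect_equal(unname(ecc[c("x", "y")]), c(1L, 1L))
  expect_equal(unname(ecc["z"]), 0L)

  bet <- betweenness_centrality(net)
  expect_equal(unname(bet[c("x", "y", "z")]), c(0, 0, 0))
  expect_equal(unname(bet["b"]), 1)

  comp <- component_ids(net)
  expect_equal(length(unique(comp)), 3L)
})

test_that("radius-diameter inequality holds within every component", {
  set.seed(5)
  for (k in 1:25) {
    net <- random_connected_net(sample(4:12, 1L), extra = sample(0:4, 1L))
    ecc <- eccentricity(net)
    expect_lte(max(ecc), 2 * min(ecc))
  }
})

test_that("node relabeling permutes all scores identically", {
  set.seed(8)
  net <- random_connected_net(9, extra = 4L, weights = TRUE)
  perm <- sample(nrow(net$nodes))
  new_ids <- stats::setNames(sprintf("w%02d", perm), net$nodes$clinician_id)
  net2 <- collab_network(
    data.frame(clinician_id = unname(new_ids), specialty = "x"),
    data.frame(from = unname(new_ids[net$edges$from]),
               to = unname(new_ids[net$edges$to]),
               weight = net$edges$weight))
  for (f in list(eigenvector_centrality, betweenness_centrality,
                 eccentricity)) {
    a <- f(net); b <- f(net2)
    expect_equal(unname(b[new_ids[names(a)]]), unname(a), tolerance = 1e-9)
  }
})

test_that("scaling all weights leaves weighted eigenvector unchanged", {
  set.seed(13)
  net <- random_connected_net(8, extra = 4L, weights = TRUE)
  net2 <- net
  net2$edges$weight <- net2$edges$weight * 7
  expect_equal(eigenvector_centrality(net, weighted = TRUE),
               eigenvector_centrality(net2, weighted = TRUE),
               tolerance = 1e-7)
})

test_that("non-convergence raises an error naming the component", {
  net <- net_from_edges("a-b,b-c,c-d,d-a,a-c")
  expect_error(eigenvector_centrality(net, max_iter = 1L),
               "did not converge on component")
})

test_that("specialty summaries compute medians, means and network row", {
  tab <- data.frame(period = "t",
                    clinician_id = c("a", "b", "c"),
                    specialty = c("nurse", "nurse", "doc"),
                    component_id = 1L,
                    eigenvector = c(0.2, 0.4, 1.0),
                    betweenness = c(0, 0, 1),
                    eccentricity = c(2L, 2L, 1L))
  s <- summarize_by_specialty(tab)
  nm <- s[s$specialty == "nurse" & s$metric == "eigenvector", ]
  expect_equal(nm$median, 0.3); expect_equal(nm$mean, 0.3)
  all_ecc <- s[s$specialty == "<all>" & s$metric == "eccentricity", ]
  expect_equal(all_ecc$median, 2)
  # empty specialty from roster reported with n = 0
  s2 <- summarize_by_specialty(tab, roster = data.frame(
    clinician_id = "z", specialty = "rt"))
  expect_true(all(is.na(s2$median[s2$specialty == "rt"])))
  expect_equal(unique(s2$n[s2$specialty == "rt"]), 0L)
})
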