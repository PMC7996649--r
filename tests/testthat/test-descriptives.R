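test_that("density follows the directed n(n-1) convention", {
  y <- matrix(1L, 5, 5); diag(y) <- 0L
  expect_equal(network_density(make_net(y)), 1)
  expect_equal(network_density(make_net(matrix(0L, 5, 5))), 0)
  y2 <- matrix(0L, 5, 5); y2[1, 2] <- 1L
  net <- make_net(y2)
  expect_equal(network_density(net), 1 / 20)
  ## strictly increases when a tie is added
  y3 <- y2; y3[2, 3] <- 1L
  expect_gt(network_density(make_net(y3)), network_density(net))
  expect_error(network_density(make_net(matrix(0L, 1, 1))),
               class = "referralnet_data_error")
})

test_that("tier flow tables reproduce the published district panels", {
  cases <- list(
    list("kilolo", "childcare",
         c(d_hc = 5, d_h = 22, hc_d = 1, hc_h = 2, h_h = 3)),
    list("msalala", "ncd",
         c(d_d = 2, d_hc = 6, d_h = 8, hc_h = 3)),
    list("msalala", "childcare",
         c(d_d = 3, d_hc = 10, d_h = 16, hc_hc = 1, hc_h = 2))
  )
  key <- c(d = "dispensary", hc = "health_centre", h = "hospital")
  for (case in cases) {
    fx <- fixture_from_table4(case[[1]], case[[2]])
    net <- assemble_network(fx$records, fx$roster, case[[1]], case[[2]])
    fl <- tier_flow_counts(net)
    expect_equal(sum(fl$flows), fl$total)
    expect_equal(fl$total, network_edge_count(net))
    expected <- case[[3]]
    for (nm in names(expected)) {
      pair <- key[strsplit(nm, "_")[[1]]]
      expect_equal(fl$flows[pair[1], pair[2]], unname(expected[nm]),
                   info = sprintf("%s %s %s", case[[1]], case[[2]], nm))
    }
    expect_equal(sum(fl$flows), sum(expected))
  }
  ## empty network: all-zero table
  fl0 <- tier_flow_counts(make_net(matrix(0L, 4, 4)))
  expect_true(all(fl0$flows == 0))
})

test_that("referral rate is ties per scale visits and rejects zero denominators", {
  expect_equal(referral_rate(5, 1000, 1000), 5)
  expect_equal(referral_rate(0, 500, 10000), 0)
  expect_equal(referral_rate(33, 13750, 10000), 24)
  expect_error(referral_rate(3, 0), class = "referralnet_data_error")
})

test_that("degree summary satisfies its counting identities", {
  y <- matrix(0L, 3, 3); y[1, 2] <- 1L; y[2, 3] <- 1L
  ds <- degree_summary(make_net(y))
  expect_equal(ds$nodes$in_degree, c(0, 1, 1))
  expect_equal(ds$nodes$out_degree, c(1, 1, 0))
  ds0 <- degree_summary(make_net(matrix(0L, 6, 6)))
  expect_equal(unname(ds0$indegree_distribution["0"]), 6)
  set.seed(21)
  for (rep in 1:10) {
    net <- make_net(random_digraph(10, 0.25))
    ds <- degree_summary(net)
    Dk <- ds$indegree_distribution
    expect_equal(sum(Dk), 10)
    expect_equal(sum(as.integer(names(Dk)) * Dk), network_edge_count(net))
  }
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  ## referral chain: the middle facility is the gatekeeper
  y <- matrix(0L, 3, 3); y[1, 2] <- 1L; y[2, 3] <- 1L
  b <- node_betweenness(make_net(y, tiers = c("dispensary", "health_centre",
                                              "hospital")))
  expect_equal(b$betweenness, c(0, 1, 0))
  ## in-star: the hub bridges nothing (no outgoing paths)
  y2 <- matrix(0L, 5, 5); y2[2:5, 1] <- 1L
  expect_equal(node_betweenness(make_net(y2))$betweenness, rep(0, 5))
  ## random digraphs against the brute-force oracle
  set.seed(33)
  for (n in c(5, 6, 7, 8)) {
    for (rep in 1:3) {
      y <- random_digraph(n, 0.25)
      expect_equal(node_betweenness(make_net(y))$betweenness,
                   bf_betweenness(y), tolerance = 1e-10)
    }
  }
})

test_that("betweenness is zero for pure sources and sinks", {
  set.seed(42)
  y <- random_digraph(7, 0.3)
  b <- node_betweenness(make_net(y))
  deg <- degree_summary(make_net(y))$nodes
  expect_true(all(b$betweenness[deg$in_degree == 0 | deg$out_degree == 0] == 0))
})

test_that("centrality ranking orders by score with lexicographic tie-break", {
  tab <- data.frame(facility_id = c("C", "A", "B"),
                    in_degree = c(2L, 18L, 7L),
                    betweenness = c(0, 0, 0), stringsAsFactors = FALSE)
  top <- rank_centrality(tab, "in_degree", 2)
  expect_equal(top$facility_id, c("A", "B"))
  expect_equal(top$score, c(18, 7))
  ## all-zero scores: first k facilities by id
  ztop <- rank_centrality(tab, "betweenness", 3)
  expect_equal(ztop$facility_id, c("A", "B", "C"))
  expect_error(rank_centrality(tab, "in_degree", 0),
               class = "referralnet_usage_error")
  ## permutation property: no facility appears twice
  expect_false(anyDuplicated(rank_centrality(tab, "in_degree", 3)$facility_id) > 0)
})

test_that("a designed hub ranks first by in-degree", {
  y <- matrix(0L, 8, 8); y[2:7, 8] <- 1L; y[1, 2] <- 1L
  net <- make_net(y)
  top <- rank_centrality(node_betweenness(net), "in_degree", 1)
  expect_equal(top$facility_id, "F08")
})
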