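test_that("term constructors enforce their invariants", {
  expect_error(ergm_term("gwidegree"), class = "referralnet_usage_error")
  expect_error(ergm_term("edges", decay = 0.5),
               class = "referralnet_usage_error")
  expect_error(ergm_term("node_factor_in", attribute = "tier"),
               class = "referralnet_usage_error")
  expect_error(ergm_term("node_factor_in", attribute = "tier",
                         level = "dispensary"),
               class = "referralnet_usage_error")
  expect_error(ergm_terms(ergm_term("edges"), ergm_term("edges")),
               class = "referralnet_usage_error")
})

test_that("network statistics match their definitions on known graphs", {
  fx <- fixture_from_table4("kilolo", "childcare")
  net <- assemble_network(fx$records, fx$roster, "kilolo", "childcare")
  u <- network_statistics(net, ergm_terms(ergm_term("edges")))
  expect_equal(unname(u), 33)

  empty <- make_net(matrix(0L, 10, 10))
  u2 <- network_statistics(empty, ergm_terms(ergm_term("isolates")))
  expect_equal(unname(u2), 10)

  ## gwidegree equals D_1 when every in-degree is <= 1 (algebraic identity)
  y <- matrix(0L, 6, 6); y[1, 2] <- 1L; y[3, 4] <- 1L; y[5, 6] <- 1L
  net3 <- make_net(y)
  u3 <- network_statistics(net3, ergm_terms(ergm_term("gwidegree",
                                                      decay = 0.7)))
  expect_equal(unname(u3), 3)

  ## edgecov sums the dyadic covariate over ties
  set.seed(9)
  D <- random_dyadcov(6)
  u4 <- network_statistics(net3, ergm_terms(ergm_term("edgecov",
                                                      attribute = "distance")),
                           dyadcov = list(distance = D))
  expect_equal(unname(u4), D[1, 2] + D[3, 4] + D[5, 6])
})

test_that("gwidegree change statistic follows the geometric decay of in-degree", {
  y <- matrix(0L, 5, 5)
  net <- make_net(y)
  tm <- ergm_terms(ergm_term("gwidegree", decay = 0.7))
  ## receiver with prior in-degree 0: change is exactly 1
  expect_equal(unname(change_statistics(net, tm, 1, 2)), 1)
  ## receiver with prior in-degree 1: 1 - exp(-0.7)
  y[3, 2] <- 1L
  net <- make_net(y)
  expect_equal(unname(change_statistics(net, tm, 1, 2)), 1 - exp(-0.7),
               tolerance = 1e-12)
  expect_error(change_statistics(net, tm, 2, 2),
               class = "referralnet_usage_error")
})

test_that("change statistics equal global statistic differences for every term", {
  set.seed(77)
  tm <- all_terms()
  for (n in c(4, 6, 8)) {
    D <- random_dyadcov(n)
    for (rep in 1:4) {
      y <- random_digraph(n, 0.35)
      net <- make_net(y)
      model <- referralnet:::resolve_terms(tm, net, list(distance = D))
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        y1 <- y; y1[i, j] <- 1L
        y0 <- y; y0[i, j] <- 0L
        g <- network_statistics(make_net(y1), model) -
          network_statistics(make_net(y0), model)
        d <- change_statistics(net, model, i, j)
        expect_equal(d, g, tolerance = 1e-12)
      }
    }
  }
})

test_that("the all-dyad change matrix agrees with per-dyad change statistics", {
  set.seed(5)
  n <- 7
  y <- random_digraph(n, 0.3)
  net <- make_net(y)
  D <- random_dyadcov(n)
  model <- referralnet:::resolve_terms(all_terms(), net, list(distance = D))
  X <- referralnet:::change_matrix(net, model)
  dy <- attr(X, "dyads")
  for (r in sample(nrow(X), 12)) {
    expect_equal(unname(X[r, ]),
                 unname(change_statistics(net, model, dy[r, 1], dy[r, 2])),
                 tolerance = 1e-12)
  }
  ## tie indicator column matches the adjacency
  expect_equal(attr(X, "y"), y[dy])
})

test_that("missing covariates are reported with node and attribute", {
  net <- make_net(random_digraph(4, 0.4))
  net$nodes$rooms[2] <- NA
  expect_error(
    network_statistics(net, ergm_terms(ergm_term("node_cov_in",
                                                 attribute = "rooms"))),
    "rooms", class = "referralnet_data_error")
})
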