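test_that("edges-only tie probability equals the observed density for every dyad", {
  fx <- fixture_from_table4("msalala", "ncd")
  net <- assemble_network(fx$records, fx$roster, "msalala", "ncd")
  fit <- referral_ergm(net, ergm_terms(ergm_term("edges")))
  pr <- predict(fit)
  expect_equal(nrow(pr), 31 * 30)
  expect_equal(pr$p, rep(network_density(net), nrow(pr)), tolerance = 1e-6)
  one <- tie_probability(fit, "MSA_001", "MSA_030")
  expect_equal(one$p, network_density(net), tolerance = 1e-6)
})

test_that("tie probability is the inverse logit of the linear predictor", {
  set.seed(8)
  net <- make_net(random_digraph(6, 0.3))
  tm <- ergm_terms(ergm_term("edges"),
                   ergm_term("node_cov_in", attribute = "rooms"))
  fit <- referral_ergm(net, tm)
  pr <- predict(fit)
  expect_true(all(pr$p > 0 & pr$p < 1))
  expect_equal(pr$p, plogis(pr$eta), tolerance = 1e-12)
  ## p = 0.5 exactly when the linear predictor vanishes
  fit0 <- fit; fit0$coefficients[] <- 0
  expect_equal(predict(fit0)$p, rep(0.5, nrow(pr)))
  ## monotone in a covariate with positive coefficient
  fitpos <- fit; fitpos$coefficients[] <- c(-2, 0.3)
  rooms <- net$nodes$rooms
  p_by_receiver <- vapply(2:6, function(j)
    tie_probability(fitpos, 1L, j)$p, numeric(1))
  expect_equal(order(p_by_receiver), order(rooms[-1]))
})

test_that("scenario deltas are exact for single-term attribute changes", {
  set.seed(15)
  net <- make_net(random_digraph(8, 0.25))
  tm <- ergm_terms(ergm_term("edges"),
                   ergm_term("node_cov_in", attribute = "rooms"))
  fit <- referral_ergm(net, tm)
  beta <- coef(fit)[["nodeicov.rooms"]]
  base_rooms <- net$nodes$rooms[4]
  sc <- scenario_delta(fit, 2, 4, receiver_changes = list(rooms = base_rooms + 5))
  ## the linear predictor shifts by beta * c exactly
  expect_equal(sc$eta_new - sc$eta_old, beta * 5, tolerance = 1e-10)
  expect_equal(sign(sc$relative_change), sign(beta))
  ## zero change, zero delta
  sc0 <- scenario_delta(fit, 2, 4, receiver_changes = list(rooms = base_rooms))
  expect_equal(sc0$relative_change, 0)
  ## changing an attribute outside the model warns and does nothing
  expect_warning(
    scn <- scenario_delta(fit, 2, 4,
                          receiver_changes = list(ambulances = 5)),
    "not used")
  expect_equal(scn$relative_change, 0)
})

test_that("infrastructure-expansion scenario raises incoming-referral probability", {
  ## a dispensary-to-health-centre dyad under a rooms-effect model, in the
  ## style of the worked expansion example (40 -> 45 rooms)
  fx <- fixture_from_table4("kilolo", "childcare")
  net <- assemble_network(fx$records, fx$roster, "kilolo", "childcare")
  dist <- fx$distances[net$nodes$facility_id, net$nodes$facility_id]
  tm <- ergm_terms(ergm_term("edges"),
                   ergm_term("edgecov", attribute = "distance",
                             transform = "log1p"),
                   ergm_term("node_cov_in", attribute = "rooms"))
  fit <- referral_ergm(net, tm, dyadcov = list(distance = dist))
  sc <- scenario_delta(fit, "KIL_001", "KIL_041",
                       receiver_changes = list(rooms = 45))
  beta <- coef(fit)[["nodeicov.rooms"]]
  drooms <- 45 - net$nodes$rooms[match("KIL_041", net$nodes$facility_id)]
  expect_equal(sc$eta_new - sc$eta_old, beta * drooms, tolerance = 1e-10)
  expect_equal(sign(sc$relative_change), sign(beta * drooms))
})

test_that("goodness-of-fit envelopes cover an edges-only fit", {
  fx <- fixture_from_table4("kilolo", "childcare")
  net <- assemble_network(fx$records, fx$roster, "kilolo", "childcare")
  fit <- referral_ergm(net, ergm_terms(ergm_term("edges")))
  g <- gof(fit, n_sim = 100, seed = 7)
  expect_false(g$degenerate)
  edges_row <- g$report[g$report$statistic == "edges", ]
  expect_true(edges_row$observed >= edges_row$q025 &&
                edges_row$observed <= edges_row$q975)
  ## binomial closed form: the envelope brackets m*p
  expect_lt(abs(edges_row$sim_mean - 33), 3 * sqrt(33 * (1 - 33 / 2070)))
  expect_true(all(g$report$q025 <= g$report$q975))
  expect_error(gof(fit, n_sim = 5), class = "referralnet_usage_error")
})

test_that("forcing implausible coefficients raises the degeneracy flag", {
  set.seed(30)
  y <- random_digraph(10, 0.4)
  net <- make_net(y)
  fit <- referral_ergm(net, ergm_terms(ergm_term("edges")))
  fit$coefficients[] <- -20   # simulated graphs collapse to empty
  g <- gof(fit, n_sim = 50, seed = 2)
  expect_true(g$degenerate)
})

test_that("plot method draws degree envelopes without error", {
  fx <- fixture_from_table4("msalala", "childcare")
  net <- assemble_network(fx$records, fx$roster, "msalala", "childcare")
  fit <- referral_ergm(net, ergm_terms(ergm_term("edges")))
  g <- gof(fit, n_sim = 20, seed = 3)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(g))
})
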