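test_that("edges-only pseudolikelihood returns the logit of density exactly", {
  fx <- fixture_from_table4("kilolo", "childcare")
  net <- assemble_network(fx$records, fx$roster, "kilolo", "childcare")
  fit <- referral_ergm(net, ergm_terms(ergm_term("edges")))
  expect_equal(unname(coef(fit)), qlogis(33 / 2070), tolerance = 1e-8)
  expect_equal(plogis(unname(coef(fit))), network_density(net),
               tolerance = 1e-10)
  ## binomial closed forms for pseudolikelihood and its standard error
  p <- 33 / 2070
  expect_equal(fit$loglik, 33 * log(p) + 2037 * log(1 - p), tolerance = 1e-6)
  expect_equal(unname(fit$se), sqrt(1 / (2070 * p * (1 - p))),
               tolerance = 1e-6)
  expect_equal(fit$aic, -2 * fit$loglik + 2)
  expect_equal(fit$bic, -2 * fit$loglik + log(2070))
})

test_that("degenerate boundary networks refuse to fit", {
  expect_error(referral_ergm(make_net(matrix(0L, 5, 5)),
                             ergm_terms(ergm_term("edges"))),
               "empty", class = "referralnet_data_error")
  y <- matrix(1L, 5, 5); diag(y) <- 0L
  expect_error(referral_ergm(make_net(y), ergm_terms(ergm_term("edges"))),
               "complete", class = "referralnet_data_error")
})

test_that("two-term pseudolikelihood matches a dense grid search", {
  set.seed(13)
  n <- 5
  y <- random_digraph(n, 0.4)
  if (sum(y) == 0) y[1, 2] <- 1L
  net <- make_net(y)
  D <- random_dyadcov(n)
  tm <- ergm_terms(ergm_term("edges"),
                   ergm_term("edgecov", attribute = "distance"))
  fit <- referral_ergm(net, tm, dyadcov = list(distance = D))
  model <- referralnet:::resolve_terms(tm, net, list(distance = D))
  X <- referralnet:::change_matrix(net, model)
  yv <- attr(X, "y")
  pll <- function(th) sum(yv * (X %*% th) - log1p(exp(X %*% th)))
  ## two-stage grid around the fit region
  grid1 <- expand.grid(a = seq(-6, 6, 0.1), b = seq(-3, 3, 0.05))
  v1 <- mapply(function(a, b) pll(c(a, b)), grid1$a, grid1$b)
  best <- grid1[which.max(v1), ]
  grid2 <- expand.grid(a = seq(best$a - 0.15, best$a + 0.15, 0.002),
                       b = seq(best$b - 0.08, best$b + 0.08, 0.001))
  v2 <- mapply(function(a, b) pll(c(a, b)), grid2$a, grid2$b)
  best2 <- unlist(grid2[which.max(v2), ])
  expect_equal(unname(coef(fit)), unname(best2), tolerance = 1e-3)
})

test_that("quasi-separation triggers a warning and a flagged fit", {
  ## a covariate that perfectly separates ties from non-ties
  n <- 5
  y <- matrix(0L, n, n); y[1, 2] <- 1L; y[2, 3] <- 1L
  net <- make_net(y)
  D <- matrix(10, n, n); D[1, 2] <- 0; D[2, 3] <- 0; diag(D) <- 0
  dimnames(D) <- list(net$nodes$facility_id, net$nodes$facility_id)
  tm <- ergm_terms(ergm_term("edges"),
                   ergm_term("edgecov", attribute = "distance"))
  expect_warning(fit <- referral_ergm(net, tm, dyadcov = list(distance = D)),
                 "quasi-separation")
  expect_true(fit$quasi_separation)
  expect_true(all(is.finite(coef(fit))))  # ridge fallback keeps theta finite
})

test_that("information criteria implement the dyad-count arithmetic", {
  ic <- information_criteria(-57.59, 15, 930)
  expect_equal(unname(ic["aic"]), 145.18)
  ic0 <- information_criteria(-10, 0, 100)
  expect_equal(unname(ic0["aic"]), 20)
  expect_equal(unname(ic0["bic"]), 20)
  expect_error(information_criteria(-1, 1, 0),
               class = "referralnet_usage_error")
})

test_that("the fit object behaves like a standard model fit", {
  fx <- fixture_from_table4("msalala", "ncd")
  net <- assemble_network(fx$records, fx$roster, "msalala", "ncd")
  tm <- ergm_terms(ergm_term("edges"),
                   ergm_term("node_factor_in", attribute = "tier",
                             level = "hospital"))
  fit <- referral_ergm(net, tm)
  expect_s3_class(fit, "referral_ergm")
  expect_named(coef(fit), c("edges", "nodeifactor.tier.hospital"))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 2)
  expect_equal(attr(ll, "nobs"), 930)
  expect_equal(AIC(fit), fit$aic)
  expect_equal(BIC(fit), fit$bic)
  expect_equal(dim(vcov(fit)), c(2, 2))
  s <- summary(fit)
  expect_equal(rownames(s$coefficients), names(coef(fit)))
  expect_output(print(fit), "Directed ERGM")
  ## JSON serialization carries the fit's headline numbers
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$k, 2)
  expect_equal(js$aic, fit$aic, tolerance = 1e-8)
  expect_equal(js$coefficients$edges, unname(coef(fit)[1]), tolerance = 1e-8)
})
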