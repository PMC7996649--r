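## Shared fixtures and independent oracles for the test suite.

## Small node table with all attributes the model terms use.
make_nodes <- function(n, tiers = NULL) {
  if (is.null(tiers)) {
    tiers <- rep(c("dispensary", "health_centre", "hospital"), length.out = n)
  }
  data.frame(
    facility_id = sprintf("F%02d", seq_len(n)),
    name = sprintf("facility %d", seq_len(n)),
    district = "testland",
    tier = tiers,
    ownership = "public",
    surveyed = TRUE,
    lon = 35 + seq_len(n) / 100, lat = -8 + seq_len(n) / 100,
    delivery_beds = (seq_len(n) %% 4L),
    patient_beds = 2L * seq_len(n),
    rooms = 1L + (seq_len(n) %% 7L),
    motorcycles = seq_len(n) %% 2L,
    ambulances = seq_len(n) %% 3L,
    catchment_population = 1000L + 100L * seq_len(n),
    facility_deliveries_3m = 5L * seq_len(n),
    outpatient_visits_3m = 400L + 10L * seq_len(n),
    rch_visits_3m = 150L + 5L * seq_len(n),
    stringsAsFactors = FALSE
  )
}

make_net <- function(y, tiers = NULL, district = "testland",
                     domain = "childcare") {
  referral_network(y, make_nodes(nrow(y), tiers), district, domain)
}

random_digraph <- function(n, p = 0.3) {
  y <- matrix(rbinom(n * n, 1, p), n, n)
  diag(y) <- 0L
  y
}

## Full term set over all nine kinds, exercising each change-statistic rule.
all_terms <- function(decay = 0.7) {
  ergm_terms(
    ergm_term("edges"),
    ergm_term("isolates"),
    ergm_term("gwidegree", decay = decay),
    ergm_term("edgecov", attribute = "distance"),
    ergm_term("node_factor_in", attribute = "tier", level = "hospital"),
    ergm_term("node_cov_in", attribute = "rooms"),
    ergm_term("node_cov_out", attribute = "delivery_beds", transform = "log1p"),
    ergm_term("node_cov_combined", attribute = "patient_beds"),
    ergm_term("node_factor_combined", attribute = "tier",
              level = "health_centre")
  )
}

random_dyadcov <- function(n) {
  d <- as.matrix(dist(cbind(runif(n), runif(n)))) * 10
  dimnames(d) <- list(sprintf("F%02d", seq_len(n)), sprintf("F%02d", seq_len(n)))
  d
}

## Brute-force directed betweenness: enumerate every simple path with a
## depth-first search, keep the shortest ones per ordered pair, attribute
## fractionally to interior nodes.
bf_betweenness <- function(y) {
  n <- nrow(y)
  score <- numeric(n)
  paths_from <- function(s, t) {
    found <- list()
    best <- Inf
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        len <- length(path) - 1
        if (len < best) { found <<- list(path); best <<- len }
        else if (len == best) found[[length(found) + 1]] <<- path
        return()
      }
      if (length(path) - 1 >= best) return()
      for (w in which(y[v, ] == 1)) if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    found
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    sp <- paths_from(s, t)
    if (length(sp) == 0) next
    for (p in sp) {
      interior <- setdiff(p, c(s, t))
      score[interior] <- score[interior] + 1 / length(sp)
    }
  }
  score
}

## Exact MLE for tiny digraphs by full enumeration of all 2^(n(n-1)) graphs.
enumeration_mle <- function(net, terms, start = NULL) {
  n <- network_size(net)
  m <- n * (n - 1)
  stopifnot(m <= 16)
  dyads <- which(row(diag(n)) != col(diag(n)))
  allu <- vapply(0:(2^m - 1), function(b) {
    yy <- matrix(0L, n, n)
    yy[dyads] <- as.integer(intToBits(b)[seq_len(m)])
    network_statistics(referral_network(yy, net$nodes, net$district,
                                        net$domain), terms)
  }, numeric(length(terms)))
  allu <- matrix(allu, ncol = 2^m)
  u_obs <- network_statistics(net, terms)
  nll <- function(th) {
    v <- colSums(th * allu)
    lse <- max(v)
    -(sum(th * u_obs) - (lse + log(sum(exp(v - lse)))))
  }
  opt <- optim(start %||% rep(0, length(u_obs)), nll, method = "BFGS")
  list(theta = opt$par, loglik = -opt$value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Recovery-harness ground truth shared by tests and documentation.
recovery_terms <- function() {
  ergm_terms(
    ergm_term("edges"),
    ergm_term("edgecov", attribute = "distance", transform = "log1p"),
    ergm_term("node_factor_in", attribute = "tier", level = "hospital")
  )
}
recovery_theta <- c(-3.5, -1.0, 2.0)
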