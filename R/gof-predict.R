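#' Conditional tie probabilities from a fitted ERGM
#'
#' For each dyad `(i, j)`, the change statistics `delta_ij` are computed on
#' the observed network with the focal tie set absent, and the conditional
#' probability of the tie given the rest of the network is
#' `p_ij = plogis(theta . delta_ij)`.  In an edges-only model this equals
#' the observed density for every dyad.
#'
#' @param object a `referral_ergm` fit.
#' @param sender,receiver facility ids or node indices; both `NULL` returns
#'   all dyads.
#' @param ... unused.
#' @return a `data.frame` with `sender`, `receiver`, the linear predictor
#'   `eta` and probability `p`.
#' @export
predict.referral_ergm <- function(object, sender = NULL, receiver = NULL,
                                  ...) {
  net <- object$network
  X <- change_matrix(net, object$model)
  dy <- attr(X, "dyads")
  eta <- drop(X %*% object$coefficients)
  ids <- net$nodes$facility_id
  out <- data.frame(sender = ids[dy[, 1]], receiver = ids[dy[, 2]],
                    eta = eta, p = plogis(eta), stringsAsFactors = FALSE)
  if (!is.null(sender)) {
    if (is.numeric(sender)) sender <- ids[sender]
    out <- out[out$sender %in% sender, , drop = FALSE]
  }
  if (!is.null(receiver)) {
    if (is.numeric(receiver)) receiver <- ids[receiver]
    out <- out[out$receiver %in% receiver, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' @rdname predict.referral_ergm
#' @param fit a `referral_ergm` fit.
#' @export
tie_probability <- function(fit, sender, receiver) {
  if (any(!is.finite(fit$coefficients))) {
    usage_error("tie probabilities require finite coefficients")
  }
  delta <- change_statistics(fit$network, fit$model, sender, receiver)
  eta <- sum(fit$coefficients * delta)
  list(sender = sender, receiver = receiver, delta = delta, eta = eta,
       p = plogis(eta))
}

#' Scenario prediction: relative change in tie probability
#'
#' Recomputes the conditional tie probability for a dyad after modifying
#' sender and/or receiver attributes (e.g. expanding a health centre from
#' 40 to 45 rooms), holding the rest of the observed network fixed, and
#' reports the relative change `(p_new - p_old) / p_old`.  The effect size
#' depends on the dyad's initial change statistics, so the same attribute
#' change can move different dyads by different amounts.
#'
#' @param fit a `referral_ergm` fit.
#' @param sender,receiver facility ids or node indices of the dyad.
#' @param sender_changes,receiver_changes named lists of attribute
#'   replacement values, e.g. `list(rooms = 45)`.  Changing an attribute
#'   that no model term uses triggers a warning and contributes nothing.
#' @return a list with `p_old`, `p_new`, `eta_old`, `eta_new` and
#'   `relative_change`.
#' @export
scenario_delta <- function(fit, sender, receiver, sender_changes = list(),
                           receiver_changes = list()) {
  net <- fit$network
  ids <- net$nodes$facility_id
  si <- if (is.character(sender)) match(sender, ids) else sender
  ri <- if (is.character(receiver)) match(receiver, ids) else receiver
  if (is.na(si) || is.na(ri)) data_error("dyad endpoints not found in network")
  used <- unlist(lapply(fit$terms, function(t) t$attribute))
  apply_changes <- function(nodes, idx, changes) {
    for (nm in names(changes)) {
      if (is.null(nodes[[nm]])) data_error("unknown attribute '%s'", nm)
      if (!nm %in% used) {
        warning(sprintf("attribute '%s' is not used by any model term; no effect",
                        nm), call. = FALSE)
      }
      nodes[[nm]][idx] <- changes[[nm]]
    }
    nodes
  }
  nodes_new <- apply_changes(net$nodes, si, sender_changes)
  nodes_new <- apply_changes(nodes_new, ri, receiver_changes)
  net_new <- referral_network(net$adjacency, nodes_new, net$district,
                              net$domain)
  model_new <- resolve_terms(fit$terms, net_new, fit$dyadcov)
  d_old <- change_statistics(net, fit$model, si, ri)
  d_new <- change_statistics(net_new, model_new, si, ri)
  eta_old <- sum(fit$coefficients * d_old)
  eta_new <- sum(fit$coefficients * d_new)
  p_old <- plogis(eta_old)
  p_new <- plogis(eta_new)
  list(p_old = p_old, p_new = p_new, eta_old = eta_old, eta_new = eta_new,
       relative_change = (p_new - p_old) / p_old)
}

#' Simulation-based goodness of fit
#'
#' Simulates `n_sim` networks at the fitted coefficients and compares the
#' observed monitored statistics — the model statistics plus the in-degree
#' and out-degree distributions — to the simulated 2.5/97.5 percentile
#' envelopes.  A degeneracy flag is raised when the simulated mean density
#' falls below 0.1x or above 10x the observed density, or when the
#' simulations collapse to empty or complete graphs.
#'
#' @param object a converged `referral_ergm` fit.
#' @param n_sim number of simulated networks (>= 10).
#' @param seed optional integer seed.
#' @param ... unused.
#' @return an object of class `referral_gof`: a `data.frame`-carrying list
#'   with one row per monitored statistic (`observed`, `sim_mean`, `q025`,
#'   `q975`, `outside_envelope`) plus the degeneracy flag.
#' @export
gof <- function(object, ...) UseMethod("gof")

#' @rdname gof
#' @export
gof.referral_ergm <- function(object, n_sim = 100, seed = NULL, ...) {
  if (n_sim < 10) usage_error("n_sim must be >= 10")
  net <- object$network
  n <- network_size(net)
  sims <- simulate_networks(net, object$model, object$coefficients,
                            nsamples = n_sim,
                            burnin = object$control$burnin,
                            interval = object$control$interval, seed = seed)
  model_obs <- object$u_obs
  su <- vapply(sims, function(s) network_statistics(s, object$model),
               numeric(length(model_obs)))
  sim_u <- if (is.matrix(su)) t(su) else matrix(su, ncol = 1)
  deg_counts <- function(net, margin) {
    d <- if (margin == "in") colSums(net$adjacency) else rowSums(net$adjacency)
    tabulate(d + 1L, nbins = n)
  }
  obs_in <- deg_counts(net, "in"); obs_out <- deg_counts(net, "out")
  sim_in <- t(vapply(sims, deg_counts, numeric(n), margin = "in"))
  sim_out <- t(vapply(sims, deg_counts, numeric(n), margin = "out"))
  kmax_in <- max(which(obs_in > 0 | colSums(sim_in) > 0))
  kmax_out <- max(which(obs_out > 0 | colSums(sim_out) > 0))
  rows <- function(labels, obs, sim) {
    data.frame(
      statistic = labels, observed = obs,
      sim_mean = colMeans(sim),
      q025 = apply(sim, 2, quantile, 0.025),
      q975 = apply(sim, 2, quantile, 0.975),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  report <- rbind(
    rows(names(model_obs), as.numeric(model_obs), sim_u),
    rows(sprintf("in_degree_%d", 0:(kmax_in - 1)), obs_in[1:kmax_in],
         sim_in[, 1:kmax_in, drop = FALSE]),
    rows(sprintf("out_degree_%d", 0:(kmax_out - 1)), obs_out[1:kmax_out],
         sim_out[, 1:kmax_out, drop = FALSE])
  )
  report$outside_envelope <- report$observed < report$q025 |
    report$observed > report$q975
  obs_density <- network_density(net)
  sim_edges <- vapply(sims, network_edge_count, numeric(1))
  sim_density <- mean(sim_edges) / (n * (n - 1))
  collapsed <- all(sim_edges == 0) || all(sim_edges == n * (n - 1))
  degenerate <- collapsed ||
    (obs_density > 0 &&
       (sim_density < 0.1 * obs_density || sim_density > 10 * obs_density))
  structure(list(report = report, degenerate = degenerate,
                 obs_density = obs_density, sim_density = sim_density,
                 n_sim = n_sim, seed = seed),
            class = "referral_gof")
}

#' @export
print.referral_gof <- function(x, ...) {
  cat(sprintf("Goodness of fit from %d simulated networks\n", x$n_sim))
  cat(sprintf("Observed density %.4f, simulated mean density %.4f%s\n",
              x$obs_density, x$sim_density,
              if (x$degenerate) "  ** DEGENERACY FLAG **" else ""))
  out <- x$report
  out[c("observed", "sim_mean", "q025", "q975")] <-
    lapply(out[c("observed", "sim_mean", "q025", "q975")], round, digits = 2)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @rdname gof
#' @param x a `referral_gof` object.
#' @importFrom graphics polygon lines points legend par
#' @importFrom grDevices adjustcolor
#' @export
plot.referral_gof <- function(x, ...) {
  rep <- x$report
  panels <- list(
    `in-degree` = rep[grepl("^in_degree_", rep$statistic), ],
    `out-degree` = rep[grepl("^out_degree_", rep$statistic), ]
  )
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  for (nm in names(panels)) {
    d <- panels[[nm]]
    k <- seq_len(nrow(d)) - 1
    plot(k, d$observed, type = "n",
         ylim = range(c(d$observed, d$q025, d$q975)),
         xlab = nm, ylab = "node count",
         main = sprintf("%s distribution", nm))
    polygon(c(k, rev(k)), c(d$q025, rev(d$q975)), border = NA,
            col = adjustcolor("steelblue", 0.3))
    lines(k, d$sim_mean, col = "steelblue", lwd = 2)
    points(k, d$observed, pch = 19)
  }
  invisible(x)
}

#' @export
plot.referral_ergm <- function(x, n_sim = 100, seed = NULL, ...) {
  plot(gof(x, n_sim = n_sim, seed = seed), ...)
}
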