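#' Control parameters for ERGM estimation and simulation
#'
#' @param burnin proposals discarded before the first retained draw.
#' @param interval proposals between retained draws.
#' @param n_samples retained draws per estimation round.
#' @param max_iter maximum Monte-Carlo refinement rounds.
#' @param tol convergence tolerance on `max |theta_t+1 - theta_t|`.
#' @param bridge_steps path-sampling steps used for the log-likelihood.
#' @param bridge_samples draws per path-sampling step.
#' @param ridge ridge penalty applied to the pseudolikelihood as a fallback
#'   when quasi-separation is detected (set 0 to disable).
#' @param seed integer seed; every stochastic fit records it.
#' @return a list of class `ergm_control`.
#' @export
ergm_control <- function(burnin = 1e5, interval = 1e3, n_samples = 1000,
                         max_iter = 20, tol = 0.01, bridge_steps = 32,
                         bridge_samples = 256, ridge = 1e-4, seed = NULL) {
  structure(list(burnin = as.integer(burnin), interval = as.integer(interval),
                 n_samples = as.integer(n_samples),
                 max_iter = as.integer(max_iter), tol = tol,
                 bridge_steps = as.integer(bridge_steps),
                 bridge_samples = as.integer(bridge_samples),
                 ridge = ridge, seed = seed),
            class = "ergm_control")
}

degeneracy_error <- function(msg, payload = NULL) {
  stop(errorCondition(msg, payload = payload,
                      class = c("referralnet_degeneracy_error", "error")))
}

pseudolik <- function(theta, X, yvec) {
  eta <- drop(X %*% theta)
  sum(yvec * eta - log1p(exp(eta)))
}

#' Fit a directed ERGM to a referral network
#'
#' The network `y` is modelled as `P(y) = exp(theta . u(y)) / Z(theta)` with
#' sufficient statistics `u` given by `terms`.  Two estimators are
#' available:
#'
#' * `method = "mple"` — maximum pseudolikelihood: logistic regression of
#'   the tie indicators on the change statistics over all `n (n - 1)` dyads
#'   (IRLS Newton via `glm.fit`), standard errors from the observed
#'   information of that objective.  Exact when all terms are
#'   dyad-independent.
#' * `method = "mcmc"` — Monte-Carlo maximum likelihood
#'   (Geyer–Thompson): starting from the MPLE, iteratively simulate
#'   networks at the current estimate with the tie/no-tie sampler and
#'   maximize the importance-sampled log-likelihood ratio, until the update
#'   is below `tol`.  Standard errors come from the inverse covariance of
#'   the simulated statistics (estimated Fisher information) and the
#'   log-likelihood from a path-sampling bridge to the null model.
#'
#' @param net a `referral_network`.
#' @param terms an `ergm_terms` specification.
#' @param dyadcov named list of dyadic covariate matrices (e.g.
#'   `list(distance = km_matrix)`).
#' @param method `"mple"` or `"mcmc"`.
#' @param control an [ergm_control()] list.
#' @param theta0 optional starting coefficients for `"mcmc"` (defaults to
#'   the MPLE).
#' @return an object of class `referral_ergm` with `coef`, `vcov`,
#'   `logLik`, `summary`, `simulate`, `predict`, `gof` and `plot` methods.
#'   `logLik` carries the method tag: for MPLE fits it is the maximized
#'   pseudolikelihood and is labelled as such.
#' @export
referral_ergm <- function(net, terms, dyadcov = list(),
                          method = c("mple", "mcmc"),
                          control = ergm_control(), theta0 = NULL) {
  method <- match.arg(method)
  model <- resolve_terms(terms, net, dyadcov)
  fit <- fit_mple(net, model, control)
  if (method == "mcmc") {
    fit <- fit_mcmc_mle(net, model, control,
                        theta0 = theta0 %||% fit$coefficients, mple = fit)
  }
  fit$network <- net
  fit$model <- model
  fit$terms <- if (inherits(terms, "ergm_terms")) terms else ergm_terms(terms)
  fit$dyadcov <- dyadcov
  fit
}

fit_mple <- function(net, model, control) {
  X <- change_matrix(net, model)
  yvec <- attr(X, "y")
  if (all(yvec == 1L)) data_error("complete network: pseudolikelihood separates")
  if (all(yvec == 0L)) data_error("empty network: pseudolikelihood separates")
  gf <- suppressWarnings(
    glm.fit(X, yvec, family = binomial(), intercept = FALSE)
  )
  theta <- gf$coefficients
  quasi <- any(!is.finite(theta)) || any(abs(theta) > 20) || !gf$converged
  if (quasi) {
    warning("quasi-separation detected in pseudolikelihood fit",
            call. = FALSE)
    if (control$ridge > 0) {
      obj <- function(th) -pseudolik(th, X, yvec) + control$ridge * sum(th^2)
      grd <- function(th) {
        p <- plogis(drop(X %*% th))
        -drop(crossprod(X, yvec - p)) + 2 * control$ridge * th
      }
      start <- ifelse(is.finite(theta), pmin(pmax(theta, -20), 20), 0)
      theta <- optim(start, obj, grd, method = "BFGS",
                     control = list(maxit = 500))$par
    }
  }
  names(theta) <- model$names
  p <- plogis(drop(X %*% theta))
  w <- pmax(p * (1 - p), 1e-12)
  info <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, length(theta), length(theta))
  })
  dimnames(vcov) <- list(model$names, model$names)
  ll <- pseudolik(theta, X, yvec)
  n <- network_size(net)
  m <- n * (n - 1)
  k <- length(theta)
  ic <- information_criteria(ll, k, m)
  structure(list(
    coefficients = theta, se = sqrt(diag(vcov)), vcov = vcov,
    loglik = ll, loglik_kind = "pseudolikelihood",
    k = k, m = m, n = n, aic = ic[["aic"]], bic = ic[["bic"]],
    method = "mple", converged = gf$converged && !quasi,
    quasi_separation = quasi, control = control, seed = control$seed,
    u_obs = network_statistics(net, model)
  ), class = "referral_ergm")
}

log_mean_exp <- function(x) {
  mx <- max(x)
  mx + log(mean(exp(x - mx)))
}

## One Geyer-Thompson maximization: maximize
##   (theta - theta0) . u_obs - log mean exp((theta - theta0) . S)
## by Newton.  The importance approximation is only trustworthy near the
## sampling point theta0, so both the per-Newton step and the total
## displacement of one round are capped in the infinity norm.
gt_maximize <- function(theta0, u_obs, S, step_cap = 0.5, total_cap = 1,
                        max_inner = 50) {
  theta <- theta0
  for (it in seq_len(max_inner)) {
    lw <- drop(S %*% (theta - theta0))
    lw <- lw - log_mean_exp(lw) - log(nrow(S))
    w <- exp(lw)
    mu <- drop(crossprod(S, w))
    grad <- u_obs - mu
    Sc <- sweep(S, 2, mu)
    H <- crossprod(Sc * sqrt(w), Sc * sqrt(w))
    step <- tryCatch(solve(H + diag(1e-8, ncol(S)), grad),
                     error = function(e) grad / max(diag(H), 1))
    if (max(abs(step)) > step_cap) step <- step * step_cap / max(abs(step))
    theta <- theta + step
    disp <- theta - theta0
    if (max(abs(disp)) > total_cap) {
      theta <- theta0 + disp * total_cap / max(abs(disp))
      break
    }
    if (max(abs(step)) < 1e-6) break
  }
  theta
}

sample_stats <- function(net, model, theta, burnin, interval, nsamples,
                         init = NULL) {
  enc <- encode_model(model)
  y0 <- init %||% net$adjacency
  u0 <- network_statistics(
    referral_network(y0, net$nodes, net$district, net$domain), model)
  out <- tnt_sampler_cpp(y0, theta, enc$codes, enc$decay, enc$vecs, enc$mats,
                         u0, as.integer(burnin), as.integer(interval),
                         as.integer(nsamples), FALSE)
  S <- out$stats
  colnames(S) <- model$names
  list(stats = S, final = out$final)
}

fit_mcmc_mle <- function(net, model, control, theta0, mple) {
  if (!is.null(control$seed)) set.seed(control$seed)
  if (any(!is.finite(theta0))) data_error("non-finite starting coefficients")
  u_obs <- network_statistics(net, model)
  theta <- theta0
  converged <- FALSE
  S <- NULL
  init <- net$adjacency
  for (iter in seq_len(control$max_iter)) {
    sim <- sample_stats(net, model, theta, control$burnin, control$interval,
                        control$n_samples, init = init)
    S <- sim$stats
    init <- sim$final
    lo <- apply(S, 2, min); hi <- apply(S, 2, max)
    outside <- u_obs < lo | u_obs > hi
    if (any(outside)) {
      degeneracy_error(
        sprintf(paste0("observed statistic(s) outside the simulated range: %s; ",
                       "the model appears degenerate at the current estimate"),
                paste(model$names[outside], collapse = ", ")),
        payload = list(theta = theta, u_obs = u_obs,
                       sim_mean = colMeans(S), sim_min = lo, sim_max = hi))
    }
    theta_new <- gt_maximize(theta, u_obs, S)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < control$tol) { converged <- TRUE; break }
  }
  ## final simulation at the estimate: Fisher information = Cov(u)
  sim <- sample_stats(net, model, theta, control$burnin, control$interval,
                      control$n_samples, init = init)
  Sf <- sim$stats
  fisher <- cov(Sf)
  vcov <- tryCatch(solve(fisher + diag(1e-10, ncol(Sf))),
                   error = function(e)
                     matrix(NA_real_, length(theta), length(theta)))
  dimnames(vcov) <- list(model$names, model$names)
  n <- network_size(net)
  m <- n * (n - 1)
  ll <- bridge_loglik(net, model, theta, u_obs, control)
  k <- length(theta)
  ic <- information_criteria(ll, k, m)
  names(theta) <- model$names
  structure(list(
    coefficients = theta, se = sqrt(diag(vcov)), vcov = vcov,
    loglik = ll, loglik_kind = "mcmc_likelihood",
    k = k, m = m, n = n, aic = ic[["aic"]], bic = ic[["bic"]],
    method = "mcmc_mle", converged = converged,
    quasi_separation = mple$quasi_separation,
    iterations = iter, control = control, seed = control$seed,
    u_obs = u_obs, sim_stats = Sf, mple = mple$coefficients
  ), class = "referral_ergm")
}

## Path-sampled log-likelihood by thermodynamic integration along the linear
## path t * theta, t in [0, 1]:
##   log Z(theta) - log Z(0) = int_0^1 theta . E_{t theta}[u] dt,
## approximated by the midpoint rule with simulated expectations; Z(0) = 2^m
## for a binary digraph.
bridge_loglik <- function(net, model, theta, u_obs, control) {
  K <- control$bridge_steps
  m <- network_size(net) * (network_size(net) - 1)
  burn <- max(1e4, 10 * m)
  logz <- 0
  init <- net$adjacency
  ## walk the path from the fitted end towards the null so each step's chain
  ## warm-starts near its stationary distribution (the observed network is
  ## typical at theta-hat, not at theta = 0)
  interval <- max(control$interval, m)   # decorrelate draws on the path
  for (jj in rev(seq_len(K))) {
    t_mid <- (jj - 0.5) / K
    sim <- sample_stats(net, model, theta * t_mid, burn, interval,
                        control$bridge_samples, init = init)
    init <- sim$final
    logz <- logz + sum(theta * colMeans(sim$stats)) / K
  }
  sum(theta * u_obs) - m * log(2) - logz
}

#' AIC and BIC for a network model
#'
#' `AIC = -2 l + 2 k`; `BIC = -2 l + k log(m)` with the sample size taken
#' as the number of directed dyads `m = n (n - 1)`.
#'
#' @param loglik log-likelihood `l`.
#' @param k number of estimated coefficients (fixed gwidegree decays do not
#'   count).
#' @param m number of directed dyads.
#' @return named numeric vector `c(aic, bic)`.
#' @export
information_criteria <- function(loglik, k, m) {
  if (m < 1) usage_error("m must be >= 1")
  if (k < 0) usage_error("k must be >= 0")
  c(aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(m))
}

#' @export
coef.referral_ergm <- function(object, ...) object$coefficients

#' @export
vcov.referral_ergm <- function(object, ...) object$vcov

#' @export
logLik.referral_ergm <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$m,
            kind = object$loglik_kind, class = "logLik")
}

#' @export
print.referral_ergm <- function(x, ...) {
  cat(sprintf("Directed ERGM (%s)%s\n", x$method,
              if (x$converged) "" else " [not converged]"))
  print(round(x$coefficients, 4))
  cat(sprintf("%s: %.2f   AIC: %.2f   BIC: %.2f   (k = %d, dyads = %d)\n",
              x$loglik_kind, x$loglik, x$aic, x$bic, x$k, x$m))
  invisible(x)
}

#' @export
summary.referral_ergm <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(coefficients = tab, fit = object),
            class = "summary.referral_ergm")
}

#' @export
print.summary.referral_ergm <- function(x, ...) {
  f <- x$fit
  cat(sprintf("Directed ERGM fitted by %s%s\n", f$method,
              if (f$converged) "" else " [not converged]"))
  printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("%s: %.2f   AIC: %.2f   BIC: %.2f\n",
              f$loglik_kind, f$loglik, f$aic, f$bic))
  invisible(x)
}

#' @importFrom stats pnorm printCoefmat simulate
NULL

#' Simulate networks from an ERGM
#'
#' Draws networks with the tie/no-tie Metropolis sampler at the supplied
#' coefficients, starting from `init` (default: the observed network),
#' discarding `burnin` proposals and spacing retained draws by `interval`.
#'
#' @param net a `referral_network` supplying the node set and covariates.
#' @param terms an `ergm_terms` specification (or resolved model).
#' @param theta coefficient vector (finite).
#' @param dyadcov named list of dyadic covariate matrices.
#' @param nsamples number of networks to return.
#' @param burnin,interval sampler settings (proposal counts).
#' @param seed integer seed (optional; `set.seed` is called when supplied).
#' @param init starting adjacency matrix, or `"empty"`.
#' @param return_stats if `TRUE` return the statistic matrix instead of
#'   network objects.
#' @return a list of `referral_network` objects, or an
#'   `nsamples x p` statistic matrix when `return_stats = TRUE`.
#' @export
simulate_networks <- function(net, terms, theta, dyadcov = list(),
                              nsamples = 100, burnin = 1e5, interval = 1e3,
                              seed = NULL, init = NULL,
                              return_stats = FALSE) {
  if (any(!is.finite(theta))) usage_error("theta must be finite")
  if (network_size(net) < 2) usage_error("need at least 2 nodes to simulate")
  model <- if (inherits(terms, "ergm_model")) terms
           else resolve_terms(terms, net, dyadcov)
  if (length(theta) != length(model$terms)) {
    usage_error("theta has %d entries for %d terms", length(theta),
                length(model$terms))
  }
  if (!is.null(seed)) set.seed(seed)
  y0 <- if (identical(init, "empty")) {
    matrix(0L, network_size(net), network_size(net))
  } else init %||% net$adjacency
  u0 <- network_statistics(
    referral_network(y0, net$nodes, net$district, net$domain), model)
  enc <- encode_model(model)
  out <- tnt_sampler_cpp(y0, theta, enc$codes, enc$decay, enc$vecs, enc$mats,
                         u0, as.integer(burnin), as.integer(interval),
                         as.integer(nsamples), !return_stats)
  if (return_stats) {
    S <- out$stats
    colnames(S) <- model$names
    return(S)
  }
  n <- network_size(net)
  lapply(out$networks, function(el) {
    y <- matrix(0L, n, n)
    if (nrow(el) > 0) y[el] <- 1L
    referral_network(y, net$nodes, net$district, net$domain)
  })
}

#' @export
simulate.referral_ergm <- function(object, nsim = 100, seed = NULL, ...) {
  simulate_networks(object$network, object$model, object$coefficients,
                    nsamples = nsim,
                    burnin = object$control$burnin,
                    interval = object$control$interval, seed = seed, ...)
}

#' Serialize a fit to JSON
#'
#' Writes coefficients, standard errors, log-likelihood (with its kind),
#' AIC/BIC, gwidegree decay(s), seed and sampler settings.
#'
#' @param fit a `referral_ergm` object.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_fit_json <- function(fit, path) {
  decays <- unlist(lapply(fit$terms, function(t)
    if (t$kind == "gwidegree") t$decay else NULL))
  obj <- list(
    method = fit$method,
    coefficients = as.list(fit$coefficients),
    ses = as.list(setNames(fit$se, names(fit$coefficients))),
    loglik = fit$loglik, loglik_kind = fit$loglik_kind,
    k = fit$k, dyads = fit$m, aic = fit$aic, bic = fit$bic,
    decay = if (length(decays)) decays else NULL,
    converged = fit$converged,
    seed = fit$seed,
    sampler = list(burnin = fit$control$burnin,
                   interval = fit$control$interval,
                   n_samples = fit$control$n_samples)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
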