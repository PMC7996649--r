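#' Parse a compact model-term specification string
#'
#' Terms are joined with `+`; supported atoms are `edges`, `isolates`,
#' `gwidegree(decay)`, `edgecov(name[,transform])`,
#' `nodeifactor(attr,level)`, `nodefactor(attr,level)`,
#' `nodeicov(attr[,transform])`, `nodeocov(attr[,transform])` and
#' `nodecov(attr[,transform])`.  Example:
#' `"edges+isolates+gwidegree(0.7)+edgecov(distance,log1p)+nodeifactor(tier,hospital)"`.
#'
#' @param spec specification string.
#' @return an `ergm_terms` list.
#' @export
parse_terms <- function(spec) {
  atoms <- trimws(strsplit(spec, "+", fixed = TRUE)[[1]])
  atoms <- atoms[nzchar(atoms)]
  if (length(atoms) == 0) usage_error("empty term specification")
  terms <- lapply(atoms, function(a) {
    m <- regmatches(a, regexec("^([a-z]+)(\\(([^)]*)\\))?$", a))[[1]]
    if (length(m) == 0) usage_error("cannot parse term '%s'", a)
    head_ <- m[2]
    args <- if (nzchar(m[4])) trimws(strsplit(m[4], ",")[[1]]) else character(0)
    tr <- function(i, default = "identity") {
      if (length(args) >= i) args[i] else default
    }
    switch(head_,
      edges = ergm_term("edges"),
      isolates = ergm_term("isolates"),
      gwidegree = ergm_term("gwidegree", decay = as.numeric(tr(1, NA))),
      edgecov = ergm_term("edgecov", attribute = tr(1), transform = tr(2)),
      nodeifactor = ergm_term("node_factor_in", attribute = tr(1),
                              level = tr(2)),
      nodefactor = ergm_term("node_factor_combined", attribute = tr(1),
                             level = tr(2)),
      nodeicov = ergm_term("node_cov_in", attribute = tr(1),
                           transform = tr(2)),
      nodeocov = ergm_term("node_cov_out", attribute = tr(1),
                           transform = tr(2)),
      nodecov = ergm_term("node_cov_combined", attribute = tr(1),
                          transform = tr(2)),
      usage_error("unknown term '%s'", head_)
    )
  })
  ergm_terms(terms)
}

write_manifest <- function(out_dir, command, params, seed) {
  manifest <- list(
    command = command,
    package = "referralnet",
    version = as.character(utils::packageVersion("referralnet")),
    r_version = as.character(getRversion()),
    seed = seed,
    params = params
  )
  path <- file.path(out_dir, sprintf("manifest_%s.json", command))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Pipeline command: generate a synthetic district on disk
#'
#' Generates a roster, distance matrix and a referral record set drawn from
#' a ground-truth ERGM, and writes `facilities.csv`, `referrals.csv`,
#' `distances.csv` plus a machine-readable manifest (configuration, package
#' version, seed) to `out_dir`.  Rerunning with the same arguments is
#' byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param seed integer seed (mandatory).
#' @param theta,terms ground-truth model; default is an edges-only model at
#'   the sparse density typical of referral networks (2 percent of dyads).
#' @param domain care domain label for the generated records.
#' @return invisibly, the vector of written file paths.
#' @export
cmd_simulate <- function(out_dir, config = kilolo_config(), seed,
                         theta = qlogis(0.02), terms = ergm_terms(ergm_term("edges")),
                         domain = "childcare") {
  if (missing(seed) || is.null(seed)) usage_error("seed is mandatory")
  ensure_dir(out_dir)
  roster <- generate_roster(config, seed)
  distances <- generate_distances(roster, config)
  net <- generate_network(roster, distances, theta, terms, domain = domain,
                          seed = seed + 1L)
  edge <- which(net$adjacency == 1L, arr.ind = TRUE)
  records <- data.frame(
    sender_id = roster$facility_id[edge[, 1]],
    receiver_id = roster$facility_id[edge[, 2]],
    condition_category = "simulated",
    domain = domain, n_referrals = 1L, stringsAsFactors = FALSE
  )
  records <- records[order(records$sender_id, records$receiver_id), ,
                     drop = FALSE]
  paths <- c(
    write_facility_table(roster, file.path(out_dir, "facilities.csv")),
    write_referral_records(records, file.path(out_dir, "referrals.csv")),
    write_distance_matrix(distances, file.path(out_dir, "distances.csv"))
  )
  write_manifest(out_dir, "simulate",
                 list(district = config$district,
                      n = nrow(roster), theta = theta, domain = domain),
                 seed)
  invisible(paths)
}

#' Pipeline command: descriptive network reports
#'
#' Reads the tabular inputs, assembles the requested network and writes a
#' summary report (nodes, ties, density, tier-to-tier flows) and the
#' centrality rankings (top facilities by in-degree and betweenness).
#'
#' @param facilities,referrals input CSV paths.
#' @param district,domain network selector.
#' @param out_dir output directory.
#' @param top_k ranking depth.
#' @return invisibly, a list with the assembled network and report paths.
#' @export
cmd_describe <- function(facilities, referrals, district, domain, out_dir,
                         top_k = 3) {
  ensure_dir(out_dir)
  roster <- read_facility_table(facilities)
  records <- read_referral_records(referrals, roster)
  net <- assemble_network(records, roster, district, domain)
  summary_path <- file.path(out_dir, "network_summary.csv")
  write.csv(describe_network(net), summary_path, row.names = FALSE)
  cent <- node_betweenness(net)
  rank_path <- file.path(out_dir, "centrality_rankings.csv")
  write.csv(rbind(rank_centrality(cent, "in_degree", top_k),
                  rank_centrality(cent, "betweenness", top_k)),
            rank_path, row.names = FALSE)
  graphml_path <- file.path(out_dir, sprintf("network_%s_%s.graphml",
                                             district, domain))
  write_network_graphml(net, graphml_path)
  write_manifest(out_dir, "describe",
                 list(district = district, domain = domain, top_k = top_k),
                 seed = NULL)
  invisible(list(network = net,
                 paths = c(summary_path, rank_path, graphml_path)))
}

#' Pipeline command: fit an ERGM from files
#'
#' Reads the inputs, assembles the network, fits the model and writes the
#' fit as JSON (coefficients, standard errors, log-likelihood, AIC/BIC,
#' decay, seed, sampler settings) plus a manifest.
#'
#' @param facilities,referrals,distances input CSV paths.
#' @param district,domain network selector.
#' @param terms an `ergm_terms` list or a specification string for
#'   [parse_terms()].
#' @param out_dir output directory.
#' @param method `"mple"` or `"mcmc"`.
#' @param seed integer seed (mandatory for the stochastic `"mcmc"` method).
#' @param control an [ergm_control()]; its seed is overridden by `seed`.
#' @return invisibly, the `referral_ergm` fit.
#' @export
cmd_fit <- function(facilities, referrals, distances, district, domain,
                    terms, out_dir, method = "mple", seed = NULL,
                    control = ergm_control()) {
  if (identical(method, "mcmc") && is.null(seed)) {
    usage_error("seed is mandatory for MCMC estimation")
  }
  ensure_dir(out_dir)
  if (is.character(terms)) terms <- parse_terms(terms)
  roster <- read_facility_table(facilities)
  records <- read_referral_records(referrals, roster)
  net <- assemble_network(records, roster, district, domain)
  dist <- read_distance_matrix(distances, net$nodes)
  control$seed <- seed
  fit <- referral_ergm(net, terms, dyadcov = list(distance = dist),
                       method = method, control = control)
  write_fit_json(fit, file.path(out_dir, "fit.json"))
  write_manifest(out_dir, "fit",
                 list(district = district, domain = domain, method = method,
                      terms = names(fit$terms)), seed)
  invisible(fit)
}

#' Pipeline command: simulation-based goodness of fit from files
#'
#' Fits the model as [cmd_fit()] does, runs [gof()] and writes the
#' envelope report as CSV.  Degeneracy raises a classed error.
#'
#' @inheritParams cmd_fit
#' @param n_sim number of simulated networks (>= 10).
#' @return invisibly, the `referral_gof` report.
#' @export
cmd_gof <- function(facilities, referrals, distances, district, domain,
                    terms, out_dir, method = "mple", seed = NULL,
                    n_sim = 100, control = ergm_control()) {
  if (n_sim < 10) usage_error("n_sim must be >= 10")
  if (is.null(seed)) usage_error("seed is mandatory for goodness-of-fit")
  fit <- cmd_fit(facilities, referrals, distances, district, domain, terms,
                 out_dir, method = method, seed = seed, control = control)
  report <- gof(fit, n_sim = n_sim, seed = seed + 1L)
  write.csv(report$report, file.path(out_dir, "gof_report.csv"),
            row.names = FALSE)
  if (report$degenerate) {
    degeneracy_error("goodness-of-fit simulations indicate degeneracy",
                     payload = report)
  }
  invisible(report)
}

#' Pipeline command: tie-probability scenario prediction from files
#'
#' Fits the model, then reports the conditional tie probability for a dyad
#' under the observed attributes and under modified receiver/sender
#' attributes, writing one CSV row per scenario.
#'
#' @inheritParams cmd_fit
#' @param sender,receiver facility ids of the focal dyad.
#' @param receiver_changes,sender_changes named lists of attribute
#'   replacements, e.g. `list(rooms = 45)`.
#' @return invisibly, the scenario result list.
#' @export
cmd_predict <- function(facilities, referrals, distances, district, domain,
                        terms, out_dir, sender, receiver,
                        receiver_changes = list(), sender_changes = list(),
                        method = "mple", seed = NULL,
                        control = ergm_control()) {
  fit <- cmd_fit(facilities, referrals, distances, district, domain, terms,
                 out_dir, method = method, seed = seed, control = control)
  sc <- scenario_delta(fit, sender, receiver,
                       sender_changes = sender_changes,
                       receiver_changes = receiver_changes)
  out <- data.frame(
    sender = sender, receiver = receiver,
    p_baseline = sc$p_old, p_scenario = sc$p_new,
    relative_change = sc$relative_change,
    percent_change = 100 * sc$relative_change
  )
  write.csv(out, file.path(out_dir, "scenario_prediction.csv"),
            row.names = FALSE)
  invisible(sc)
}
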