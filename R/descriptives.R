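#' Network density
#'
#' Fraction of existing directed ties out of all `n (n - 1)` possible ties.
#'
#' @param net a `referral_network` with at least 2 nodes.
#' @return a number in `[0, 1]`.
#' @export
network_density <- function(net) {
  n <- network_size(net)
  if (n < 2) data_error("density undefined for networks with fewer than 2 nodes")
  network_edge_count(net) / (n * (n - 1))
}

#' Tier-to-tier referral flow counts
#'
#' Cross-tabulates directed ties by the sender and receiver facility tier,
#' and additionally counts ties whose receiver is private or faith-based and
#' ties that cross the network's district boundary.  The tier-pair counts
#' always sum to the total tie count.
#'
#' @param net a `referral_network`; every node must carry a tier.
#' @return an object of class `tier_flow_table`: a list with `flows` (3x3
#'   integer matrix, sender tier x receiver tier), `to_private_or_faith`
#'   and `outside_district` counts, and `total`.
#' @export
tier_flow_counts <- function(net) {
  tier <- net$nodes$tier
  if (anyNA(tier) || any(!tier %in% TIERS)) {
    data_error("every node needs a valid tier to tabulate flows")
  }
  edge <- which(net$adjacency == 1L, arr.ind = TRUE)
  flows <- matrix(0L, 3, 3, dimnames = list(TIERS, TIERS))
  if (nrow(edge) > 0) {
    tab <- table(factor(tier[edge[, 1]], levels = TIERS),
                 factor(tier[edge[, 2]], levels = TIERS))
    flows <- flows + unclass(tab)
  }
  recv <- edge[, 2]
  structure(
    list(
      flows = flows,
      to_private_or_faith =
        sum(net$nodes$ownership[recv] %in% c("private", "faith_based")),
      outside_district = sum(net$nodes$district[recv] != net$district),
      total = nrow(edge)
    ),
    class = "tier_flow_table"
  )
}

#' @export
print.tier_flow_table <- function(x, ...) {
  cat("Tier-to-tier referral flows (sender rows, receiver columns):\n")
  print(x$flows)
  cat(sprintf("To private/faith-based receivers: %d\n", x$to_private_or_faith))
  cat(sprintf("Crossing district boundary: %d\n", x$outside_district))
  cat(sprintf("Total ties: %d\n", x$total))
  invisible(x)
}

#' Referral rate per fixed number of visits
#'
#' @param tie_count number of referrals (ties).
#' @param visit_total total visits over the same window; must be positive.
#' @param scale visits denominator, e.g. 10000 for "per 10 000 visits".
#' @return `tie_count / visit_total * scale`.
#' @export
referral_rate <- function(tie_count, visit_total, scale = 10000) {
  if (visit_total <= 0) {
    data_error("referral rate undefined: visit_total must be positive")
  }
  tie_count / visit_total * scale
}

#' Per-node degree summary
#'
#' In-degree counts incoming referrals (how strongly a facility attracts
#' referrals); out-degree counts outgoing referrals.  The in-degree
#' distribution `D_k` records the number of nodes with in-degree `k` for
#' `k = 0 .. n-1`; it satisfies `sum(D_k) == n` and
#' `sum(k * D_k) == edge count`.
#'
#' @param net a `referral_network`.
#' @return a list with `nodes` (`data.frame`: facility_id, in_degree,
#'   out_degree) and `indegree_distribution` (named integer vector over
#'   `k = 0 .. n-1`).
#' @export
degree_summary <- function(net) {
  y <- net$adjacency
  n <- nrow(y)
  indeg <- colSums(y)
  outdeg <- rowSums(y)
  dist <- tabulate(indeg + 1L, nbins = n)
  names(dist) <- 0:(n - 1)
  list(
    nodes = data.frame(facility_id = net$nodes$facility_id,
                       in_degree = as.integer(indeg),
                       out_degree = as.integer(outdeg),
                       stringsAsFactors = FALSE, row.names = NULL),
    indegree_distribution = dist
  )
}

#' Betweenness centrality of facilities
#'
#' Raw (unnormalized) directed betweenness on the binary network: for each
#' facility, the number of shortest directed paths between ordered pairs of
#' other facilities that pass through it, with fractional attribution when
#' several shortest paths tie; endpoints are excluded.  This operationalizes
#' gatekeeping: a health centre on the dispensary-to-hospital path scores,
#' the endpoints do not.
#'
#' @param net a `referral_network`.
#' @return a `data.frame` with `facility_id`, `in_degree` and `betweenness`,
#'   in node order.
#' @export
node_betweenness <- function(net) {
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = TRUE, weights = NA)
  data.frame(
    facility_id = net$nodes$facility_id,
    in_degree = as.integer(colSums(net$adjacency)),
    betweenness = as.numeric(b),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Rank facilities by a centrality measure
#'
#' @param table a `data.frame` with a `facility_id` column and the score
#'   columns produced by [node_betweenness()].
#' @param measure `"in_degree"` or `"betweenness"`.
#' @param top_k number of facilities to return (>= 1).
#' @return the `top_k` rows ordered by descending score; ties broken by
#'   lexicographic `facility_id`.
#' @export
rank_centrality <- function(table, measure = c("in_degree", "betweenness"),
                            top_k = 3) {
  measure <- match.arg(measure)
  if (top_k < 1) usage_error("top_k must be >= 1")
  score <- table[[measure]]
  ord <- order(-score, table$facility_id)
  out <- table[head(ord, top_k), c("facility_id", measure), drop = FALSE]
  names(out) <- c("facility_id", "score")
  out$measure <- measure
  rownames(out) <- NULL
  out
}

#' District summary report in the shape of the descriptive tables
#'
#' Convenience wrapper producing one row per summary statistic for a
#' network: node/tie counts, density (3 decimals for reporting), tier-pair
#' flows and ownership/district margins.
#'
#' @param net a `referral_network`.
#' @return a two-column `data.frame` (`statistic`, `value`).
#' @export
describe_network <- function(net) {
  fl <- tier_flow_counts(net)
  pairs <- expand.grid(from = TIERS, to = TIERS, stringsAsFactors = FALSE)
  flow_rows <- data.frame(
    statistic = sprintf("ties_%s_to_%s", pairs$from, pairs$to),
    value = as.numeric(fl$flows[cbind(pairs$from, pairs$to)]),
    stringsAsFactors = FALSE
  )
  rbind(
    data.frame(statistic = c("nodes", "ties", "density",
                             "to_private_or_faith", "outside_district"),
               value = c(network_size(net), network_edge_count(net),
                         round(network_density(net), 3),
                         fl$to_private_or_faith, fl$outside_district),
               stringsAsFactors = FALSE),
    flow_rows
  )
}
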