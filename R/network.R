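#' Construct a referral network object
#'
#' A `referral_network` is a simple directed binary graph over a fixed,
#' ordered facility node set: `adjacency[i, j] == 1` iff at least one
#' referral from facility `i` to facility `j` was recorded, regardless of
#' condition category or multiplicity (referral ledgers are coded to binary
#' non-weighted networks).  Self-ties are forbidden.
#'
#' @param adjacency square 0/1 matrix; dimnames give the node order.
#' @param nodes `data.frame` of node attributes (one row per node, in node
#'   order) containing at least `facility_id`, `tier`, `ownership`,
#'   `district`.
#' @param district district label of the network.
#' @param domain care domain, `"childcare"` or `"ncd"`.
#' @return an object of class `referral_network`.
#' @export
referral_network <- function(adjacency, nodes, district = "", domain = "") {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) data_error("adjacency must be square")
  if (!all(adjacency %in% c(0L, 1L))) {
    data_error("adjacency entries must be 0 or 1")
  }
  if (any(diag(adjacency) != 0L)) data_error("self-ties are not allowed")
  if (nrow(nodes) != n) data_error("nodes table must have one row per node")
  dimnames(adjacency) <- list(nodes$facility_id, nodes$facility_id)
  structure(
    list(adjacency = adjacency, nodes = nodes,
         district = district, domain = domain),
    class = "referral_network"
  )
}

#' @export
print.referral_network <- function(x, ...) {
  cat(sprintf("Referral network: district=%s domain=%s\n",
              x$district, x$domain))
  cat(sprintf("  %d nodes, %d directed ties, density %.4f\n",
              network_size(x), network_edge_count(x),
              if (network_size(x) > 1) network_density(x) else NA_real_))
  invisible(x)
}

#' Basic size accessors for referral networks
#' @param net a `referral_network`.
#' @return node count / directed tie count.
#' @export
network_size <- function(net) nrow(net$adjacency)

#' @rdname network_size
#' @export
network_edge_count <- function(net) sum(net$adjacency)

#' Assemble a binary directed referral network
#'
#' Restricts the records to one district and care domain, then codes a
#' directed tie for every ordered facility pair with at least one matching
#' referral (any condition category; multiplicities collapse).  The node set
#' is every roster facility of the district plus any external referral
#' destination that appears as a sender or receiver of the district's
#' records; isolates are retained.  Node order is roster order.
#'
#' @param records validated referral records.
#' @param roster validated facility roster (may span several districts; the
#'   roster must contain every facility referenced by the records).
#' @param district district to assemble.
#' @param domain care domain, `"childcare"` or `"ncd"`.
#' @return a `referral_network`.
#' @export
assemble_network <- function(records, roster, district, domain) {
  if (!domain %in% DOMAINS) {
    data_error("unknown domain '%s' (allowed: %s)", domain,
               paste(DOMAINS, collapse = ", "))
  }
  validate_records(records, roster = roster, where = "assemble_network")
  rec <- records[records$domain == domain, , drop = FALSE]
  dist_of <- setNames(roster$district, roster$facility_id)
  in_district <- roster$facility_id[roster$district == district]
  ## a record belongs to the district's network when either endpoint is an
  ## in-district facility; the external counterpart becomes a network node
  keep <- dist_of[rec$sender_id] == district |
    dist_of[rec$receiver_id] == district
  rec <- rec[keep, , drop = FALSE]
  extra <- setdiff(unique(c(rec$sender_id, rec$receiver_id)), in_district)
  node_ids <- c(in_district, extra[order(match(extra, roster$facility_id))])
  idx <- match(node_ids, roster$facility_id)
  nodes <- roster[idx, , drop = FALSE]
  rownames(nodes) <- NULL
  n <- length(node_ids)
  y <- matrix(0L, n, n, dimnames = list(node_ids, node_ids))
  if (nrow(rec) > 0) {
    y[cbind(match(rec$sender_id, node_ids),
            match(rec$receiver_id, node_ids))] <- 1L
  }
  referral_network(y, nodes, district = district, domain = domain)
}

#' Filter referral records by condition category
#'
#' @param records referral records.
#' @param categories character vector of condition categories to keep.
#' @return the matching records, input order preserved.  Unknown categories
#'   trigger a warning; an empty result is allowed.
#' @export
filter_by_category <- function(records, categories) {
  known <- unique(records$condition_category)
  unknown <- setdiff(categories, known)
  if (length(unknown) > 0) {
    warning(sprintf("condition categor%s not present in records: %s",
                    if (length(unknown) > 1) "ies" else "y",
                    paste(unknown, collapse = ", ")))
  }
  records[records$condition_category %in% categories, , drop = FALSE]
}

#' Export / import a referral network as GraphML
#'
#' Writes directed GraphML with node attributes `facility_id` (as the node
#' name), `tier`, `ownership` and `district`, plus graph-level `district`
#' and `domain` attributes; `read_network_graphml()` restores a
#' `referral_network` with identical adjacency and attributes.
#'
#' @param net a `referral_network`.
#' @param path output / input file path.
#' @return `path` invisibly for the writer; a `referral_network` for the
#'   reader.
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  tryCatch(
    igraph::write_graph(g, path, format = "graphml"),
    error = function(e) data_error("cannot write GraphML to %s: %s", path,
                                   conditionMessage(e))
  )
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) data_error("GraphML file not found: %s", path)
  g <- igraph::read_graph(path, format = "graphml")
  ids <- igraph::vertex_attr(g, "name")
  nodes <- data.frame(
    facility_id = ids,
    tier = igraph::vertex_attr(g, "tier"),
    ownership = igraph::vertex_attr(g, "ownership"),
    district = igraph::vertex_attr(g, "district"),
    stringsAsFactors = FALSE
  )
  y <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  y <- (y > 0) + 0L
  dimnames(y) <- list(ids, ids)
  referral_network(
    y, nodes,
    district = igraph::graph_attr(g, "district") %||% "",
    domain = igraph::graph_attr(g, "domain") %||% ""
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a referral network to an igraph graph
#' @param net a `referral_network`.
#' @return a directed `igraph` graph with node and graph attributes.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "directed")
  igraph::V(g)$name <- net$nodes$facility_id
  igraph::V(g)$tier <- net$nodes$tier
  igraph::V(g)$ownership <- net$nodes$ownership
  igraph::V(g)$district <- net$nodes$district
  igraph::graph_attr(g, "district") <- net$district
  igraph::graph_attr(g, "domain") <- net$domain
  g
}
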