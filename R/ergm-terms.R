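TERM_KINDS <- c("edges", "isolates", "gwidegree", "edgecov",
                "node_factor_in", "node_cov_in", "node_cov_out",
                "node_cov_combined", "node_factor_combined")
TRANSFORMS <- c("identity", "log", "log1p")

#' Declare one ERGM model term
#'
#' Terms follow the model structure used for sparse facility referral
#' networks: endogenous structure (`edges`, `isolates`, `gwidegree` with a
#' fixed decay), a dyadic edge covariate (road distance in km), and facility
#' covariates acting on incoming ties, outgoing ties, or both combined.
#' Factor terms (`node_factor_*`) use `dispensary` as the implicit reference
#' level and must name another tier level.
#'
#' @param kind one of `edges`, `isolates`, `gwidegree`, `edgecov`,
#'   `node_factor_in`, `node_cov_in`, `node_cov_out`, `node_cov_combined`,
#'   `node_factor_combined`.
#' @param attribute node attribute (covariate/factor kinds) or dyadic
#'   covariate name (`edgecov`); `NULL` for structural terms.
#' @param level factor level for `node_factor_*` kinds (e.g. `"hospital"`).
#' @param transform covariate transform applied before summation:
#'   `identity`, `log` (requires values >= 1, e.g. catchment population) or
#'   `log1p` (zero-tolerant, for counts).
#' @param decay fixed geometric decay `alpha > 0`; required for, and only
#'   for, `gwidegree`.  The decay is fixed (not curved-estimated) and does
#'   not count as a free coefficient.
#' @return an object of class `ergm_term`.
#' @export
ergm_term <- function(kind, attribute = NULL, level = NULL,
                      transform = "identity", decay = NULL) {
  kind <- match.arg(kind, TERM_KINDS)
  transform <- match.arg(transform, TRANSFORMS)
  if (kind == "gwidegree") {
    if (is.null(decay) || !is.finite(decay) || decay <= 0) {
      usage_error("gwidegree requires a fixed positive decay")
    }
  } else if (!is.null(decay)) {
    usage_error("decay is only meaningful for gwidegree")
  }
  needs_attr <- kind %in% c("edgecov", "node_factor_in", "node_cov_in",
                            "node_cov_out", "node_cov_combined",
                            "node_factor_combined")
  if (needs_attr && is.null(attribute)) {
    usage_error("term '%s' requires an attribute name", kind)
  }
  is_factor <- kind %in% c("node_factor_in", "node_factor_combined")
  if (is_factor) {
    if (is.null(level)) usage_error("factor term '%s' requires a level", kind)
    if (identical(attribute, "tier") && identical(level, "dispensary")) {
      usage_error("dispensary is the factor reference level and cannot appear as a term")
    }
  } else if (!is.null(level)) {
    usage_error("level is only meaningful for factor terms")
  }
  structure(list(kind = kind, attribute = attribute, level = level,
                 transform = transform, decay = decay),
            class = "ergm_term")
}

#' @export
print.ergm_term <- function(x, ...) {
  cat(term_name(x), "\n")
  invisible(x)
}

term_name <- function(t) {
  tr <- if (t$transform != "identity") paste0(t$transform, ".") else ""
  switch(t$kind,
    edges = "edges",
    isolates = "isolates",
    gwidegree = sprintf("gwidegree(%g)", t$decay),
    edgecov = paste0("edgecov.", tr, t$attribute),
    node_factor_in = sprintf("nodeifactor.%s.%s", t$attribute, t$level),
    node_cov_in = paste0("nodeicov.", tr, t$attribute),
    node_cov_out = paste0("nodeocov.", tr, t$attribute),
    node_cov_combined = paste0("nodecov.", tr, t$attribute),
    node_factor_combined = sprintf("nodefactor.%s.%s", t$attribute, t$level)
  )
}

#' Bundle a list of terms into a model specification
#'
#' @param ... `ergm_term` objects (or a single list of them).
#' @return an object of class `ergm_terms` (ordered term list).
#' @export
ergm_terms <- function(...) {
  terms <- list(...)
  if (length(terms) == 1 && is.list(terms[[1]]) &&
      !inherits(terms[[1]], "ergm_term")) {
    terms <- terms[[1]]
  }
  ok <- vapply(terms, inherits, logical(1), what = "ergm_term")
  if (!all(ok)) usage_error("all arguments must be ergm_term objects")
  nm <- vapply(terms, term_name, character(1))
  if (anyDuplicated(nm)) {
    usage_error("duplicated term(s): %s", paste(nm[duplicated(nm)], collapse = ", "))
  }
  structure(terms, names = nm, class = "ergm_terms")
}

apply_transform <- function(x, transform, attribute) {
  switch(transform,
    identity = x,
    log = {
      if (any(x < 1)) {
        data_error("log transform of '%s' requires values >= 1; use log1p for counts",
                   attribute)
      }
      log(x)
    },
    log1p = {
      if (any(x < 0)) data_error("log1p transform of '%s' requires values >= 0",
                                 attribute)
      log1p(x)
    }
  )
}

## Resolve a term list against a network: attach transformed node vectors,
## dyadic matrices and integer kind codes (shared with the C++ sampler).
resolve_terms <- function(terms, net, dyadcov = list()) {
  if (!inherits(terms, "ergm_terms")) terms <- ergm_terms(terms)
  n <- network_size(net)
  nodes <- net$nodes
  resolved <- lapply(seq_along(terms), function(k) {
    t <- terms[[k]]
    vec <- NULL
    mat <- NULL
    if (t$kind == "edgecov") {
      mat <- dyadcov[[t$attribute]]
      if (is.null(mat)) {
        data_error("dyadic covariate '%s' not supplied", t$attribute)
      }
      mat <- as.matrix(mat)
      if (!all(dim(mat) == n)) {
        data_error("dyadic covariate '%s' must be %d x %d", t$attribute, n, n)
      }
      if (!is.null(rownames(mat)) &&
          !identical(rownames(mat), nodes$facility_id)) {
        mat <- mat[nodes$facility_id, nodes$facility_id, drop = FALSE]
      }
      mat <- apply_transform(mat, t$transform, t$attribute)
    } else if (t$kind %in% c("node_factor_in", "node_factor_combined")) {
      a <- nodes[[t$attribute]]
      if (is.null(a)) data_error("node attribute '%s' not found", t$attribute)
      vec <- as.numeric(a == t$level)
    } else if (t$kind %in% c("node_cov_in", "node_cov_out",
                             "node_cov_combined")) {
      a <- nodes[[t$attribute]]
      if (is.null(a)) data_error("node attribute '%s' not found", t$attribute)
      if (anyNA(a)) {
        data_error("missing value of '%s' for node %s", t$attribute,
                   paste(nodes$facility_id[is.na(a)], collapse = ", "))
      }
      vec <- apply_transform(as.numeric(a), t$transform, t$attribute)
    }
    list(kind = t$kind, code = match(t$kind, TERM_KINDS),
         name = term_name(t), vec = vec, mat = mat,
         decay = t$decay %||% 0)
  })
  structure(list(terms = resolved, n = n,
                 names = vapply(resolved, `[[`, character(1), "name")),
            class = "ergm_model")
}

#' Sufficient network statistics of an ERGM specification
#'
#' Computes the statistic vector `u(y)`: `edges` is the tie count;
#' `isolates` counts nodes with zero total degree; `gwidegree(alpha)` is
#' `exp(a) * sum_k (1 - (1 - exp(-a))^k) * D_k` over in-degrees `k >= 1`;
#' `edgecov` is `sum y_ij x_ij`; node covariate/factor terms sum the
#' (transformed) sender and/or receiver attribute over ties.
#'
#' @param net a `referral_network`.
#' @param terms an `ergm_terms` list (or resolved model).
#' @param dyadcov named list of dyadic covariate matrices (e.g.
#'   `list(distance = mat)`).
#' @return named numeric vector, one entry per term.
#' @export
network_statistics <- function(net, terms, dyadcov = list()) {
  model <- if (inherits(terms, "ergm_model")) terms
           else resolve_terms(terms, net, dyadcov)
  y <- net$adjacency
  indeg <- colSums(y)
  outdeg <- rowSums(y)
  n <- nrow(y)
  u <- vapply(model$terms, function(t) {
    switch(t$kind,
      edges = sum(y),
      isolates = sum(indeg + outdeg == 0),
      gwidegree = {
        a <- t$decay
        k <- seq_len(max(1, n - 1))
        Dk <- tabulate(indeg, nbins = n - 1)
        exp(a) * sum((1 - (1 - exp(-a))^k) * Dk)
      },
      edgecov = sum(y * t$mat),
      node_factor_in = sum(indeg * t$vec),
      node_cov_in = sum(indeg * t$vec),
      node_cov_out = sum(outdeg * t$vec),
      node_cov_combined = sum((indeg + outdeg) * t$vec),
      node_factor_combined = sum((indeg + outdeg) * t$vec)
    )
  }, numeric(1))
  setNames(u, model$names)
}

#' Change statistics for one dyad
#'
#' `delta_ij = u(y with tie i->j present) - u(y with tie i->j absent)`,
#' evaluated holding every other tie at its current state (the focal tie is
#' first removed if present).  The conditional log-odds of the tie is
#' `theta . delta_ij`.
#'
#' @param net a `referral_network`.
#' @param terms an `ergm_terms` list or resolved model.
#' @param i,j sender and receiver node indices (or facility ids); `i != j`.
#' @param dyadcov named list of dyadic covariate matrices.
#' @return named numeric vector `delta_ij`.
#' @export
change_statistics <- function(net, terms, i, j, dyadcov = list()) {
  model <- if (inherits(terms, "ergm_model")) terms
           else resolve_terms(terms, net, dyadcov)
  ids <- net$nodes$facility_id
  if (is.character(i)) i <- match(i, ids)
  if (is.character(j)) j <- match(j, ids)
  if (is.na(i) || is.na(j)) data_error("dyad endpoints not found in network")
  if (i == j) usage_error("change statistics undefined on the diagonal (i == j)")
  y <- net$adjacency
  yij <- y[i, j]
  indeg <- colSums(y)
  outdeg <- rowSums(y)
  delta <- vapply(model$terms, function(t) {
    switch(t$kind,
      edges = 1,
      isolates = {
        deg_i <- indeg[i] + outdeg[i] - yij
        deg_j <- indeg[j] + outdeg[j] - yij
        -((deg_i == 0) + (deg_j == 0))
      },
      gwidegree = (1 - exp(-t$decay))^(indeg[j] - yij),
      edgecov = t$mat[i, j],
      node_factor_in = t$vec[j],
      node_cov_in = t$vec[j],
      node_cov_out = t$vec[i],
      node_cov_combined = t$vec[i] + t$vec[j],
      node_factor_combined = t$vec[i] + t$vec[j]
    )
  }, numeric(1))
  setNames(delta, model$names)
}

## All-dyad change-statistic matrix (m x p), dyads enumerated in node order,
## row-major: (1,2), (1,3), ..., (2,1), ...  Each row is delta for that dyad
## computed with the focal tie removed.  This is the MPLE design matrix.
change_matrix <- function(net, model) {
  y <- net$adjacency
  n <- nrow(y)
  ## dyads in node order, row-major: (1,2), (1,3), ..., (2,1), ...
  idx <- cbind(rep(seq_len(n), each = n), rep.int(seq_len(n), n))
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  ii <- idx[, 1]; jj <- idx[, 2]
  yfocal <- y[cbind(ii, jj)]
  indeg <- colSums(y)
  outdeg <- rowSums(y)
  tot <- indeg + outdeg
  cols <- lapply(model$terms, function(t) {
    switch(t$kind,
      edges = rep(1, length(ii)),
      isolates = -(((tot[ii] - yfocal) == 0) + ((tot[jj] - yfocal) == 0)),
      gwidegree = (1 - exp(-t$decay))^(indeg[jj] - yfocal),
      edgecov = t$mat[cbind(ii, jj)],
      node_factor_in = t$vec[jj],
      node_cov_in = t$vec[jj],
      node_cov_out = t$vec[ii],
      node_cov_combined = t$vec[ii] + t$vec[jj],
      node_factor_combined = t$vec[ii] + t$vec[jj]
    )
  })
  X <- do.call(cbind, cols)
  colnames(X) <- model$names
  attr(X, "dyads") <- cbind(sender = ii, receiver = jj)
  attr(X, "y") <- yfocal
  X
}

## Encode a resolved model for the C++ sampler.
encode_model <- function(model) {
  list(
    codes = vapply(model$terms, `[[`, numeric(1), "code"),
    decay = vapply(model$terms, `[[`, numeric(1), "decay"),
    vecs = lapply(model$terms, function(t) t$vec %||% numeric(0)),
    mats = lapply(model$terms, function(t) {
      if (is.null(t$mat)) matrix(0, 0, 0) else t$mat
    })
  )
}
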