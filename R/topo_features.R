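#' Topological link features for a (drug, effect) pair
#'
#' All four indices operate on the pharmacological neighborhood
#' \eqn{\Gamma(x)}, the set of nodes within two hops of \eqn{x} (excluding
#' \eqn{x} itself): common-neighbor count
#' \eqn{N(d,e) = |\Gamma(d) \cap \Gamma(e)|}; Jaccard coefficient
#' \eqn{S(d,e) = |\Gamma(d) \cap \Gamma(e)| / |\Gamma(d) \cup \Gamma(e)|}
#' (0 when both neighborhoods are empty); Adamic-Adar index
#' \eqn{A(d,e) = \sum_{z} 1/\ln|\Gamma(z)|} over common-neighborhood nodes
#' \eqn{z} with \eqn{|\Gamma(z)| > 1} (natural log; smaller neighborhoods make
#' a common neighbor more informative); preferential attachment
#' \eqn{PA(d,e) = |\Gamma(d)| \cdot |\Gamma(e)|}.
#'
#' The queried pair need not be an edge of the graph. The default convention
#' measures the graph exactly as given: recorded edges are featurized with
#' themselves present (the query edge is never removed) and non-edges (e.g.
#' sampled pseudo-negatives) are featurized in their absence. `insert = TRUE`
#' temporarily inserts a missing pair before measuring; it is the convention
#' for hypothetical edges, which are individually inserted and then scored
#' (see [classify_hypothetical()]).
#'
#' @param x A [deg].
#' @param drug_id,effect_id Node ids; the drug must exist in the drug partite
#'   set and the effect in the effect set.
#' @return `common_neighbors` and `preferential_attachment` return an integer
#'   count; `jaccard_coefficient` a number in \[0, 1\]; `adamic_adar` a
#'   non-negative number.
#' @name topo_features
NULL

check_pair <- function(x, drug_id, effect_id) {
  if (!drug_id %in% x$drugs$id) stop("unknown drug node id: ", drug_id, call. = FALSE)
  if (!effect_id %in% x$effects$id) stop("unknown effect node id: ", effect_id, call. = FALSE)
  invisible(TRUE)
}

# Core feature computation against a prebuilt adjacency + Gamma cache.
# `insert` temporarily adds the pair when absent; the Gamma sets of the two
# endpoints and of every node one hop from either endpoint are recomputed
# (adding edge (d, e) can only change Gamma(z) for z in {d, e} or adjacent to
# d or e, since Gamma is a two-hop set).
feat_pair <- function(adj, gammas, dtag, etag, insert) {
  if (insert && !(etag %in% adj[[dtag]])) {
    adj[[dtag]] <- c(adj[[dtag]], etag)
    adj[[etag]] <- c(adj[[etag]], dtag)
    affected <- unique(c(dtag, etag, adj[[dtag]], adj[[etag]]))
    for (a in affected) gammas[[a]] <- gamma_set(adj, a)
  }
  gd <- gammas[[dtag]]
  ge <- gammas[[etag]]
  common <- intersect(gd, ge)
  n_union <- length(gd) + length(ge) - length(common)
  jac <- if (n_union == 0L) 0 else length(common) / n_union
  aa <- 0
  for (z in common) {
    sz <- length(gammas[[z]])
    if (sz > 1L) aa <- aa + 1 / log(sz)
  }
  c(degree_d = length(adj[[dtag]]),
    degree_e = length(adj[[etag]]),
    common_neighbors = length(common),
    jaccard = jac,
    adamic_adar = aa,
    pref_attach = length(gd) * length(ge))
}

all_gammas <- function(adj) {
  out <- lapply(names(adj), function(n) gamma_set(adj, n))
  names(out) <- names(adj)
  out
}

#' @rdname topo_features
#' @export
common_neighbors <- function(x, drug_id, effect_id) {
  check_pair(x, drug_id, effect_id)
  adj <- deg_adjacency(x)
  length(intersect(gamma_set(adj, tag_drug(drug_id)),
                   gamma_set(adj, tag_effect(effect_id))))
}

#' @rdname topo_features
#' @export
jaccard_coefficient <- function(x, drug_id, effect_id) {
  check_pair(x, drug_id, effect_id)
  adj <- deg_adjacency(x)
  gd <- gamma_set(adj, tag_drug(drug_id))
  ge <- gamma_set(adj, tag_effect(effect_id))
  u <- union(gd, ge)
  if (!length(u)) 0 else length(intersect(gd, ge)) / length(u)
}

#' @rdname topo_features
#' @export
adamic_adar <- function(x, drug_id, effect_id) {
  check_pair(x, drug_id, effect_id)
  adj <- deg_adjacency(x)
  common <- intersect(gamma_set(adj, tag_drug(drug_id)),
                      gamma_set(adj, tag_effect(effect_id)))
  aa <- 0
  for (z in common) {
    sz <- length(gamma_set(adj, z))
    if (sz > 1L) aa <- aa + 1 / log(sz)
  }
  aa
}

#' @rdname topo_features
#' @export
preferential_attachment <- function(x, drug_id, effect_id) {
  check_pair(x, drug_id, effect_id)
  adj <- deg_adjacency(x)
  length(gamma_set(adj, tag_drug(drug_id))) *
    length(gamma_set(adj, tag_effect(effect_id)))
}

#' Featurize one (drug, effect) pair
#'
#' Computes the full topological feature vector from one neighborhood
#' computation: the two incident-edge degrees (one-hop counts, distinct from
#' the two-hop \eqn{|\Gamma|} sizes used by preferential attachment) plus the
#' four indices of [topo_features].
#'
#' @inheritParams topo_features
#' @param insert Temporarily insert the pair when it is not an edge (see
#'   [topo_features] for the convention). Default `FALSE` (graph as given).
#' @return Named numeric vector with elements `degree_d`, `degree_e`,
#'   `common_neighbors`, `jaccard`, `adamic_adar`, `pref_attach`.
#' @export
featurize_edge <- function(x, drug_id, effect_id, insert = FALSE) {
  check_pair(x, drug_id, effect_id)
  adj <- deg_adjacency(x)
  feat_pair(adj, all_gammas(adj), tag_drug(drug_id), tag_effect(effect_id), insert)
}

#' Featurize many (drug, effect) pairs against one graph
#'
#' Builds the adjacency and neighborhood cache once and featurizes each row of
#' `pairs`. Insertions (for pairs that are not edges) are local and temporary:
#' each pair is measured against the base graph plus only itself.
#'
#' @inheritParams featurize_edge
#' @param pairs Data frame with columns `drug_id`, `effect_id`.
#' @return Data frame: `drug_id`, `effect_id`, then the six feature columns of
#'   [featurize_edge()] in fixed order.
#' @export
featurize_edges <- function(x, pairs, insert = FALSE) {
  stopifnot(inherits(x, "deg"))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_id", "effect_id") %in% names(pairs)))
  bad <- !pairs$drug_id %in% x$drugs$id
  if (any(bad)) stop("unknown drug node id: ", pairs$drug_id[which(bad)[1L]], call. = FALSE)
  bad <- !pairs$effect_id %in% x$effects$id
  if (any(bad)) stop("unknown effect node id: ", pairs$effect_id[which(bad)[1L]], call. = FALSE)
  adj <- deg_adjacency(x)
  gammas <- all_gammas(adj)
  n <- nrow(pairs)
  out <- matrix(0, nrow = n, ncol = 6L,
                dimnames = list(NULL, c("degree_d", "degree_e", "common_neighbors",
                                        "jaccard", "adamic_adar", "pref_attach")))
  dt <- tag_drug(pairs$drug_id)
  et <- tag_effect(pairs$effect_id)
  for (i in seq_len(n)) {
    out[i, ] <- feat_pair(adj, gammas, dt[i], et[i], insert)
  }
  cbind(pairs[, c("drug_id", "effect_id"), drop = FALSE],
        as.data.frame(out))
}

#' Write a feature matrix to CSV
#'
#' Header order is `drug_id`, `effect_id`, `label` (when present), then the
#' feature columns in their fixed order.
#'
#' @param features Data frame as returned by [featurize_edges()] or
#'   [edge_feature_matrix()].
#' @param path Output file.
#' @export
write_feature_matrix <- function(features, path) {
  lead <- intersect(c("drug_id", "effect_id", "label"), names(features))
  rest <- setdiff(names(features), lead)
  utils::write.csv(features[, c(lead, rest), drop = FALSE], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}
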