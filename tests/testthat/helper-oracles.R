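# Independent brute-force oracles, written against the raw edge list only
# (no reuse of the package's adjacency machinery).

# Two-hop neighborhood by explicit BFS over an undirected edge list of tagged
# endpoints ("drug:<id>" / "effect:<id>").
brute_gamma <- function(el, x) {
  nbrs <- function(v) unique(c(el$to[el$from == v], el$from[el$to == v]))
  n1 <- nbrs(x)
  n2 <- unique(unlist(lapply(n1, nbrs)))
  setdiff(unique(c(n1, n2)), x)
}

deg_edge_list <- function(g, extra = NULL) {
  edges <- g$edges[, c("drug_id", "effect_id"), drop = FALSE]
  if (!is.null(extra)) {
    dup <- edges$drug_id == extra[1L] & edges$effect_id == extra[2L]
    if (!any(dup)) {
      edges <- rbind(edges, data.frame(drug_id = extra[1L],
                                       effect_id = extra[2L]))
    }
  }
  data.frame(from = paste0("drug:", edges$drug_id),
             to = paste0("effect:", edges$effect_id),
             stringsAsFactors = FALSE)
}

# Full feature vector via brute-force neighborhoods and direct set algebra.
brute_features <- function(g, drug_id, effect_id, insert = TRUE) {
  el <- deg_edge_list(g, extra = if (insert) c(drug_id, effect_id))
  dt <- paste0("drug:", drug_id)
  et <- paste0("effect:", effect_id)
  gd <- brute_gamma(el, dt)
  ge <- brute_gamma(el, et)
  common <- intersect(gd, ge)
  uni <- union(gd, ge)
  aa <- 0
  for (z in common) {
    s <- length(brute_gamma(el, z))
    if (s > 1) aa <- aa + 1 / log(s)
  }
  c(degree_d = sum(el$from == dt), degree_e = sum(el$to == et),
    common_neighbors = length(common),
    jaccard = if (length(uni)) length(common) / length(uni) else 0,
    adamic_adar = aa,
    pref_attach = length(gd) * length(ge))
}

# Random bipartite DEG with at most `max_drugs` + `max_effects` nodes; uses
# the current RNG state (seed set by the caller).
random_deg <- function(max_drugs = 12L, max_effects = 18L) {
  nd <- sample.int(max_drugs, 1L)
  ne <- sample.int(max_effects, 1L)
  p <- runif(1L, 0.05, 0.5)
  grid <- expand.grid(d = seq_len(nd), e = seq_len(ne))
  keep <- runif(nrow(grid)) < p
  edges <- NULL
  if (any(keep)) {
    edges <- data.frame(drug_id = paste0("d", grid$d[keep]),
                        effect_id = paste0("e", grid$e[keep]),
                        label = "adverse", stringsAsFactors = FALSE)
  }
  deg(drugs = paste0("d", seq_len(nd)), effects = paste0("e", seq_len(ne)),
      edges = edges)
}

# Brute-force mean day gap over all qualifying mention pairs of one user.
brute_user_edges <- function(history, t_window) {
  d <- history[history$entity_class == "drug", , drop = FALSE]
  e <- history[history$entity_class == "effect", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(nrow(e))) {
      gap <- abs(as.numeric(d$date[i] - e$date[j]))
      if (gap <= t_window) {
        key <- paste(d$canonical_id[i], e$canonical_id[j], sep = "\r")
        out[[key]] <- c(out[[key]], gap)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(drug_id = character(), effect_id = character(),
                      temporal_weight = numeric()))
  }
  parts <- strsplit(names(out), "\r", fixed = TRUE)
  data.frame(drug_id = vapply(parts, `[[`, "", 1L),
             effect_id = vapply(parts, `[[`, "", 2L),
             temporal_weight = vapply(out, mean, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
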