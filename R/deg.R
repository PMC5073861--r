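#' Construct a drug-effect graph (DEG)
#'
#' A DEG is a bipartite graph whose partite sets are drugs and effects and
#' whose edges record drug-effect relationships. Edges carry a label
#' (`"adverse"`, `"pseudo_non_adverse"` or `"unlabeled"`) and two optional
#' weights: `temporal_weight`, the mean number of days between the drug and
#' effect mentions that produced the edge, and `frequency_weight`, the number
#' of per-user graphs that contributed the edge.
#'
#' Drug and effect ids are opaque strings kept in disjoint namespaces, so the
#' same string may appear as a drug id and as an effect id without the partite
#' sets intersecting.
#'
#' @param drugs Data frame with columns `id` and `name`, or a character vector
#'   of ids (names default to the ids).
#' @param effects Same form as `drugs`.
#' @param edges Data frame with columns `drug_id` and `effect_id`; optional
#'   columns `label`, `temporal_weight`, `frequency_weight`.
#' @return An object of class `"deg"`: a list with data-frame components
#'   `drugs`, `effects` and `edges`.
#' @examples
#' g <- deg(
#'   drugs = c("d1", "d2"), effects = c("e1", "e2", "e3"),
#'   edges = data.frame(
#'     drug_id = c("d1", "d1", "d2", "d2"),
#'     effect_id = c("e1", "e2", "e2", "e3")
#'   )
#' )
#' g
#' @export
deg <- function(drugs = NULL, effects = NULL, edges = NULL) {
  drugs <- as_node_table(drugs)
  effects <- as_node_table(effects)
  edges <- as_edge_table(edges)
  out <- structure(list(drugs = drugs, effects = effects, edges = edges),
                   class = "deg")
  validate_deg(out)
}

as_node_table <- function(x) {
  if (is.null(x)) {
    return(data.frame(id = character(), name = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.character(x)) x <- data.frame(id = x, name = x, stringsAsFactors = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"id" %in% names(x)) stop("node table needs an `id` column", call. = FALSE)
  if (!"name" %in% names(x)) x$name <- x$id
  x <- x[, c("id", "name")]
  x$id <- as.character(x$id)
  x$name <- as.character(x$name)
  rownames(x) <- NULL
  x
}

as_edge_table <- function(x) {
  if (is.null(x)) {
    return(data.frame(drug_id = character(), effect_id = character(),
                      label = character(), temporal_weight = numeric(),
                      frequency_weight = numeric(), stringsAsFactors = FALSE))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in c("drug_id", "effect_id")) {
    if (!col %in% names(x)) stop("edge table needs a `", col, "` column", call. = FALSE)
    x[[col]] <- as.character(x[[col]])
  }
  if (!"label" %in% names(x)) x$label <- rep("unlabeled", nrow(x))
  if (!"temporal_weight" %in% names(x)) x$temporal_weight <- rep(NA_real_, nrow(x))
  if (!"frequency_weight" %in% names(x)) x$frequency_weight <- rep(NA_real_, nrow(x))
  x$label <- as.character(x$label)
  x$temporal_weight <- as.numeric(x$temporal_weight)
  x$frequency_weight <- as.numeric(x$frequency_weight)
  x <- x[, c("drug_id", "effect_id", "label", "temporal_weight", "frequency_weight")]
  rownames(x) <- NULL
  x
}

edge_labels <- c("adverse", "pseudo_non_adverse", "unlabeled")

validate_deg <- function(x) {
  stopifnot(inherits(x, "deg"))
  for (set in c("drugs", "effects")) {
    ids <- x[[set]]$id
    if (any(is.na(ids) | !nzchar(ids))) {
      stop("empty or missing ", set, " id", call. = FALSE)
    }
    if (anyDuplicated(ids)) {
      stop("duplicate ", set, " ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    }
  }
  e <- x$edges
  if (nrow(e)) {
    bad <- !e$drug_id %in% x$drugs$id
    if (any(bad)) {
      stop("edge references unknown drug id: ",
           paste(unique(e$drug_id[bad]), collapse = ", "), call. = FALSE)
    }
    bad <- !e$effect_id %in% x$effects$id
    if (any(bad)) {
      stop("edge references unknown effect id: ",
           paste(unique(e$effect_id[bad]), collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(pair_key(e$drug_id, e$effect_id))) {
      stop("duplicate (drug, effect) edge", call. = FALSE)
    }
    if (!all(e$label %in% edge_labels)) {
      stop("edge labels must be one of: ", paste(edge_labels, collapse = ", "),
           call. = FALSE)
    }
    tw <- e$temporal_weight
    if (any(!is.na(tw) & (!is.finite(tw) | tw < 0))) {
      stop("temporal_weight must be absent (NA) or finite and >= 0", call. = FALSE)
    }
    fw <- e$frequency_weight
    if (any(!is.na(fw) & fw < 1)) {
      stop("frequency_weight must be absent (NA) or >= 1", call. = FALSE)
    }
  }
  x
}

#' @export
print.deg <- function(x, ...) {
  cat(sprintf("<deg> %d drugs, %d effects, %d edges\n",
              nrow(x$drugs), nrow(x$effects), nrow(x$edges)))
  if (nrow(x$edges)) {
    tab <- table(factor(x$edges$label, levels = edge_labels))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load a SIDER-style drug/side-effect relationship table into a DEG
#'
#' Each row records one drug-effect relationship; the resulting graph has one
#' node per distinct drug and effect id and one edge, labeled `"adverse"`, per
#' distinct (drug, effect) pair. Duplicate rows collapse silently (a message
#' reports the count).
#'
#' @param x A data frame, or the path of a UTF-8 TSV file with a header row,
#'   carrying columns `drug_id`, `drug_name`, `effect_id`, `effect_name`
#'   (a column-compatible subset of SIDER's MedDRA side-effect export).
#' @return A [deg] whose edges are all labeled `"adverse"`.
#' @export
load_sider <- function(x) {
  if (is_scalar_character(x)) {
    x <- utils::read.delim(x, colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("drug_id", "drug_name", "effect_id", "effect_name")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in need) x[[col]] <- as.character(x[[col]])
  bad <- which(is.na(x$drug_id) | !nzchar(x$drug_id) |
                 is.na(x$effect_id) | !nzchar(x$effect_id))
  if (length(bad)) {
    stop("row(s) with missing or empty id: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L),
         call. = FALSE)
  }
  key <- pair_key(x$drug_id, x$effect_id)
  dup <- duplicated(key)
  if (any(dup)) {
    message("collapsed ", sum(dup), " duplicate relationship row(s)")
    x <- x[!dup, , drop = FALSE]
  }
  drugs <- x[!duplicated(x$drug_id), c("drug_id", "drug_name")]
  names(drugs) <- c("id", "name")
  effects <- x[!duplicated(x$effect_id), c("effect_id", "effect_name")]
  names(effects) <- c("id", "name")
  edges <- data.frame(drug_id = x$drug_id, effect_id = x$effect_id,
                      label = rep("adverse", nrow(x)), stringsAsFactors = FALSE)
  deg(drugs = drugs, effects = effects, edges = edges)
}

# Adjacency list keyed by tagged node id ("drug:<id>" / "effect:<id>");
# isolated nodes map to character(0).
deg_adjacency <- function(x) {
  all_ids <- c(tag_drug(x$drugs$id), tag_effect(x$effects$id))
  adj <- stats::setNames(vector("list", length(all_ids)), all_ids)
  for (i in seq_along(adj)) adj[[i]] <- character(0)
  if (nrow(x$edges)) {
    d <- tag_drug(x$edges$drug_id)
    e <- tag_effect(x$edges$effect_id)
    by_d <- split(e, d)
    by_e <- split(d, e)
    adj[names(by_d)] <- by_d
    adj[names(by_e)] <- by_e
  }
  adj
}

# Pharmacological neighborhood: nodes within two hops of `tagged`, excluding
# `tagged` itself.
gamma_set <- function(adj, tagged) {
  n1 <- adj[[tagged]]
  if (!length(n1)) return(character(0))
  setdiff(unique(c(n1, unlist(adj[n1], use.names = FALSE))), tagged)
}

resolve_node <- function(x, node_id, node_class = NULL) {
  is_drug <- node_id %in% x$drugs$id
  is_effect <- node_id %in% x$effects$id
  if (!is.null(node_class)) {
    node_class <- match.arg(node_class, c("drug", "effect"))
    ok <- if (node_class == "drug") is_drug else is_effect
    if (!ok) stop("unknown ", node_class, " node id: ", node_id, call. = FALSE)
    return(if (node_class == "drug") tag_drug(node_id) else tag_effect(node_id))
  }
  if (is_drug && is_effect) {
    stop("node id `", node_id,
         "` exists as both a drug and an effect; supply `node_class`",
         call. = FALSE)
  }
  if (is_drug) return(tag_drug(node_id))
  if (is_effect) return(tag_effect(node_id))
  stop("unknown node id: ", node_id, call. = FALSE)
}

#' Pharmacological neighborhood of a node
#'
#' Returns every node reachable within two hops of `node_id`, excluding the
#' node itself. For a drug the result mixes effects (distance 1) and drugs
#' sharing an effect (distance 2); symmetrically for an effect.
#'
#' @param x A [deg].
#' @param node_id Node id present in `x`.
#' @param node_class `"drug"` or `"effect"`; required only when the same id
#'   string exists in both partite sets.
#' @return Character vector of tagged node ids of the form `"drug:<id>"` /
#'   `"effect:<id>"`, sorted.
#' @export
neighborhood <- function(x, node_id, node_class = NULL) {
  stopifnot(inherits(x, "deg"), is_scalar_character(node_id))
  tagged <- resolve_node(x, node_id, node_class)
  sort(gamma_set(deg_adjacency(x), tagged))
}

#' Sample pseudo-non-adverse (negative) drug-effect pairs
#'
#' Draws `n` distinct (drug, effect) pairs uniformly without replacement from
#' the complement of the adverse edge set, i.e. pairs of existing nodes that
#' are not recorded as adverse. Sampling is rejection-free (index sampling
#' over the complement) and fully reproducible from `seed`.
#'
#' @param x A [deg].
#' @param n Number of pairs to draw.
#' @param seed Integer seed (required; restores the caller's RNG state).
#' @return Data frame with columns `drug_id`, `effect_id`.
#' @export
sample_pseudo_negatives <- function(x, n, seed) {
  stopifnot(inherits(x, "deg"))
  n <- as.integer(n)
  nd <- nrow(x$drugs)
  ne <- nrow(x$effects)
  total <- as.double(nd) * as.double(ne)
  adverse <- x$edges[x$edges$label == "adverse", , drop = FALSE]
  k <- nrow(adverse)
  avail <- total - k
  if (n > avail) {
    stop(sprintf("requested %d pseudo-negatives but only %.0f non-adverse pairs exist",
                 n, avail), call. = FALSE)
  }
  if (n == 0L) {
    return(data.frame(drug_id = character(), effect_id = character(),
                      stringsAsFactors = FALSE))
  }
  di <- match(adverse$drug_id, x$drugs$id)
  ei <- match(adverse$effect_id, x$effects$id)
  a <- sort((di - 1) * ne + ei)  # linear indices of adverse pairs
  r <- local_seed(seed, sample.int(avail, n))
  # shift sampled complement ranks past the adverse indices
  res <- r
  repeat {
    new <- r + findInterval(res, a)
    if (identical(new, res)) break
    res <- new
  }
  data.frame(
    drug_id = x$drugs$id[(res - 1) %/% ne + 1],
    effect_id = x$effects$id[(res - 1) %% ne + 1],
    stringsAsFactors = FALSE
  )
}

#' Balance a DEG with sampled pseudo-non-adverse edges
#'
#' Adds `n` pseudo-negative edges (label `"pseudo_non_adverse"`) sampled with
#' [sample_pseudo_negatives()]; by default as many as there are adverse edges,
#' yielding a class-balanced labeled edge set.
#'
#' @inheritParams sample_pseudo_negatives
#' @param n Number of negatives; defaults to the adverse edge count.
#' @return A [deg] with the negative edges appended.
#' @export
add_pseudo_negatives <- function(x, n = NULL, seed) {
  n <- n %||% sum(x$edges$label == "adverse")
  neg <- sample_pseudo_negatives(x, n, seed)
  if (!nrow(neg)) return(x)
  neg$label <- "pseudo_non_adverse"
  neg$temporal_weight <- NA_real_
  neg$frequency_weight <- NA_real_
  x$edges <- rbind(x$edges, neg[, names(x$edges)])
  rownames(x$edges) <- NULL
  validate_deg(x)
}

#' Merge per-user DEGs into one graph
#'
#' Takes the union of nodes and edges. For an edge present in `c` member
#' graphs the merged `temporal_weight` is the arithmetic mean of the member
#' weights and `frequency_weight = c` (the number of users whose histories
#' contain the pair).
#'
#' @param user_degs List of [deg] objects, each with `temporal_weight` set on
#'   every edge.
#' @return A merged [deg] with `"unlabeled"` edges.
#' @export
merge_degs <- function(user_degs) {
  stopifnot(is.list(user_degs))
  if (!length(user_degs)) return(deg())
  for (g in user_degs) {
    stopifnot(inherits(g, "deg"))
    if (anyNA(g$edges$temporal_weight)) {
      stop("every member edge must carry a temporal_weight", call. = FALSE)
    }
  }
  drugs <- do.call(rbind, lapply(user_degs, `[[`, "drugs"))
  effects <- do.call(rbind, lapply(user_degs, `[[`, "effects"))
  drugs <- drugs[!duplicated(drugs$id), , drop = FALSE]
  effects <- effects[!duplicated(effects$id), , drop = FALSE]
  all_edges <- do.call(rbind, lapply(user_degs, `[[`, "edges"))
  if (is.null(all_edges) || !nrow(all_edges)) {
    return(deg(drugs = drugs, effects = effects))
  }
  key <- pair_key(all_edges$drug_id, all_edges$effect_id)
  w <- tapply(all_edges$temporal_weight, key, mean)
  cnt <- tapply(rep(1L, nrow(all_edges)), key, sum)
  first <- !duplicated(key)
  edges <- data.frame(
    drug_id = all_edges$drug_id[first],
    effect_id = all_edges$effect_id[first],
    label = "unlabeled",
    stringsAsFactors = FALSE
  )
  k <- pair_key(edges$drug_id, edges$effect_id)
  edges$temporal_weight <- as.numeric(w[k])
  edges$frequency_weight <- as.numeric(cnt[k])
  deg(drugs = drugs, effects = effects, edges = edges)
}

#' Label edges against a reference (SIDER) DEG
#'
#' Marks each edge `"adverse"` if the (drug, effect) pair is an adverse edge
#' of `reference`, else `"pseudo_non_adverse"`.
#'
#' @param x A [deg] to relabel.
#' @param reference A [deg] whose adverse edges define the positive class.
#' @return `x` with updated edge labels.
#' @export
label_edges <- function(x, reference) {
  stopifnot(inherits(x, "deg"), inherits(reference, "deg"))
  ref <- reference$edges
  ref_keys <- pair_key(ref$drug_id[ref$label == "adverse"],
                       ref$effect_id[ref$label == "adverse"])
  keys <- pair_key(x$edges$drug_id, x$edges$effect_id)
  x$edges$label <- ifelse(keys %in% ref_keys, "adverse", "pseudo_non_adverse")
  x
}

fmt_num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))

#' Write / read a DEG edge-list file
#'
#' The file is a TSV whose data table has exactly the columns `drug_id`,
#' `effect_id`, `label`, `temporal_weight`, `frequency_weight`. Node records
#' (including isolated nodes and display names) are carried as leading
#' `#`-prefixed metadata lines, so `read_deg(write_deg(x, p))` is the identity
#' on nodes, edges, labels and weights; weights round-trip at full precision
#' and missing weights serialize as empty fields.
#'
#' @param x A [deg].
#' @param path File path.
#' @return `write_deg` returns `path` invisibly; `read_deg` returns a [deg].
#' @export
write_deg <- function(x, path) {
  stopifnot(inherits(x, "deg"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("## degmine drug-effect graph v1", con)
  if (nrow(x$drugs)) {
    writeLines(paste("# drug", x$drugs$id, x$drugs$name, sep = "\t"), con)
  }
  if (nrow(x$effects)) {
    writeLines(paste("# effect", x$effects$id, x$effects$name, sep = "\t"), con)
  }
  writeLines(paste("drug_id", "effect_id", "label", "temporal_weight",
                   "frequency_weight", sep = "\t"), con)
  if (nrow(x$edges)) {
    writeLines(paste(x$edges$drug_id, x$edges$effect_id, x$edges$label,
                     fmt_num(x$edges$temporal_weight),
                     fmt_num(x$edges$frequency_weight), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_deg
#' @export
read_deg <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- startsWith(lines, "#")
  meta <- lines[is_meta]
  body <- lines[!is_meta]
  node_lines <- meta[startsWith(meta, "# ")]
  parse_nodes <- function(cls) {
    sel <- node_lines[startsWith(node_lines, paste0("# ", cls, "\t"))]
    if (!length(sel)) {
      return(data.frame(id = character(), name = character(),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(sel, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad)) {
      stop("malformed node line ", which(is_meta)[match(sel[bad[1]], meta)],
           " in ", path, call. = FALSE)
    }
    data.frame(id = vapply(parts, `[[`, "", 2L),
               name = vapply(parts, `[[`, "", 3L), stringsAsFactors = FALSE)
  }
  drugs <- parse_nodes("drug")
  effects <- parse_nodes("effect")
  if (!length(body)) stop("missing header line in ", path, call. = FALSE)
  header <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
  expected <- c("drug_id", "effect_id", "label", "temporal_weight", "frequency_weight")
  if (!identical(header, expected)) {
    stop("unexpected header in ", path, call. = FALSE)
  }
  rows <- body[-1L]
  edges <- NULL
  if (length(rows)) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    # trailing empty fields are dropped by strsplit; pad to 5
    nfield <- lengths(parts)
    if (any(nfield > 5L | nfield < 2L)) {
      bad_line <- which(nfield > 5L | nfield < 2L)[1L]
      stop("malformed line ", which(!is_meta)[bad_line + 1L], " in ", path,
           call. = FALSE)
    }
    parts <- lapply(parts, function(p) c(p, rep("", 5L - length(p))))
    m <- do.call(rbind, parts)
    edges <- data.frame(
      drug_id = m[, 1L], effect_id = m[, 2L],
      label = ifelse(nzchar(m[, 3L]), m[, 3L], "unlabeled"),
      temporal_weight = suppressWarnings(
        ifelse(nzchar(m[, 4L]), as.numeric(m[, 4L]), NA_real_)),
      frequency_weight = suppressWarnings(
        ifelse(nzchar(m[, 5L]), as.numeric(m[, 5L]), NA_real_)),
      stringsAsFactors = FALSE
    )
  }
  deg(drugs = drugs, effects = effects, edges = edges)
}
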