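test_that("load_sider builds one adverse edge per distinct pair", {
  empty <- load_sider(data.frame(drug_id = character(), drug_name = character(),
                                 effect_id = character(), effect_name = character()))
  expect_equal(nrow(empty$drugs) + nrow(empty$effects), 0L)
  expect_equal(nrow(empty$edges), 0L)

  rows <- data.frame(
    drug_id = c("d1", "d1", "d2"), drug_name = c("Alpha", "Alpha", "Beta"),
    effect_id = c("e1", "e1", "e1"), effect_name = "Nausea",
    stringsAsFactors = FALSE)
  expect_message(g <- load_sider(rows), "1 duplicate")
  expect_equal(nrow(g$edges), 2L)
  expect_true(all(g$edges$label == "adverse"))
  expect_setequal(g$drugs$id, c("d1", "d2"))
})

test_that("load_sider rejects rows with missing ids, naming the row", {
  rows <- data.frame(drug_id = c("d1", ""), drug_name = "x",
                     effect_id = c("e1", "e2"), effect_name = "y",
                     stringsAsFactors = FALSE)
  expect_error(load_sider(rows), "row\\(s\\) with missing or empty id: 2")
})

test_that("deg enforces bipartite invariants", {
  expect_error(deg(drugs = c("d1", "d1"), effects = "e1"), "duplicate drugs ids")
  expect_error(
    deg(drugs = "d1", effects = "e1",
        edges = data.frame(drug_id = "d9", effect_id = "e1")),
    "unknown drug id")
  expect_error(
    deg(drugs = "d1", effects = "e1",
        edges = data.frame(drug_id = c("d1", "d1"), effect_id = c("e1", "e1"))),
    "duplicate")
  expect_error(
    deg(drugs = "d1", effects = "e1",
        edges = data.frame(drug_id = "d1", effect_id = "e1",
                           temporal_weight = -1)),
    "temporal_weight")
  # the same string may serve as a drug id and an effect id (disjoint namespaces)
  g <- deg(drugs = "x", effects = "x",
           edges = data.frame(drug_id = "x", effect_id = "x"))
  expect_equal(nrow(g$edges), 1L)
  expect_setequal(neighborhood(g, "x", node_class = "drug"), "effect:x")
})

test_that("neighborhood returns all nodes within two hops, excluding self", {
  iso <- deg(drugs = "d1", effects = "e1")
  expect_length(neighborhood(iso, "d1"), 0L)

  single <- deg(drugs = "d", effects = "e",
                edges = data.frame(drug_id = "d", effect_id = "e"))
  expect_equal(neighborhood(single, "d"), "effect:e")
  expect_equal(neighborhood(single, "e"), "drug:d")

  t1 <- toy_t1()
  expect_setequal(neighborhood(t1, "d1"),
                  c("effect:e1", "effect:e2", "drug:d2"))
  expect_error(neighborhood(t1, "nope"), "unknown node id: nope")
})

test_that("neighborhood agrees with brute-force depth-2 BFS on random graphs", {
  set.seed(42)
  for (i in 1:150) {
    g <- random_deg()
    el <- deg_edge_list(g)
    node <- if (runif(1) < 0.5) {
      list(id = sample(g$drugs$id, 1L), cls = "drug")
    } else {
      list(id = sample(g$effects$id, 1L), cls = "effect")
    }
    expect_setequal(neighborhood(g, node$id, node_class = node$cls),
                    brute_gamma(el, paste0(node$cls, ":", node$id)))
  }
})

test_that("pseudo-negative sampling is uniform over the complement and seeded", {
  g <- deg(drugs = c("a", "b"), effects = c("x", "y"),
           edges = data.frame(drug_id = c("a", "a", "b"),
                              effect_id = c("x", "y", "x"),
                              label = "adverse"))
  expect_equal(nrow(sample_pseudo_negatives(g, 0, seed = 1)), 0L)
  one <- sample_pseudo_negatives(g, 1, seed = 7)
  expect_equal(one, data.frame(drug_id = "b", effect_id = "y",
                               stringsAsFactors = FALSE))
  expect_error(sample_pseudo_negatives(g, 2, seed = 1), "2.*1 non-adverse")
})

test_that("sampling the full complement returns exactly the complement", {
  set.seed(9)
  for (i in 1:25) {
    g <- random_deg(6L, 8L)
    n_comp <- nrow(g$drugs) * nrow(g$effects) - nrow(g$edges)
    neg <- sample_pseudo_negatives(g, n_comp, seed = i)
    expect_equal(nrow(neg), n_comp)
    neg_keys <- paste(neg$drug_id, neg$effect_id)
    edge_keys <- paste(g$edges$drug_id, g$edges$effect_id)
    expect_length(intersect(neg_keys, edge_keys), 0L)
    expect_equal(anyDuplicated(neg_keys), 0L)
    expect_identical(sample_pseudo_negatives(g, min(3L, n_comp), seed = 11),
                     sample_pseudo_negatives(g, min(3L, n_comp), seed = 11))
  }
})

test_that("merge_degs averages temporal weights and counts contributing graphs", {
  mk <- function(w) {
    deg(drugs = "d", effects = "e",
        edges = data.frame(drug_id = "d", effect_id = "e",
                           temporal_weight = w))
  }
  expect_equal(nrow(merge_degs(list())$edges), 0L)

  one <- merge_degs(list(mk(5)))
  expect_equal(one$edges$frequency_weight, 1)
  expect_equal(one$edges$temporal_weight, 5)

  two <- merge_degs(list(mk(2), mk(4)))
  expect_equal(two$edges$temporal_weight, 3)
  expect_equal(two$edges$frequency_weight, 2)

  expect_error(merge_degs(list(deg(drugs = "d", effects = "e",
                                   edges = data.frame(drug_id = "d",
                                                      effect_id = "e")))),
               "temporal_weight")
})

test_that("merge frequency equals membership count on random user graphs", {
  set.seed(31)
  for (trial in 1:20) {
    members <- lapply(1:4, function(i) {
      g <- random_deg(4L, 5L)
      g$edges$temporal_weight <- round(runif(nrow(g$edges), 0, 20), 3)
      g
    })
    merged <- merge_degs(members)
    for (r in seq_len(nrow(merged$edges))) {
      key_d <- merged$edges$drug_id[r]
      key_e <- merged$edges$effect_id[r]
      w <- unlist(lapply(members, function(m) {
        m$edges$temporal_weight[m$edges$drug_id == key_d &
                                  m$edges$effect_id == key_e]
      }))
      expect_equal(merged$edges$frequency_weight[r], length(w))
      expect_equal(merged$edges$temporal_weight[r], mean(w), tolerance = 1e-9)
    }
  }
})

test_that("write_deg / read_deg round-trips nodes, edges, labels and weights", {
  path <- withr::local_tempfile(fileext = ".tsv")

  empty <- deg()
  write_deg(empty, path)
  expect_equal(read_deg(path), empty)

  g <- toy_t1()
  g$edges$label <- c("adverse", "pseudo_non_adverse", "adverse", "unlabeled")
  g$edges$temporal_weight <- c(2, NA, 1 / 3, 17.123456789012345)
  g$edges$frequency_weight <- c(1, NA, 2, 7)
  g$drugs$name <- c("Drug One", "Drug Two")
  write_deg(g, path)
  expect_equal(read_deg(path), g)

  # isolated nodes survive the round trip
  iso <- deg(drugs = c("d1", "d2"), effects = "e1",
             edges = data.frame(drug_id = "d1", effect_id = "e1"))
  write_deg(iso, path)
  expect_equal(read_deg(path), iso)
})

test_that("read_deg reports malformed lines by number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("drug_id\teffect_id\tlabel\ttemporal_weight\tfrequency_weight",
               "d1"), path)
  expect_error(read_deg(path), "malformed line 2")
})
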