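toy_annotations <- function() {
  rbind(
    data.frame(gene = c("A", "B", "C"), uniprot = "X", facet = "cellular_component",
               term = "cytoplasm", stringsAsFactors = FALSE),
    data.frame(gene = "D", uniprot = "X", facet = "cellular_component",
               term = "mitochondrion", stringsAsFactors = FALSE))
}

test_that("facet proportions are percentages of annotated proteins", {
  out <- facet_proportions(toy_annotations(), "cellular_component")
  expect_equal(out$percent[out$term == "cytoplasm"], 75)
  expect_equal(out$percent[out$term == "mitochondrion"], 25)
  # single-label facet sums to 100
  expect_equal(sum(out$percent), 100)
})

test_that("empty facets yield empty tables and unknown facets error", {
  out <- facet_proportions(toy_annotations(), "biological_process")
  expect_equal(nrow(out), 0)
  expect_error(facet_proportions(toy_annotations(), "pathway"), "unknown facet")
  expect_error(facet_proportions(toy_annotations()[0, ], "protein_class"), "empty")
})

test_that("multi-label proteins count once per term", {
  ann <- rbind(toy_annotations(),
               data.frame(gene = c("A", "A"), uniprot = "X",
                          facet = "molecular_function",
                          term = c("catalytic_activity", "oxidoreductase_activity"),
                          stringsAsFactors = FALSE),
               data.frame(gene = "B", uniprot = "X", facet = "molecular_function",
                          term = "catalytic_activity", stringsAsFactors = FALSE))
  out <- facet_proportions(ann, "molecular_function")
  expect_equal(out$percent[out$term == "catalytic_activity"], 100)
  expect_equal(out$percent[out$term == "oxidoreductase_activity"], 50)
  expect_gt(sum(out$percent), 100)
})

test_that("packaged synthetic annotation fixture reproduces its encoded aggregates", {
  # the fixture is constructed to the published aggregate percentages, so
  # this documents the encoding rather than validating external databases
  ann <- read_annotations()
  cc <- facet_proportions(ann, "cellular_component")
  expect_lt(abs(cc$percent[cc$term == "mitochondrion"] - 28.6), 1)
  expect_lt(abs(cc$percent[cc$term == "cytoplasm"] - 57.1), 1)
  mf <- facet_proportions(ann, "molecular_function")
  expect_lt(abs(mf$percent[mf$term == "catalytic_activity"] - 75.0), 1)
  expect_lt(abs(mf$percent[mf$term == "oxidoreductase_activity"] - 45), 1)
  expect_lt(abs(mf$percent[mf$term == "transferase_activity"] - 25), 1)
  expect_lt(abs(mf$percent[mf$term == "hydrolase_activity"] - 10), 1)
  expect_lt(abs(mf$percent[mf$term == "ligase_activity"] - 7.5), 1)
  bp <- facet_proportions(ann, "biological_process")
  expect_lt(abs(bp$percent[bp$term == "metabolic_process"] - 46.0), 1)
  expect_lt(abs(bp$percent[bp$term == "cellular_amino_acid_metabolic_process"] - 36.4), 1)
  expect_lt(abs(bp$percent[bp$term == "lipid_metabolic_process"] - 21.2), 1)
  expect_lt(abs(bp$percent[bp$term == "carbohydrate_metabolic_process"] - 18.2), 1)
})

triangle <- function(scores = c(0.9, 0.9, 0.9)) {
  data.frame(protein_a = c("a", "b", "c"), protein_b = c("b", "c", "a"),
             evidence = "physical", score = scores, stringsAsFactors = FALSE)
}

test_that("network summary filters by confidence and drops isolated nodes", {
  s <- network_summary(triangle(), min_confidence = 0.4)
  expect_equal(s$n_nodes, 3)
  expect_equal(s$n_edges, 3)
  expect_true(all(s$degree == 2))
  expect_equal(s$components$count, 1)
  # one sub-threshold edge: still three connected nodes, two edges
  s2 <- network_summary(triangle(c(0.9, 0.9, 0.2)), min_confidence = 0.4)
  expect_equal(s2$n_nodes, 3)
  expect_equal(s2$n_edges, 2)
  # empty network
  s0 <- network_summary(triangle()[0, ])
  expect_equal(c(s0$n_nodes, s0$n_edges), c(0L, 0L))
})

test_that("threshold zero is the identity on the edge set", {
  edges <- read_interactions()
  s <- network_summary(edges, min_confidence = 0)
  expect_equal(s$n_edges, nrow(edges))
  expect_equal(s$n_nodes, length(unique(c(edges$protein_a, edges$protein_b))))
})

test_that("filtered counts match a brute-force filter on random graphs", {
  set.seed(63)
  for (i in 1:10) {
    nodes <- paste0("p", 1:8)
    all_pairs <- t(combn(nodes, 2))
    pick <- sample(nrow(all_pairs), 12)
    edges <- data.frame(protein_a = all_pairs[pick, 1],
                        protein_b = all_pairs[pick, 2],
                        evidence = "functional",
                        score = round(runif(12), 3), stringsAsFactors = FALSE)
    thr <- runif(1)
    s <- network_summary(edges, min_confidence = thr)
    keep <- edges$score >= thr
    expect_equal(s$n_edges, sum(keep))
    expect_equal(s$n_nodes,
                 length(unique(c(edges$protein_a[keep], edges$protein_b[keep]))))
    expect_equal(sum(s$degree), 2 * s$n_edges)  # handshake identity
  }
})

test_that("the packaged synthetic network matches its encoded medium-confidence summary", {
  s <- network_summary(read_interactions(), min_confidence = 0.4)
  expect_equal(s$n_nodes, 23)
  expect_equal(s$n_edges, 52)
})

test_that("malformed edge lists are rejected", {
  bad_loop <- data.frame(protein_a = "a", protein_b = "a", evidence = "physical",
                         score = 0.5, stringsAsFactors = FALSE)
  expect_error(network_summary(bad_loop), "self-loops")
  dup <- rbind(triangle(), data.frame(protein_a = "b", protein_b = "a",
                                      evidence = "physical", score = 0.7))
  expect_error(network_summary(dup), "duplicate")
  bad_score <- triangle(c(0.5, 1.2, 0.5))
  expect_error(network_summary(bad_score), "\\[0, 1\\]")
})
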