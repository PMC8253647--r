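toy_network <- function() {
  # one compound in one herb with two targets -> 3 edges, compound degree 3
  records <- make_compound_df("MOLT1", 50, 0.5, "HerbA")
  build_multinetwork(records, list(MOLT1 = c("TP53", "IL6")),
                     c("TP53", "IL6"))
}

test_that("tripartite construction wires herb and target edges only", {
  net <- toy_network()
  expect_equal(igraph::ecount(net), 3L)
  expect_equal(unname(igraph::degree(net)["MOLT1"]), 3)
  parts <- setNames(igraph::V(net)$partition, igraph::V(net)$name)
  expect_equal(unname(parts[c("HerbA", "MOLT1", "TP53")]),
               c("herb", "compound", "gene"))

  # empty target map degenerates to the herb-compound bipartite graph
  bip <- build_multinetwork(make_compound_df("MOLT1", 50, 0.5, "HerbA"),
                            list(), character(0))
  expect_equal(igraph::ecount(bip), 1L)
  expect_true(igraph::V(bip)$isolated[igraph::V(bip)$name == "MOLT1"] == FALSE)
})

test_that("node label collisions across partitions are rejected", {
  records <- make_compound_df("TP53", 50, 0.5, "HerbA") # compound named as a gene
  expect_error(build_multinetwork(records, list(TP53 = "TP53"), "TP53"),
               "collide")
})

test_that("degree report gives exact degrees and means", {
  path <- igraph::make_graph(~ a - b, b - c)
  rep <- degree_report(path)
  expect_setequal(rep$degree, c(1L, 2L, 1L))
  expect_equal(attr(rep, "network_mean"), 4 / 3)
  expect_error(degree_report(igraph::make_empty_graph(0)), "empty")
})

test_that("key-node selection uses strict above-mean and deterministic tie-breaks", {
  g <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("a", "c"), c("a", "d"), c("a", "e"), c("a", "f"),
          c("b", "c"), c("b", "d")), directed = FALSE)
  # degrees: a 5, b 3, c 2, d 2, e 1, f 1; mean = 14/6
  rep <- degree_report(g)
  expect_equal(select_key_nodes(rep, rule = "above_mean")$node, c("a", "b"))

  tie <- degree_report(igraph::graph_from_edgelist(
    rbind(c("b", "x"), c("b", "y"), c("a", "x"), c("a", "y"), c("c", "x")),
    directed = FALSE))
  top <- select_key_nodes(tie, rule = "top_k", k = 2)
  expect_equal(top$node, c("x", "a")) # x deg 3; a/b tie at 2 -> label order
  expect_warning(all_of_them <- select_key_nodes(tie, rule = "top_k", k = 99),
                 "exceeds")
  expect_equal(nrow(all_of_them), 5L)
})

test_that("strict inequality at the mean excludes boundary nodes", {
  # degrees {a:5, b:3, c:1} on a multigraph-free star-ish graph is awkward;
  # assert via a direct report: mean 3 must not select b
  g <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("a", "c"), c("a", "x1"), c("a", "x2"), c("a", "x3"),
          c("b", "x1"), c("b", "x2")), directed = FALSE)
  rep <- degree_report(g)
  sel <- select_key_nodes(rep, rule = "above_mean")
  expect_true(all(sel$degree > attr(rep, "network_mean")))
  expect_false(any(sel$degree == attr(rep, "network_mean")))
})

test_that("handshake lemma, partition purity and degree decomposition hold", {
  for (seed in c(3, 17, 42)) {
    cfg <- sim_config(seed = seed, n_herbs = 6L, n_compounds_per_herb = 25L)
    comp <- gen_compound_table(cfg)
    dd <- dedupe_compounds(screen_compounds(comp$records))
    tm <- gen_target_map(cfg, dd$unique$mol_id, comp$truth$hub_mol_ids)
    genes <- sample(tm$universe, 60)
    net <- build_multinetwork(dd$unique, tm$target_map, genes)

    expect_equal(sum(igraph::degree(net)), 2L * igraph::ecount(net))

    el <- igraph::as_edgelist(net)
    part <- setNames(igraph::V(net)$partition, igraph::V(net)$name)
    pairs <- paste(pmin(part[el[, 1]], part[el[, 2]]),
                   pmax(part[el[, 1]], part[el[, 2]]))
    expect_true(all(pairs %in% c("compound herb", "compound gene")))

    deg <- igraph::degree(net)
    for (m in dd$unique$mol_id) {
      expected <- dd$unique$n_herbs[dd$unique$mol_id == m] +
        length(intersect(tm$target_map[[m]], toupper(genes)))
      expect_equal(unname(deg[[m]]), expected)
    }
  }
})

test_that("top-5 compounds recover the planted hubs", {
  cfg <- sim_config(seed = 23)
  comp <- gen_compound_table(cfg)
  dd <- dedupe_compounds(screen_compounds(comp$records))
  tm <- gen_target_map(cfg, dd$unique$mol_id, comp$truth$hub_mol_ids)
  dis <- gen_disease_genes(cfg, tm$target_map)
  common <- intersect_with_targets(
    dis$disease, gene_set(unlist(tm$target_map, use.names = FALSE)))
  net <- build_multinetwork(dd$unique, tm$target_map, common)
  top5 <- select_key_nodes(degree_report(net), "compound", "top_k", k = 5)$node
  expect_gte(length(intersect(top5, comp$truth$hub_mol_ids)), 4L)
})

test_that("network exports carry the partition attribute", {
  net <- toy_network()
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$partition, c("herb", "compound", "gene"))

  sif <- withr::local_tempfile(fileext = ".sif")
  write_network_sif(net, sif)
  lines <- readLines(sif)
  expect_length(lines, 3L)
  expect_true(any(grepl("compound-gene|gene-compound", lines)))
})
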