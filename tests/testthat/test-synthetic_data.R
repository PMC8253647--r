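test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(duplicate_rate = 1.2), "probabilities")
  expect_error(sim_config(hub_targets = c(10, 20), hub_herb_counts = 3L), "equal length")
  expect_error(sim_config(hub_targets = rep(500L, 5)), "universe")
  expect_error(sim_config(planted_enrichment = list(index = 500L, boost = 2L)),
               "index")
  expect_error(sim_config(pathway_size_range = c(10L, 5L)), "size range")
})

test_that("same seed gives byte-identical outputs; different seeds differ", {
  cfg4 <- function(seed) sim_config(seed = seed, n_herbs = 4L,
                                    n_compounds_per_herb = 30L,
                                    hub_herb_counts = c(2L, 3L, 1L, 2L, 2L))
  a <- gen_compound_table(cfg4(42))
  b <- gen_compound_table(cfg4(42))
  expect_identical(a, b)
  c <- gen_compound_table(cfg4(43))
  expect_false(identical(a$records, c$records))

  cfg <- sim_config(seed = 7, n_herbs = 4L, n_compounds_per_herb = 25L,
                    hub_herb_counts = c(2L, 3L, 1L, 2L, 2L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_all(cfg, outdir = d1)
  simulate_all(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("compound generator plants duplicates and screen-pass fraction as configured", {
  no_dup <- gen_compound_table(sim_config(seed = 2, duplicate_rate = 0,
                                          n_herbs = 4L, n_compounds_per_herb = 40L,
                                          hub_herb_counts = rep(1L, 5)))
  expect_equal(dedupe_compounds(no_dup$records)$n_removed, 0L)
  expect_equal(no_dup$truth$n_duplicate_listings, 0L)

  all_act <- gen_compound_table(sim_config(seed = 3, bioactive_fraction = 1,
                                           n_herbs = 3L, n_compounds_per_herb = 30L,
                                           hub_herb_counts = c(1L, 2L, 1L, 2L, 1L)))
  expect_equal(nrow(screen_compounds(all_act$records)),
               nrow(all_act$records))

  # 8 herbs x 125 listings, no duplication -> 1000 unique compounds
  cfg <- sim_config(seed = 4, n_herbs = 8L, n_compounds_per_herb = 125L,
                    duplicate_rate = 0, bioactive_fraction = 0.15,
                    hub_herb_counts = rep(1L, 5))
  comp <- gen_compound_table(cfg)
  n <- comp$truth$n_unique
  expect_equal(n, 1000L)
  frac <- length(unique(screen_compounds(comp$records)$mol_id)) / n
  se <- sqrt(0.15 * 0.85 / n)
  expect_lt(abs(frac - 0.15), 3 * se + 5 / n) # +5/n: hubs forced active
})

test_that("target map plants exact hub counts and a sane background", {
  cfg <- sim_config(seed = 9)
  mols <- sprintf("MOLS%05d", 1:200)
  hubs <- mols[1:5]
  tm <- gen_target_map(cfg, mols, hubs)
  expect_identical(unname(tm$truth$hub_target_counts), cfg$hub_targets)
  expect_identical(unname(lengths(tm$target_map[hubs])), cfg$hub_targets)
  expect_true(all(lengths(tm$target_map) >= 0L))
  expect_true(all(unlist(tm$target_map) %in% tm$universe))

  # background mean within 3 SE of the configured negative-binomial mean
  bg <- lengths(tm$target_map[setdiff(mols, hubs)])
  se <- sqrt(cfg$bg_target_mu * (1 + cfg$bg_target_mu / cfg$bg_target_size) /
               length(bg))
  expect_lt(abs(mean(bg) - cfg$bg_target_mu), 3 * se)
})

test_that("disease-gene overlap is constructed exactly", {
  cfg <- sim_config(seed = 6)
  tm <- gen_target_map(cfg, sprintf("M%03d", 1:150),
                       sprintf("M%03d", 1:5))
  drug_union <- unique(unlist(tm$target_map))

  dis <- gen_disease_genes(cfg, tm$target_map)
  expect_equal(dis$truth$n_overlap, round(cfg$overlap_fraction * cfg$n_disease_genes))
  expect_equal(length(intersect(dis$disease$genes, drug_union)),
               dis$truth$n_overlap)
  expect_equal(length(dis$disease), cfg$n_disease_genes)
  # the source lists union back to the disease set
  expect_setequal(union_gene_sources(dis$sources)$genes, dis$disease$genes)

  disjoint <- gen_disease_genes(sim_config(seed = 6, overlap_fraction = 0),
                                tm$target_map)
  expect_length(intersect(disjoint$disease$genes, drug_union), 0L)

  subset_cfg <- sim_config(seed = 6, overlap_fraction = 1, n_disease_genes = 50L)
  subs <- gen_disease_genes(subset_cfg, tm$target_map)
  expect_true(all(subs$disease$genes %in% drug_union))
})

test_that("PPI generator wires planted hubs and leaves isolated genes out", {
  genes <- sprintf("GENE%04d", 1:40)
  empty <- gen_ppi(sim_config(seed = 5, ppi_density = 0, n_ppi_hubs = 0L,
                              n_ppi_isolated = 0L), genes)
  expect_equal(nrow(empty$edges), 0L)

  cfg <- sim_config(seed = 5)
  sim <- gen_ppi(cfg, genes)
  expect_length(sim$truth$hub_genes, cfg$n_ppi_hubs)
  expect_length(sim$truth$isolated_genes, cfg$n_ppi_isolated)
  expect_false(any(sim$truth$isolated_genes %in%
                     c(sim$edges$gene_a, sim$edges$gene_b)))
  expect_equal(sum(sim$edges$score > 0.9), sim$truth$n_edges_passing)

  # a planted hub touches every non-isolated gene
  deg <- table(c(sim$edges$gene_a, sim$edges$gene_b))
  wired <- length(genes) - cfg$n_ppi_isolated
  expect_true(all(deg[sim$truth$hub_genes] == wired - 1L))
})

test_that("GMT generator plants the boost exactly and respects the size range", {
  cfg <- sim_config(seed = 13)
  universe <- sprintf("GENE%04d", 1:269)
  set.seed(1); query <- sample(universe, 48)
  g <- gen_gmt(cfg, universe, query)
  sizes <- lengths(lapply(g$collection, `[[`, "genes"))
  expect_true(all(sizes >= cfg$pathway_size_range[1L] &
                    sizes <= cfg$pathway_size_range[2L]))
  planted <- g$collection[[cfg$planted_enrichment$index]]
  k <- length(intersect(planted$genes, toupper(query)))
  expect_equal(k, g$truth$planted_k)
  expect_equal(k, min(length(query), length(planted$genes),
                      round(g$truth$null_expectation) + cfg$planted_enrichment$boost))

  flat <- gen_gmt(sim_config(seed = 13,
                             planted_enrichment = list(index = 1L, boost = 0L)),
                  universe, query)
  expect_equal(flat$truth$planted_k, round(flat$truth$null_expectation))
})

test_that("simulate_all writes every format plus a truth log that reloads", {
  cfg <- sim_config(seed = 3, n_herbs = 5L, n_compounds_per_herb = 30L)
  outdir <- withr::local_tempdir()
  sim <- simulate_all(cfg, outdir = outdir)
  expect_setequal(list.files(outdir),
                  c("compounds.tsv", "targets.tsv", "disease_db1.txt",
                    "disease_db2.txt", "disease_db3.txt", "ppi.tsv",
                    "pathways.gmt", "truth.json"))
  records <- read_compound_table(file.path(outdir, "compounds.tsv"))
  expect_equal(nrow(records), nrow(sim$records))
  truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$compounds$n_unique, sim$truth$compounds$n_unique)
  expect_equal(truth$gmt$planted_pathway, sim$truth$gmt$planted_pathway)
})
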