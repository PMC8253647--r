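#' Configuration for the synthetic-data generators
#'
#' The generators emulate the statistical shape of the database snapshots a
#' network-pharmacology run consumes — a TCMSP-style herb-compound table
#' with OB/DL attributes, a compound-to-target map with a heavy-tailed
#' degree distribution and planted hub compounds, disease-gene source lists
#' with a constructed drug-target overlap, a STRING-style scored PPI edge
#' table with planted hub proteins, and a KEGG-style GMT collection with one
#' planted enriched pathway. Defaults reproduce the scale of a nine-herb
#' formula study: ~1180 herb-level compound listings of which ~14.5% pass
#' the OB/DL screen, a 269-gene target universe, 255 disease genes of which
#' exactly `round(overlap_fraction * n_disease_genes)` overlap the drug
#' targets.
#'
#' A single integer `seed` governs every generator through a fixed
#' splitting scheme (sub-seed = `(seed * 101 + stage offset) mod 2^31 - 1`),
#' so the full fixture suite is reproducible from one number.
#'
#' @param seed integer master seed.
#' @param n_herbs number of herbs (default 9).
#' @param n_compounds_per_herb herb-level listing count per herb (default
#'   131, giving ~1180 listings in total).
#' @param duplicate_rate probability that a listing reuses a compound
#'   already created under another herb (default 0.105).
#' @param bioactive_fraction expected fraction of compounds passing the
#'   OB >= 30 / DL >= 0.18 screen (default 0.145).
#' @param ob_active,dl_active ranges (length-2) OB and DL are drawn from for
#'   passing compounds.
#' @param n_targets_universe size of the drug-target gene universe (269).
#' @param bg_target_mu,bg_target_size negative-binomial mean and size for
#'   background per-compound target counts (heavy-tailed).
#' @param hub_targets exact target counts planted on hub compounds
#'   (default `c(150, 110, 90, 75, 60)`); these are pre-restriction counts,
#'   chosen so hubs still dominate after intersection with disease genes.
#' @param hub_herb_counts herb memberships planted on each hub compound.
#' @param n_disease_genes total disease-associated genes (255).
#' @param n_disease_sources number of database-style source lists the
#'   disease genes are split across (3).
#' @param overlap_fraction fraction of disease genes drawn from the
#'   drug-target union — the overlap is constructed exactly, not sampled
#'   (default 48/255).
#' @param ppi_density probability of a background PPI edge between two
#'   non-hub genes (default 0.45).
#' @param ppi_pass_fraction fraction of background edges scoring above the
#'   0.9 confidence threshold (default 0.8).
#' @param n_ppi_hubs number of planted PPI hub genes, wired to every
#'   non-isolated gene with a passing score (default 4).
#' @param n_ppi_isolated number of query genes left without any edge
#'   (default 3).
#' @param n_pathways number of pathways in the GMT collection (100).
#' @param pathway_size_range inclusive size range for pathways (10 to 80).
#' @param planted_enrichment list with `index` (which pathway carries the
#'   signal) and `boost` (how many genes above the null expectation the
#'   planted overlap is). The default 12 is about four null standard
#'   deviations of the overlap count at the largest configured pathway size
#'   (K = 80, n = 48, N = 269 gives sd ~ 2.9), so the planted pathway's p
#'   clears the extreme order statistic of ~100 null pathways for every
#'   feasible size; a count-scale margin smaller than that loses first rank
#'   when the planted pathway happens to be large.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_herbs = 9L,
                       n_compounds_per_herb = 131L,
                       duplicate_rate = 0.105,
                       bioactive_fraction = 0.145,
                       ob_active = c(30, 75),
                       dl_active = c(0.18, 0.95),
                       n_targets_universe = 269L,
                       bg_target_mu = 8,
                       bg_target_size = 2,
                       hub_targets = c(150L, 110L, 90L, 75L, 60L),
                       hub_herb_counts = c(3L, 5L, 1L, 4L, 3L),
                       n_disease_genes = 255L,
                       n_disease_sources = 3L,
                       overlap_fraction = 48 / 255,
                       ppi_density = 0.45,
                       ppi_pass_fraction = 0.8,
                       n_ppi_hubs = 4L,
                       n_ppi_isolated = 3L,
                       n_pathways = 100L,
                       pathway_size_range = c(10L, 80L),
                       planted_enrichment = list(index = 1L, boost = 12L)) {
  cfg <- list(seed = as.integer(seed), n_herbs = as.integer(n_herbs),
              n_compounds_per_herb = as.integer(n_compounds_per_herb),
              duplicate_rate = duplicate_rate,
              bioactive_fraction = bioactive_fraction,
              ob_active = ob_active, dl_active = dl_active,
              n_targets_universe = as.integer(n_targets_universe),
              bg_target_mu = bg_target_mu, bg_target_size = bg_target_size,
              hub_targets = as.integer(hub_targets),
              hub_herb_counts = as.integer(hub_herb_counts),
              n_disease_genes = as.integer(n_disease_genes),
              n_disease_sources = as.integer(n_disease_sources),
              overlap_fraction = overlap_fraction,
              ppi_density = ppi_density,
              ppi_pass_fraction = ppi_pass_fraction,
              n_ppi_hubs = as.integer(n_ppi_hubs),
              n_ppi_isolated = as.integer(n_ppi_isolated),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              planted_enrichment = planted_enrichment)
  probs <- c(cfg$duplicate_rate, cfg$bioactive_fraction, cfg$overlap_fraction,
             cfg$ppi_density, cfg$ppi_pass_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(cfg$hub_targets) != length(cfg$hub_herb_counts)) {
    stop("hub_targets and hub_herb_counts must have equal length")
  }
  if (any(cfg$hub_targets > cfg$n_targets_universe)) {
    stop("planted hub target counts exceed the target universe")
  }
  if (any(cfg$hub_herb_counts > cfg$n_herbs)) {
    stop("planted hub herb counts exceed the number of herbs")
  }
  if (cfg$planted_enrichment$index > cfg$n_pathways) {
    stop("planted pathway index exceeds n_pathways")
  }
  if (cfg$pathway_size_range[1L] > cfg$pathway_size_range[2L] ||
      cfg$pathway_size_range[1L] < 1L) {
    stop("invalid pathway size range")
  }
  structure(cfg, class = "sim_config")
}

# documented seed-splitting scheme: one master seed, fixed per-stage offsets
sub_seed <- function(cfg, stage) {
  offsets <- c(compounds = 1L, targets = 2L, disease = 3L,
               ppi = 4L, gmt = 5L)
  as.integer((as.numeric(cfg$seed) * 101 + offsets[[stage]]) %% (2^31 - 1))
}

draw_ob_dl <- function(n, cfg) {
  pass <- runif(n) < cfg$bioactive_fraction
  ob <- dl <- numeric(n)
  ob[pass] <- runif(sum(pass), cfg$ob_active[1L], cfg$ob_active[2L])
  dl[pass] <- runif(sum(pass), cfg$dl_active[1L], cfg$dl_active[2L])
  if (any(!pass)) {
    # failing compounds miss at least one threshold
    mode <- sample(1:3, sum(!pass), replace = TRUE)
    nf <- sum(!pass)
    ob_f <- ifelse(mode <= 2, runif(nf, 0, 29.99), runif(nf, 30, 100))
    dl_f <- ifelse(mode >= 2, runif(nf, 0, 0.1799), runif(nf, 0.18, 1))
    ob[!pass] <- ob_f
    dl[!pass] <- dl_f
  }
  list(ob = round(ob, 2L), dl = round(dl, 4L), pass = pass)
}

#' Generate a synthetic herb-compound table
#'
#' Planted hub compounds are created first: each is bioactive by
#' construction and listed under `hub_herb_counts[i]` herbs. Remaining
#' listing slots are filled left to right; each slot either reuses an
#' already-created compound under a new herb (probability `duplicate_rate`,
#' planting the cross-herb repeats that deduplication later removes) or
#' creates a fresh compound whose OB/DL pass the screen with probability
#' `bioactive_fraction`.
#'
#' @param cfg a [sim_config()].
#' @return A list with `records` (a herb-expanded `compound_table`) and
#'   `truth`: hub mol_ids, per-compound pass flags, listing/unique/duplicate
#'   counts.
#' @export
gen_compound_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sub_seed(cfg, "compounds"))
  herbs <- sprintf("Herb%02d", seq_len(cfg$n_herbs))
  n_slots <- cfg$n_herbs * cfg$n_compounds_per_herb
  n_hubs <- length(cfg$hub_targets)

  mol_ids <- character(0L); obs <- numeric(0L); dls <- numeric(0L)
  pass_flags <- logical(0L)
  herb_of <- vector("list", 0L)   # herbs each compound is listed under
  new_compound <- function(force_active = FALSE) {
    id <- sprintf("MOLS%05d", length(mol_ids) + 1L)
    if (force_active) {
      ob <- round(runif(1L, cfg$ob_active[1L], cfg$ob_active[2L]), 2L)
      dl <- round(runif(1L, cfg$dl_active[1L], cfg$dl_active[2L]), 4L)
      pass <- TRUE
    } else {
      d <- draw_ob_dl(1L, cfg)
      ob <- d$ob; dl <- d$dl; pass <- d$pass
    }
    mol_ids[[length(mol_ids) + 1L]] <<- id
    obs[[length(obs) + 1L]] <<- ob
    dls[[length(dls) + 1L]] <<- dl
    pass_flags[[length(pass_flags) + 1L]] <<- pass
    herb_of[[length(herb_of) + 1L]] <<- character(0L)
    length(mol_ids)
  }

  hub_idx <- integer(n_hubs)
  for (i in seq_len(n_hubs)) {
    j <- new_compound(force_active = TRUE)
    hub_idx[[i]] <- j
    herb_of[[j]] <- sample(herbs, cfg$hub_herb_counts[[i]])
  }
  slots_left <- n_slots - sum(cfg$hub_herb_counts)
  per_herb_left <- setNames(rep(cfg$n_compounds_per_herb, cfg$n_herbs), herbs)
  for (j in hub_idx) {
    per_herb_left[herb_of[[j]]] <- per_herb_left[herb_of[[j]]] - 1L
  }
  for (h in herbs) {
    for (s in seq_len(per_herb_left[[h]])) {
      reusable <- which(!vapply(herb_of, function(hh) h %in% hh, logical(1L)))
      if (length(reusable) && runif(1L) < cfg$duplicate_rate) {
        j <- if (length(reusable) == 1L) reusable else sample(reusable, 1L)
      } else {
        j <- new_compound()
      }
      herb_of[[j]] <- c(herb_of[[j]], h)
    }
  }
  n_listings <- sum(lengths(herb_of))
  idx <- rep.int(seq_along(mol_ids), lengths(herb_of))
  records <- validate_compound_table(data.frame(
    mol_id = mol_ids[idx],
    name = paste0("compound-", sub("^MOLS0*", "", mol_ids[idx])),
    ob = obs[idx], dl = dls[idx],
    herb = unlist(herb_of),
    n_targets = NA_real_,
    stringsAsFactors = FALSE))
  list(records = records,
       truth = list(hub_mol_ids = mol_ids[hub_idx],
                    hub_herb_counts = cfg$hub_herb_counts,
                    bioactive_mol_ids = mol_ids[pass_flags],
                    n_unique = length(mol_ids),
                    n_listings = n_listings,
                    n_duplicate_listings = n_listings - length(mol_ids)))
}

#' Generate a synthetic compound-to-target map
#'
#' Background compounds draw their target counts from a heavy-tailed
#' negative binomial; the planted hub compounds receive exactly the
#' configured `hub_targets` counts (the largest in the map by
#' construction). Targets are sampled without replacement from a universe
#' of `n_targets_universe` gene symbols.
#'
#' @param cfg a [sim_config()].
#' @param mol_ids character vector of compound ids to map (typically the
#'   screened, deduplicated compounds).
#' @param hub_mol_ids which of them are the planted hubs (defaults to the
#'   truth log naming of [gen_compound_table()]).
#' @return A list with `target_map` (named list), `universe` (gene symbol
#'   vector) and `truth` (planted hub counts, realized mean background
#'   count).
#' @export
gen_target_map <- function(cfg, mol_ids, hub_mol_ids = character(0L)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sub_seed(cfg, "targets"))
  universe <- sprintf("GENE%04d", seq_len(cfg$n_targets_universe))
  hub_mol_ids <- intersect(hub_mol_ids, mol_ids)
  counts <- setNames(integer(length(mol_ids)), mol_ids)
  counts[hub_mol_ids] <- cfg$hub_targets[seq_along(hub_mol_ids)]
  bg <- setdiff(mol_ids, hub_mol_ids)
  counts[bg] <- as.integer(pmin(rnbinom(length(bg), mu = cfg$bg_target_mu,
                                        size = cfg$bg_target_size),
                                cfg$n_targets_universe))
  tm <- lapply(counts, function(k) {
    if (k == 0L) character(0L) else sort(sample(universe, k))
  })
  list(target_map = tm, universe = universe,
       truth = list(hub_mol_ids = hub_mol_ids,
                    hub_target_counts = counts[hub_mol_ids],
                    mean_bg_count = if (length(bg)) mean(counts[bg]) else NA_real_))
}

#' Generate synthetic disease-gene source lists
#'
#' The overlap with the drug-target union is CONSTRUCTED, not sampled:
#' exactly `round(overlap_fraction * n_disease_genes)` disease genes are
#' drawn from the union of mapped targets, the rest are novel symbols
#' disjoint from it. The disease genes are then distributed across
#' `n_disease_sources` overlapping database-style lists (each gene lands in
#' one, two or all sources with equal probability), whose union restores
#' the full disease set exactly.
#'
#' @param cfg a [sim_config()].
#' @param target_map the compound-to-target map whose union defines the
#'   drug-target side.
#' @return A list with `sources` (list of `gene_set`), `disease` (their
#'   union as a `gene_set`) and `truth` (the planted overlap genes).
#' @export
gen_disease_genes <- function(cfg, target_map) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sub_seed(cfg, "disease"))
  drug_union <- sort(unique(unlist(target_map, use.names = FALSE)))
  n_overlap <- round(cfg$overlap_fraction * cfg$n_disease_genes)
  if (n_overlap > length(drug_union)) {
    stop("requested overlap exceeds the drug-target union size")
  }
  shared <- if (n_overlap) sort(sample(drug_union, n_overlap)) else character(0L)
  novel <- sprintf("DIS%04d", seq_len(cfg$n_disease_genes - n_overlap))
  disease <- c(shared, novel)
  n_src <- cfg$n_disease_sources
  assignment <- lapply(disease, function(g) {
    k <- sample.int(n_src, 1L)
    sample.int(n_src, k)
  })
  sources <- lapply(seq_len(n_src), function(s) {
    gene_set(disease[vapply(assignment, function(a) s %in% a, logical(1L))],
             label = sprintf("disease_db%d", s), source = "synthetic")
  })
  list(sources = sources,
       disease = gene_set(disease, label = "disease", source = "synthetic"),
       truth = list(overlap_genes = shared, n_overlap = n_overlap))
}

#' Generate a synthetic scored PPI edge table
#'
#' `n_ppi_isolated` genes are left without any edge (they will be dropped
#' when the subnetwork is induced); `n_ppi_hubs` planted hub genes are wired
#' to every other non-isolated gene with a score strictly above 0.9;
#' remaining pairs carry a background edge with probability `ppi_density`,
#' scoring above 0.9 with probability `ppi_pass_fraction`. Scores live on
#' the 0-1 scale, never exactly at the 0.9 boundary.
#'
#' @param cfg a [sim_config()].
#' @param genes character vector (or `gene_set`) of genes to wire.
#' @return A list with `edges` (a [scored_edges()] table) and `truth`
#'   (hub genes, isolated genes, exact count of edges scoring > 0.9).
#' @export
gen_ppi <- function(cfg, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  if (inherits(genes, "gene_set")) genes <- genes$genes
  genes <- sort(normalize_symbols(genes))
  set.seed(sub_seed(cfg, "ppi"))
  n <- length(genes)
  if (n < cfg$n_ppi_hubs + cfg$n_ppi_isolated + 2L) {
    stop("too few genes for the configured hub/isolated counts")
  }
  shuffled <- sample(genes)
  isolated <- sort(shuffled[seq_len(cfg$n_ppi_isolated)])
  hubs <- sort(shuffled[cfg$n_ppi_isolated + seq_len(cfg$n_ppi_hubs)])
  wired <- setdiff(genes, isolated)
  rest <- setdiff(wired, hubs)
  a <- character(0L); b <- character(0L); sc <- numeric(0L)
  score_pass <- function(m) runif(m, 0.9005, 0.9995)
  score_fail <- function(m) runif(m, 0.40, 0.8995)
  for (h in hubs) {
    others <- setdiff(wired, h)
    others <- others[others > h | !(others %in% hubs)]  # each hub pair once
    a <- c(a, rep(h, length(others))); b <- c(b, others)
    sc <- c(sc, score_pass(length(others)))
  }
  if (length(rest) >= 2L) {
    pairs <- utils::combn(rest, 2L)
    present <- runif(ncol(pairs)) < cfg$ppi_density
    pairs <- pairs[, present, drop = FALSE]
    m <- ncol(pairs)
    pass <- runif(m) < cfg$ppi_pass_fraction
    s <- numeric(m); s[pass] <- score_pass(sum(pass)); s[!pass] <- score_fail(sum(!pass))
    a <- c(a, pairs[1L, ]); b <- c(b, pairs[2L, ]); sc <- c(sc, s)
  }
  edges <- scored_edges(a, b, sc, scale = 1)
  list(edges = edges,
       truth = list(hub_genes = hubs, isolated_genes = isolated,
                    n_edges_passing = sum(edges$score > 0.9)))
}

#' Generate a synthetic GMT pathway collection with one planted signal
#'
#' Null pathways are drawn uniformly from the universe. The planted pathway
#' (at `planted_enrichment$index`) is constructed so that its overlap with
#' `query` exceeds the null expectation `K * n / N` by exactly
#' `planted_enrichment$boost` genes (clamped to feasibility).
#'
#' @param cfg a [sim_config()].
#' @param universe character vector of universe gene symbols.
#' @param query character vector (or `gene_set`): the query whose enrichment
#'   the planted pathway carries.
#' @return A list with `collection` (list of `gene_set`) and `truth`
#'   (planted label, its overlap `k`, the null expectation).
#' @export
gen_gmt <- function(cfg, universe, query) {
  stopifnot(inherits(cfg, "sim_config"))
  if (inherits(query, "gene_set")) query <- query$genes
  universe <- normalize_symbols(universe)
  query <- intersect(normalize_symbols(query), universe)
  set.seed(sub_seed(cfg, "gmt"))
  N <- length(universe); n <- length(query)
  sizes <- sample(seq.int(cfg$pathway_size_range[1L], cfg$pathway_size_range[2L]),
                  cfg$n_pathways, replace = TRUE)
  planted_i <- cfg$planted_enrichment$index
  labels <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  collection <- vector("list", cfg$n_pathways)
  planted_k <- NA_integer_; null_exp <- NA_real_
  for (i in seq_len(cfg$n_pathways)) {
    K <- sizes[[i]]
    if (i == planted_i && n > 0L) {
      null_exp <- K * n / N
      planted_k <- min(n, K, round(null_exp) + cfg$planted_enrichment$boost)
      inside <- sample(query, planted_k)
      outside <- sample(setdiff(universe, query), K - planted_k)
      collection[[i]] <- gene_set(c(inside, outside), label = labels[[i]],
                                  source = "synthetic-planted")
    } else {
      collection[[i]] <- gene_set(sample(universe, K), label = labels[[i]],
                                  source = "synthetic-null")
    }
  }
  list(collection = collection,
       truth = list(planted_pathway = labels[[planted_i]],
                    planted_k = planted_k, null_expectation = null_exp,
                    boost = cfg$planted_enrichment$boost))
}

#' Generate every pipeline input from one configuration
#'
#' Runs all generators in pipeline order (compounds -> screen -> dedupe ->
#' targets -> disease genes -> PPI over the common genes -> GMT over the
#' target universe) and, when `outdir` is given, writes every file format
#' the pipeline reads plus a machine-readable `truth.json`.
#'
#' @param cfg a [sim_config()].
#' @param outdir optional directory to write `compounds.tsv`,
#'   `targets.tsv`, `disease_db*.txt`, `ppi.tsv`, `pathways.gmt`,
#'   `truth.json`.
#' @return Invisibly, a list with every generated object and a merged
#'   `truth` log.
#' @export
simulate_all <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  comp <- gen_compound_table(cfg)
  screened <- screen_compounds(comp$records, screen_config())
  dd <- dedupe_compounds(screened)
  tm <- gen_target_map(cfg, dd$unique$mol_id, comp$truth$hub_mol_ids)
  dis <- gen_disease_genes(cfg, tm$target_map)
  drug_targets <- gene_set(unlist(tm$target_map, use.names = FALSE),
                           label = "drug_targets", source = "synthetic")
  common <- intersect_with_targets(dis$disease, drug_targets)
  ppi <- gen_ppi(cfg, common)
  gmt <- gen_gmt(cfg, tm$universe, common$genes)
  truth <- list(compounds = comp$truth, targets = tm$truth,
                disease = dis$truth, ppi = ppi$truth, gmt = gmt$truth)
  out <- list(records = comp$records, screened = screened, deduped = dd,
              target_map = tm$target_map, universe = tm$universe,
              disease_sources = dis$sources, disease = dis$disease,
              common = common, ppi_edges = ppi$edges,
              collection = gmt$collection, truth = truth, config = cfg)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_compound_table(comp$records, file.path(outdir, "compounds.tsv"))
    write_target_map(tm$target_map, file.path(outdir, "targets.tsv"))
    for (i in seq_along(dis$sources)) {
      write_gene_list(dis$sources[[i]],
                      file.path(outdir, sprintf("disease_db%d.txt", i)))
    }
    ppi_df <- data.frame(node1 = ppi$edges$gene_a, node2 = ppi$edges$gene_b,
                         combined_score = ppi$edges$score)
    write.table(ppi_df, file.path(outdir, "ppi.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_gmt(gmt$collection, file.path(outdir, "pathways.gmt"))
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
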