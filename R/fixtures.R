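#' Bundled Wenjing decoction example tables
#'
#' The package ships two small plain-text tables for the nine-herb Wenjing
#' decoction (a classical TCM prescription studied against endometriosis):
#' `wjd_herb_counts()` returns the per-herb summary (number of catalogued
#' compounds, number passing the OB/DL screen, number of predicted targets)
#' and `wjd_compounds()` returns the 50 screened compounds that map to the
#' 48 disease-intersected target genes, with their OB, DL, per-compound
#' mapped-target count and herb memberships.
#'
#' @return `wjd_herb_counts()`: a `data.frame` with columns `herb`,
#'   `n_compounds`, `n_bioactive`, `n_targets`. `wjd_compounds()`: a
#'   `compound_table` with one row per (compound, herb) membership.
#' @examples
#' tab <- wjd_compounds()
#' length(unique(tab$mol_id)) # 50 compounds
#' @export
wjd_compounds <- function() {
  read_compound_table(system.file("extdata", "wjd_compounds.tsv",
                                  package = "netpharm", mustWork = TRUE))
}

#' @rdname wjd_compounds
#' @export
wjd_herb_counts <- function() {
  read.delim(system.file("extdata", "wjd_herb_counts.tsv",
                         package = "netpharm", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Synthetic target map consistent with the bundled compound table
#'
#' The example compound table records how many of the 48 common target genes
#' each compound maps to, but the gene-level assignments themselves were
#' never published. This helper constructs a SYNTHETIC stand-in: a
#' deterministic round-robin assignment of each compound's `n_targets` genes
#' from a 48-symbol pool, so that every gene is covered, each compound's
#' mapped-target count matches the printed table exactly, and compound
#' degrees in the tripartite network equal herb memberships plus mapped
#' targets. Gene-level identities are placeholders (the four hub genes
#' TP53, IL6, VEGFA, ESR1 plus generic symbols) and carry no biological
#' meaning.
#'
#' @param compounds a compound table with `mol_id` and `n_targets` columns;
#'   defaults to [wjd_compounds()].
#' @return A named list mapping `mol_id` to gene-symbol vectors, with
#'   attribute `genes` holding the 48-gene pool.
#' @export
synthetic_wjd_target_map <- function(compounds = wjd_compounds()) {
  per_compound <- unique(as.data.frame(compounds)[, c("mol_id", "n_targets")])
  per_compound <- per_compound[order(per_compound$mol_id), , drop = FALSE]
  pool <- c("TP53", "IL6", "VEGFA", "ESR1", sprintf("TGT%02d", seq_len(44L)))
  stopifnot(max(per_compound$n_targets, na.rm = TRUE) <= length(pool))
  ptr <- 0L
  tm <- setNames(vector("list", nrow(per_compound)), per_compound$mol_id)
  for (i in seq_len(nrow(per_compound))) {
    k <- per_compound$n_targets[[i]]
    if (is.na(k) || k == 0L) { tm[[i]] <- character(0L); next }
    take <- ((ptr + seq_len(k) - 1L) %% length(pool)) + 1L
    tm[[i]] <- sort(pool[take])
    ptr <- (ptr + k) %% length(pool)
  }
  attr(tm, "genes") <- pool
  tm
}
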