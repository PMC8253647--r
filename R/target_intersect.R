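#' Union several disease-gene sources with provenance
#'
#' Combines gene lists from multiple databases into one nonredundant set,
#' keeping track of which sources contributed each gene (needed for the
#' per-source overlap structure of a Venn diagram).
#'
#' @param sources a list of [gene_set()] objects (at least one).
#' @param label label for the resulting set.
#' @return A `gene_set` whose `provenance` attribute is a logical membership
#'   matrix (genes x sources).
#' @export
union_gene_sources <- function(sources, label = "union") {
  stopifnot(is.list(sources), length(sources) >= 1L,
            all(vapply(sources, inherits, logical(1L), "gene_set")))
  all_genes <- sort(unique(unlist(lapply(sources, `[[`, "genes"))))
  src_labels <- vapply(sources, `[[`, character(1L), "label")
  if (anyDuplicated(src_labels)) src_labels <- make.unique(src_labels)
  membership <- vapply(sources, function(s) all_genes %in% s$genes,
                       logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(all_genes, src_labels))
  out <- gene_set(all_genes, label = label,
                  source = paste(src_labels, collapse = "+"))
  attr(out, "provenance") <- membership
  out
}

#' Intersect disease genes with compound targets
#'
#' Exact set intersection after symbol normalization. An empty intersection
#' raises a warning and returns an empty set so the pipeline can continue.
#'
#' @param disease a `gene_set` of disease-associated genes.
#' @param drug_targets a `gene_set` of predicted compound targets.
#' @param label label for the result.
#' @return A `gene_set` of the common genes.
#' @export
intersect_with_targets <- function(disease, drug_targets, label = "common") {
  stopifnot(inherits(disease, "gene_set"), inherits(drug_targets, "gene_set"))
  common <- intersect(disease$genes, drug_targets$genes)
  if (!length(common)) {
    warning("no overlap between disease genes and compound targets")
  }
  gene_set(common, label = label,
           source = paste(disease$label, drug_targets$label, sep = " & "))
}

#' Venn region counts over gene-set sources
#'
#' Tabulates every disjoint Venn region over up to six sources by exhaustive
#' membership classification (each gene is assigned to exactly one region,
#' so region counts always partition the union). Optionally also reports the
#' intersection of the union with a drug-target set.
#'
#' @param sources list of `gene_set` objects (2 to 6).
#' @param drug_targets optional `gene_set`; when given, the summary includes
#'   the size of `union(sources) intersect drug_targets`.
#' @return An object of class `venn_summary`: a list with `sizes`
#'   (per-source), `regions` (a `data.frame` of disjoint region counts with
#'   one logical column per source), `union_size`, and
#'   `n_common_with_targets` (NA when `drug_targets` is absent).
#' @export
venn_summary <- function(sources, drug_targets = NULL) {
  stopifnot(is.list(sources), length(sources) >= 2L)
  if (length(sources) > 6L) {
    stop("venn_summary supports at most 6 sources (region count doubles per source)")
  }
  uni <- union_gene_sources(sources)
  membership <- attr(uni, "provenance")
  src_labels <- colnames(membership)
  # every non-empty membership pattern is one disjoint region
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(sources)))
  names(grid) <- src_labels
  grid <- grid[rowSums(grid) > 0L, , drop = FALSE]
  pattern_key <- apply(membership, 1L, paste, collapse = ",")
  grid$count <- vapply(seq_len(nrow(grid)), function(i) {
    key <- paste(unlist(grid[i, src_labels]), collapse = ",")
    sum(pattern_key == key)
  }, integer(1L))
  rownames(grid) <- NULL
  n_common <- if (is.null(drug_targets)) NA_integer_ else {
    length(intersect(uni$genes, drug_targets$genes))
  }
  structure(
    list(sizes = setNames(vapply(sources, length, integer(1L)), src_labels),
         regions = grid,
         union_size = length(uni),
         n_common_with_targets = n_common),
    class = "venn_summary"
  )
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("venn_summary over", length(x$sizes), "sources; union size",
      x$union_size, "\n")
  print(x$regions)
  if (!is.na(x$n_common_with_targets)) {
    cat("common with drug targets:", x$n_common_with_targets, "\n")
  }
  invisible(x)
}

#' Export a Venn summary as JSON
#' @param x a `venn_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_venn_json <- function(x, path) {
  stopifnot(inherits(x, "venn_summary"))
  jsonlite::write_json(
    list(sizes = as.list(x$sizes), regions = x$regions,
         union_size = x$union_size,
         n_common_with_targets = x$n_common_with_targets),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
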