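#' Build a herb-compound-gene tripartite network
#'
#' Constructs the undirected multinetwork with three node partitions: herbs,
#' compounds, and target genes. Edges connect a compound to each herb it
#' belongs to and to each of its mapped targets that survives restriction to
#' `genes`; herb-gene and within-partition edges never occur. Compounds with
#' no surviving target are retained (flagged `isolated`), as are genes in
#' `genes` that no compound maps to — a compound's degree therefore
#' decomposes exactly as herb memberships + surviving mapped targets.
#'
#' @param records deduplicated compound records: either the `unique` element
#'   of [dedupe_compounds()] (with a `herbs` column) or a herb-expanded
#'   `compound_table` (deduplicated internally).
#' @param target_map named list mapping `mol_id` to gene-symbol vectors.
#' @param genes a [gene_set()] or character vector: the gene universe the
#'   network is built against (e.g. the disease-intersected common genes).
#' @param sep separator of the `herbs` column (default `";"`).
#' @return An undirected simple `igraph` with vertex attributes `partition`
#'   (`"herb"`, `"compound"` or `"gene"`) and `isolated`.
#' @export
build_multinetwork <- function(records, target_map, genes, sep = ";") {
  if (inherits(genes, "gene_set")) genes <- genes$genes
  genes <- sort(normalize_symbols(genes))
  records <- as.data.frame(records)
  if (!"herbs" %in% names(records)) {
    if (!"herb" %in% names(records)) stop("records need a 'herb' or 'herbs' column")
    records <- dedupe_compounds(validate_compound_table(records), sep = sep)$unique
  }
  herb_lists <- lapply(strsplit(records$herbs, sep, fixed = TRUE), trimws)
  if (any(lengths(herb_lists) == 0L)) {
    stop("compound(s) without herb membership: ",
         paste(records$mol_id[lengths(herb_lists) == 0L], collapse = ", "))
  }
  compounds <- records$mol_id
  if (anyDuplicated(compounds)) stop("records not deduplicated by mol_id")
  herbs <- sort(unique(unlist(herb_lists)))
  if (anyDuplicated(c(herbs, compounds, genes))) {
    stop("node labels collide across partitions")
  }
  tm <- lapply(target_map[compounds], function(g) {
    if (is.null(g)) character(0L) else intersect(normalize_symbols(g), genes)
  })
  names(tm) <- compounds
  hc_edges <- cbind(rep(compounds, lengths(herb_lists)), unlist(herb_lists))
  cg_edges <- cbind(rep(compounds, lengths(tm)), unlist(tm, use.names = FALSE))
  edges <- rbind(hc_edges, cg_edges)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(
      name = c(herbs, compounds, genes),
      partition = rep(c("herb", "compound", "gene"),
                      c(length(herbs), length(compounds), length(genes))),
      stringsAsFactors = FALSE)
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::V(g)$isolated <- igraph::degree(g) == 0L
  g
}

#' Degree report for a typed network
#'
#' Exact integer degree per node, per-partition mean degrees, and the
#' whole-network mean degree 2E/N (reported both exactly and rounded to 3
#' decimals). Isolated nodes count in N.
#'
#' @param net an `igraph` with a `partition` vertex attribute (from
#'   [build_multinetwork()] or [induce_subnetwork()]).
#' @return A `data.frame` of class `degree_report` with columns `node`,
#'   `partition`, `degree`, `above_network_mean`; attributes `network_mean`
#'   (exact), `network_mean_3dp`, and `partition_means`.
#' @export
degree_report <- function(net) {
  stopifnot(inherits(net, "igraph"))
  if (igraph::vcount(net) == 0L) stop("empty network")
  deg <- igraph::degree(net)
  part <- igraph::V(net)$partition
  if (is.null(part)) part <- rep("node", igraph::vcount(net))
  mean_deg <- 2 * igraph::ecount(net) / igraph::vcount(net)
  out <- data.frame(node = igraph::V(net)$name,
                    partition = part,
                    degree = as.integer(deg),
                    above_network_mean = deg > mean_deg,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "network_mean") <- mean_deg
  attr(out, "network_mean_3dp") <- round(mean_deg, 3L)
  attr(out, "partition_means") <- vapply(split(deg, part), mean, numeric(1L))
  class(out) <- c("degree_report", "data.frame")
  out
}

#' Select key nodes from a degree report
#'
#' Two selection rules mirroring common hub definitions: `"above_mean"`
#' keeps nodes whose degree strictly exceeds the whole-network mean degree
#' ("exceeding" is read as `>`, so a node exactly at the mean is not
#' selected); `"top_k"` ranks by degree descending with ties broken by node
#' label ascending.
#'
#' @param report a [degree_report()].
#' @param partition restrict to one partition (e.g. `"compound"`); `NULL`
#'   for all nodes.
#' @param rule `"above_mean"` (default) or `"top_k"`.
#' @param k number of nodes for `"top_k"`; if `k` exceeds the candidate
#'   count, all candidates are returned with a warning.
#' @return The selected rows, sorted by degree descending then label.
#' @export
select_key_nodes <- function(report, partition = NULL,
                             rule = c("above_mean", "top_k"), k = 5L) {
  rule <- match.arg(rule)
  stopifnot(inherits(report, "degree_report"))
  cand <- as.data.frame(report)
  if (!is.null(partition)) cand <- cand[cand$partition %in% partition, , drop = FALSE]
  cand <- cand[order(-cand$degree, cand$node), , drop = FALSE]
  out <- if (rule == "above_mean") {
    cand[cand$degree > attr(report, "network_mean"), , drop = FALSE]
  } else {
    if (k > nrow(cand)) {
      warning("k = ", k, " exceeds candidate count ", nrow(cand), "; returning all")
      k <- nrow(cand)
    }
    cand[seq_len(k), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Export a typed network
#'
#' GraphML keeps the `partition` vertex attribute; SIF writes one
#' `source<TAB>relation<TAB>target` line per edge with the relation named
#' after the partition pair (e.g. `herb-compound`).
#'
#' @param net an `igraph` with a `partition` vertex attribute.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_sif <- function(net, path) {
  el <- igraph::as_edgelist(net)
  part <- setNames(igraph::V(net)$partition, igraph::V(net)$name)
  if (nrow(el)) {
    rel <- paste(part[el[, 1L]], part[el[, 2L]], sep = "-")
    writeLines(paste(el[, 1L], rel, el[, 2L], sep = "\t"), path)
  } else {
    writeLines(character(0L), path)
  }
  invisible(path)
}
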