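#' Construct a cleaned scored edge set
#'
#' Protein-protein interaction exports carry per-edge confidence scores on
#' either a 0-1 or 0-1000 scale (STRING prints `combined_score` as an
#' integer in 0-1000). Cleaning removes self-edges, treats (a, b) and
#' (b, a) as the same undirected edge, and keeps the highest score on
#' duplicates.
#'
#' @param gene_a,gene_b character vectors of endpoint gene symbols.
#' @param score numeric confidence scores.
#' @param scale declared scale: `1` (scores in \[0, 1\]) or `1000`.
#' @return A `data.frame` of class `scored_edges` with columns `gene_a`,
#'   `gene_b` (a < b lexicographically), `score`, and attribute `scale`.
#' @export
scored_edges <- function(gene_a, gene_b, score, scale = 1) {
  stopifnot(length(gene_a) == length(gene_b),
            length(gene_a) == length(score),
            scale %in% c(1, 1000))
  gene_a <- toupper(trimws(gene_a)); gene_b <- toupper(trimws(gene_b))
  score <- as.numeric(score)
  bad <- which(is.na(score) | score < 0 | score > scale)
  if (length(bad)) {
    stop(sprintf("edge %d (%s - %s): score %s outside declared scale [0, %s]",
                 bad[1L], gene_a[bad[1L]], gene_b[bad[1L]],
                 format(score[bad[1L]]), format(scale)))
  }
  keep <- gene_a != gene_b & nzchar(gene_a) & nzchar(gene_b)
  gene_a <- gene_a[keep]; gene_b <- gene_b[keep]; score <- score[keep]
  if (!length(score)) {
    out <- data.frame(gene_a = character(0L), gene_b = character(0L),
                      score = numeric(0L), stringsAsFactors = FALSE)
    attr(out, "scale") <- scale
    class(out) <- c("scored_edges", "data.frame")
    return(out)
  }
  lo <- pmin(gene_a, gene_b); hi <- pmax(gene_a, gene_b)
  key <- paste(lo, hi, sep = "\r")
  best <- tapply(score, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, character(1L), 1L),
                    gene_b = vapply(parts, `[`, character(1L), 2L),
                    score = as.numeric(best),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scale") <- scale
  class(out) <- c("scored_edges", "data.frame")
  out
}

#' Read a STRING-style scored edge table
#'
#' Expects a TSV with header columns for the two endpoints and the combined
#' confidence score (`node1`, `node2`, `combined_score` by default;
#' remappable via `dialect`).
#'
#' @param path path to the TSV.
#' @param scale declared score scale, `1` or `1000`.
#' @param dialect named character vector remapping `node1`, `node2`,
#'   `combined_score` to the file's headers.
#' @return A [scored_edges()] table.
#' @export
read_ppi_edges <- function(path, scale = 1000, dialect = NULL) {
  if (!file.exists(path)) stop("PPI edge table not found: ", path)
  dia <- c(node1 = "node1", node2 = "node2", combined_score = "combined_score")
  if (!is.null(dialect)) dia[names(dialect)] <- dialect
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- dia[!dia %in% names(raw)]
  if (length(miss)) stop("PPI table lacks column(s): ", paste(miss, collapse = ", "))
  scored_edges(raw[[dia[["node1"]]]], raw[[dia[["node2"]]]],
               raw[[dia[["combined_score"]]]], scale = scale)
}

#' Filter edges by confidence score
#'
#' Keeps edges whose score strictly exceeds the threshold after normalizing
#' the declared scale, so `min_score = 0.9` means `> 900` on the 0-1000
#' scale. The strict inequality follows the "confidence score > 0.9"
#' convention; set `strict = FALSE` for STRING's own "highest confidence"
#' preset (`>=`).
#'
#' @param edges a [scored_edges()] table.
#' @param min_score threshold on the 0-1 scale (default 0.9).
#' @param strict logical; strict `>` (default) or `>=`.
#' @return The retained edges (same class, same scale attribute).
#' @export
filter_edges <- function(edges, min_score = 0.9, strict = TRUE) {
  stopifnot(inherits(edges, "scored_edges"))
  scale <- attr(edges, "scale")
  thr <- min_score * scale
  keep <- if (strict) edges$score > thr else edges$score >= thr
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scale") <- scale
  class(out) <- c("scored_edges", "data.frame")
  out
}

#' Induce the PPI subnetwork on a query gene set
#'
#' Restricts the edge set to pairs with both endpoints in `genes` and builds
#' an undirected simple graph. Query genes with no surviving edge are, by
#' default, excluded from the node set and reported separately (this is what
#' makes a 48-gene query yield a smaller network when some genes have no
#' high-confidence interactions); set `drop_isolated = FALSE` to keep them
#' as degree-0 nodes.
#'
#' @param edges a (typically filtered) [scored_edges()] table.
#' @param genes a [gene_set()] or character vector of query genes.
#' @param drop_isolated logical, default `TRUE`.
#' @return A list with `network` (an `igraph` whose vertices carry
#'   `partition = "gene"`) and `dropped` (character vector of query genes
#'   with no surviving edge; empty when `drop_isolated = FALSE`).
#' @export
induce_subnetwork <- function(edges, genes, drop_isolated = TRUE) {
  stopifnot(inherits(edges, "scored_edges"))
  if (inherits(genes, "gene_set")) genes <- genes$genes
  genes <- sort(normalize_symbols(genes))
  if (!length(genes)) stop("empty query gene set")
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes
  el <- edges[keep, , drop = FALSE]
  connected <- sort(unique(c(el$gene_a, el$gene_b)))
  isolated <- setdiff(genes, connected)
  nodes <- if (drop_isolated) connected else genes
  g <- igraph::graph_from_data_frame(
    el[, c("gene_a", "gene_b", "score")], directed = FALSE,
    vertices = data.frame(name = nodes,
                          partition = rep("gene", length(nodes)),
                          stringsAsFactors = FALSE))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(score = "max"))
  list(network = g, dropped = if (drop_isolated) isolated else character(0L))
}

#' Hub statistics for a PPI network
#'
#' Mean degree is 2E/N (exact, plus a 3-decimal rounding for reporting);
#' hubs are the nodes whose degree strictly exceeds it; the top list ranks
#' by degree descending with label tie-break.
#'
#' @param net an `igraph` (e.g. `induce_subnetwork(...)$network`).
#' @param top_k how many top nodes to return (default 4).
#' @return A list with `mean_degree` (exact), `mean_degree_3dp`, `hubs`
#'   (character vector), `n_hubs`, and `top` (a `data.frame` of the top-k
#'   nodes with degrees).
#' @export
hub_stats <- function(net, top_k = 4L) {
  stopifnot(inherits(net, "igraph"))
  if (igraph::vcount(net) == 0L) stop("empty network")
  deg <- igraph::degree(net)
  mean_deg <- 2 * igraph::ecount(net) / igraph::vcount(net)
  ord <- order(-deg, names(deg))
  top_k <- min(top_k, length(deg))
  list(
    mean_degree = mean_deg,
    mean_degree_3dp = round(mean_deg, 3L),
    hubs = sort(names(deg)[deg > mean_deg]),
    n_hubs = sum(deg > mean_deg),
    top = data.frame(node = names(deg)[ord][seq_len(top_k)],
                     degree = as.integer(deg[ord][seq_len(top_k)]),
                     row.names = NULL, stringsAsFactors = FALSE)
  )
}
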