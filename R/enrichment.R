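#' Hypergeometric upper-tail probability
#'
#' The enrichment statistic: the probability of drawing at least `k`
#' pathway genes when `n` query genes are sampled without replacement from
#' a universe of `N` genes of which `K` lie in the pathway,
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' This equals the one-sided Fisher exact p of the 2x2 table
#' (k, n-k; K-k, N-K-n+k). Terms are accumulated as log-binomials
#' (log-sum-exp) for numerical stability; `k = 0` returns exactly 1.
#'
#' All four arguments are vectorized (recycled to a common length).
#'
#' @param k overlap count(s), `0 <= k <= min(n, K)`.
#' @param n query size(s).
#' @param K pathway size(s) in the universe.
#' @param N universe size(s); requires `n <= N` and `K <= N`.
#' @return Numeric vector of upper-tail probabilities in (0, 1\].
#' @examples
#' hypergeom_p(4, 4, 5, 10)  # 5/210
#' @export
hypergeom_p <- function(k, n, K, N) {
  len <- max(length(k), length(n), length(K), length(N))
  k <- rep_len(as.numeric(k), len); n <- rep_len(as.numeric(n), len)
  K <- rep_len(as.numeric(K), len); N <- rep_len(as.numeric(N), len)
  if (any(k < 0 | n < 0 | K < 0 | N < 0 | n > N | K > N | k > pmin(n, K))) {
    stop("infeasible hypergeometric margins: need 0 <= k <= min(n, K) and n, K <= N")
  }
  vapply(seq_len(len), function(j) {
    if (k[j] == 0) return(1)
    i <- seq.int(k[j], min(n[j], K[j]))
    lt <- lchoose(K[j], i) + lchoose(N[j] - K[j], n[j] - i) - lchoose(N[j], n[j])
    m <- max(lt)
    min(1, exp(m + log(sum(exp(lt - m)))))
  }, numeric(1L))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: sort p ascending, multiply by m/rank,
#' enforce monotonicity from the largest down, cap at 1. Never decreases a
#' p-value and preserves the ranking by raw p.
#'
#' @param pvalues numeric vector of p-values in (0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (!length(pvalues)) return(numeric(0L))
  if (any(is.na(pvalues) | pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(pvalues)
  ord <- order(pvalues)
  stepped <- pvalues[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  pmin(1, adj)[order(ord)]
}

#' Gene-set overrepresentation analysis
#'
#' One-sided hypergeometric (Fisher exact) test of a query gene set against
#' each pathway in a collection. The universe defaults to the union of all
#' genes in the collection — the closest self-contained convention when the
#' true annotation background is unknown — and is configurable. Query genes
#' absent from the universe are dropped (shrinking `n`) with a message,
#' never silently.
#'
#' Results are filtered to raw `p < p_max`, sorted ascending by p with label
#' tie-break, and truncated to `top_n` (mirroring the common "top 30
#' pathways by P value" presentation). BH adjustment is computed over the
#' full collection before filtering and reported in `p_adj` when
#' `adjust = "BH"`; it never drives the default filter.
#'
#' @param query a [gene_set()] (or character vector) of query genes.
#' @param collection a list of [gene_set()] pathways.
#' @param universe a `gene_set`, character vector, or `NULL` (union of the
#'   collection).
#' @param p_max raw-p filter threshold (default 0.05).
#' @param top_n maximum number of pathways returned (default 30).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `data.frame` of class `enrichment_result` with columns
#'   `pathway`, `k`, `n`, `K`, `N`, `p`, `p_adj`, `percentage`
#'   (`100 * k / n`) and `genes` (comma-joined overlap), sorted by p. The
#'   attribute `n_significant` records how many pathways passed `p < p_max`
#'   before truncation; `n_query_dropped` how many query genes fell outside
#'   the universe.
#' @export
enrich <- function(query, collection, universe = NULL, p_max = 0.05,
                   top_n = 30L, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(collection), length(collection) >= 1L,
            all(vapply(collection, inherits, logical(1L), "gene_set")))
  if (inherits(query, "gene_set")) query <- query$genes
  query <- normalize_symbols(query)
  uni <- if (is.null(universe)) {
    unique(unlist(lapply(collection, `[[`, "genes")))
  } else if (inherits(universe, "gene_set")) universe$genes else {
    normalize_symbols(universe)
  }
  if (!length(uni)) stop("empty universe")
  dropped <- setdiff(query, uni)
  if (length(dropped)) {
    message(length(dropped), " query gene(s) absent from the universe were dropped")
  }
  query <- intersect(query, uni)
  n <- length(query); N <- length(uni)
  rows <- lapply(collection, function(s) {
    members <- intersect(s$genes, uni)
    overlap <- intersect(query, members)
    data.frame(pathway = s$label, k = length(overlap), n = n,
               K = length(members), N = N,
               genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p <- hypergeom_p(res$k, res$n, res$K, res$N)
  res$p_adj <- if (adjust == "BH") bh_adjust(res$p) else NA_real_
  res$percentage <- if (n > 0) 100 * res$k / n else NA_real_
  keep <- res$p < p_max
  n_sig <- sum(keep)
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$p, res$pathway), , drop = FALSE]
  if (nrow(res) > top_n) res <- res[seq_len(top_n), , drop = FALSE]
  res <- res[, c("pathway", "k", "n", "K", "N", "p", "p_adj", "percentage", "genes")]
  rownames(res) <- NULL
  attr(res, "n_significant") <- n_sig
  attr(res, "n_query_dropped") <- length(dropped)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Export enrichment results as bubble-plot data
#'
#' Writes the fields a bubble chart encodes — pathway, overlap count `k`
#' (bubble area), `percentage` of the query in the pathway (x axis), and
#' the raw and adjusted p (bubble color) — as a TSV with full precision.
#'
#' @param results an [enrich()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
bubble_export <- function(results, path) {
  stopifnot(is.data.frame(results))
  cols <- c("pathway", "k", "percentage", "p", "p_adj")
  df <- as.data.frame(results)[, cols, drop = FALSE]
  for (col in c("percentage", "p", "p_adj")) {
    df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
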