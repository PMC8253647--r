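# independent oracle: enumerate every size-n draw from a universe of N
# elements of which the first K are "in the pathway"; P(X >= k) by counting
enum_upper_tail <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  sum(hits >= k) / ncol(draws)
}

test_that("hypergeometric tail handles the closed-form and degenerate cases", {
  expect_identical(hypergeom_p(0, 10, 5, 100), 1)
  expect_equal(hypergeom_p(4, 4, 5, 10), 5 / 210)
  # K = N: every draw is inside the pathway
  expect_equal(hypergeom_p(3, 5, 12, 12), 1)
  expect_error(hypergeom_p(6, 5, 5, 10), "infeasible")
  expect_error(hypergeom_p(2, 5, 11, 10), "infeasible")
})

test_that("hypergeom_p equals exhaustive enumeration for N <= 12", {
  for (N in c(8L, 10L, 12L)) {
    for (K in c(2L, N %/% 2L, N - 1L)) {
      for (n in c(3L, N %/% 2L)) {
        for (k in 0:min(n, K)) {
          if (n - k > N - K) next # infeasible corner
          expect_equal(hypergeom_p(k, n, K, N), enum_upper_tail(k, n, K, N),
                       tolerance = 1e-12,
                       label = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
        }
      }
    }
  }
})

test_that("hypergeom_p agrees with phyper and one-sided fisher.test", {
  cases <- data.frame(k = c(3, 10, 1), n = c(20, 48, 5),
                      K = c(15, 40, 30), N = c(100, 269, 300))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      expect_equal(hypergeom_p(k, n, K, N),
                   phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   tolerance = 1e-12)
      tab <- matrix(c(k, n - k, K - k, N - K - n + k), 2)
      expect_equal(hypergeom_p(k, n, K, N),
                   fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-9)
    })
  }
})

test_that("p is non-increasing in k for fixed margins", {
  p <- hypergeom_p(0:20, 30, 40, 200)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("BH step-up matches the hand-computed example and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.4), 0.4)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")

  set.seed(12)
  for (i in 1:5) {
    p <- runif(50)
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, method = "BH"))
    expect_true(all(adj >= p))
    expect_equal(order(p), order(adj, p)) # ranking by raw p preserved
  }
})

test_that("enrich ranks a perfectly matching pathway first", {
  universe <- sprintf("U%02d", 1:40)
  query <- gene_set(universe[1:8], label = "query")
  collection <- list(
    gene_set(universe[1:8], label = "match"),
    gene_set(universe[21:30], label = "miss1"),
    gene_set(universe[31:40], label = "miss2"))
  res <- enrich(query, collection, universe = universe)
  expect_equal(res$pathway[[1L]], "match")
  expect_equal(res$k[[1L]], 8L)
  expect_equal(res$percentage[[1L]], 100)
  expect_equal(res$p[[1L]], hypergeom_p(8, 8, 8, 40))
})

test_that("enrich drops out-of-universe query genes loudly and truncates sorted results", {
  universe <- sprintf("U%02d", 1:30)
  collection <- lapply(1:6, function(i) {
    gene_set(universe[((i - 1) * 5 + 1):(i * 5)], label = sprintf("pw%02d", i))
  })
  expect_message(
    res <- enrich(c(universe[1:5], "NOT_IN_UNIVERSE"), collection,
                  universe = universe, p_max = 1.00001, top_n = 3L),
    "dropped")
  expect_equal(attr(res, "n_query_dropped"), 1L)
  expect_equal(res$n[[1L]], 5L)
  expect_equal(nrow(res), 3L)
  expect_true(!is.unsorted(res$p))

  # default universe is the union of the collection
  res2 <- enrich(universe[1:5], collection, p_max = 1.00001, top_n = 10L)
  expect_equal(res2$N[[1L]], 30L)
  expect_error(enrich("A", collection, universe = character(0)), "universe")
})

test_that("null p-values are conservative under uniform query draws", {
  set.seed(77)
  N <- 200L; K <- 40L; n <- 30L
  reps <- 1000L
  p <- vapply(seq_len(reps), function(i) {
    k <- sum(sample.int(N, n) <= K)
    hypergeom_p(k, n, K, N)
  }, numeric(1L))
  bound <- 0.05 + 2 * sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(p < 0.05), bound)
})

test_that("bubble export round-trips the plotted fields", {
  universe <- sprintf("U%02d", 1:40)
  res <- enrich(universe[1:8],
                list(gene_set(universe[1:10], label = "pw"),
                     gene_set(universe[30:40], label = "bg")),
                universe = universe, adjust = "BH")
  path <- withr::local_tempfile(fileext = ".tsv")
  bubble_export(res, path)
  back <- read.delim(path)
  expect_equal(back$pathway, res$pathway)
  expect_equal(back$k, res$k)
  expect_equal(back$p, res$p, tolerance = 1e-12)
  expect_equal(back$percentage, res$percentage, tolerance = 1e-12)

  bubble_export(res[0, ], path)
  expect_equal(nrow(read.delim(path)), 0L)
})
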