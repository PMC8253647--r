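#' Read a docking binding-energy table
#'
#' Ingests AutoDock-Vina-style binding energies (kcal/mol; more negative
#' means stronger predicted binding) from either a long-format TSV with
#' header columns `compound`, `target`, `energy`, or a matrix-format TSV
#' whose first column holds compound identifiers and whose remaining
#' headers are targets. Duplicate (compound, target) pairs keep the minimum
#' (best) energy. Missing cells stay `NA` — never silently zero.
#'
#' @param path path to the TSV.
#' @return A numeric matrix of class `docking_matrix` (rows = compounds,
#'   columns = targets, entries in kcal/mol, `NA` for missing pairs).
#' @export
read_docking_scores <- function(path) {
  if (!file.exists(path)) stop("docking table not found: ", path)
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (all(c("compound", "target", "energy") %in% names(raw))) {
    en <- suppressWarnings(as.numeric(raw$energy))
    bad <- which(is.na(en) & !is.na(raw$energy) & nzchar(trimws(as.character(raw$energy))))
    if (length(bad)) {
      stop(sprintf("non-numeric energy %s at line %d of %s",
                   dQuote(raw$energy[bad[1L]]), bad[1L] + 1L, path))
    }
    return(docking_matrix(raw$compound, raw$target, en))
  }
  # matrix format: first column = compound ids
  compounds <- as.character(raw[[1L]])
  targets <- names(raw)[-1L]
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    mm <- suppressWarnings(apply(m, 2L, as.numeric))
    bad <- which(is.na(mm) & !is.na(m) & nzchar(trimws(m)), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric energy %s at row %d, column '%s' of %s",
                   dQuote(m[bad[1L, 1L], bad[1L, 2L]]), bad[1L, 1L],
                   targets[bad[1L, 2L]], path))
    }
    m <- matrix(mm, nrow = length(compounds))
  }
  dimnames(m) <- list(compounds, targets)
  new_docking_matrix(m)
}

new_docking_matrix <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("docking matrix needs compound row names and target column names")
  }
  class(m) <- c("docking_matrix", class(m))
  m
}

#' Build a docking matrix from long-format vectors
#'
#' @param compound,target character vectors of pair identifiers.
#' @param energy numeric binding energies (kcal/mol).
#' @return A `docking_matrix`; duplicate pairs keep the minimum energy.
#' @export
docking_matrix <- function(compound, target, energy) {
  stopifnot(length(compound) == length(target),
            length(compound) == length(energy))
  compound <- trimws(as.character(compound))
  target <- trimws(as.character(target))
  energy <- as.numeric(energy)
  rows <- sort(unique(compound)); cols <- sort(unique(target))
  m <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  for (i in seq_along(energy)) {
    cur <- m[compound[i], target[i]]
    if (is.na(cur) || energy[i] < cur) m[compound[i], target[i]] <- energy[i]
  }
  new_docking_matrix(m)
}

#' Convert a docking matrix to long format
#' @param m a `docking_matrix`.
#' @param drop_na omit missing cells (default `TRUE`).
#' @return A `data.frame` with columns `compound`, `target`, `energy`.
#' @export
docking_long <- function(m, drop_na = TRUE) {
  stopifnot(inherits(m, "docking_matrix"))
  df <- data.frame(compound = rep(rownames(m), times = ncol(m)),
                   target = rep(colnames(m), each = nrow(m)),
                   energy = as.vector(m),
                   stringsAsFactors = FALSE)
  if (drop_na) df <- df[!is.na(df$energy), , drop = FALSE]
  df <- df[order(df$compound, df$target), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Rank docking pairs by binding energy
#'
#' Lower (more negative) binding energy means stronger predicted binding,
#' so ranking is ascending by energy with ties broken by compound label
#' then target label — a total order, invariant under input permutation.
#'
#' @param m a `docking_matrix`.
#' @param per `"global"` ranks all pairs; `"target"` returns each target's
#'   best compound; `"compound"` each compound's best target.
#' @return A `data.frame` with `compound`, `target`, `energy`, `rank`.
#'   Rows or columns that are entirely missing are excluded with a warning.
#' @export
rank_pairs <- function(m, per = c("global", "target", "compound")) {
  per <- match.arg(per)
  stopifnot(inherits(m, "docking_matrix"))
  long <- docking_long(m, drop_na = TRUE)
  if (!nrow(long)) stop("docking matrix has no observed energies")
  empty_rows <- rownames(m)[!rownames(m) %in% long$compound]
  empty_cols <- colnames(m)[!colnames(m) %in% long$target]
  if (length(empty_rows) || length(empty_cols)) {
    warning("all-missing row/column(s) excluded: ",
            paste(c(empty_rows, empty_cols), collapse = ", "))
  }
  long <- long[order(long$energy, long$compound, long$target), , drop = FALSE]
  if (per == "target") {
    long <- long[!duplicated(long$target), , drop = FALSE]
    long <- long[order(long$target), , drop = FALSE]
  } else if (per == "compound") {
    long <- long[!duplicated(long$compound), , drop = FALSE]
    long <- long[order(long$compound), , drop = FALSE]
  }
  long$rank <- rank(long$energy, ties.method = "first")
  rownames(long) <- NULL
  long
}

#' Flag non-spontaneous docking pairs
#'
#' A negative binding energy indicates spontaneous binding; zero or
#' positive energies are flagged.
#'
#' @param m a `docking_matrix`.
#' @return A list with `flagged` (long-format `data.frame` of non-negative
#'   pairs), `n_flagged`, `per_compound` and `per_target` flag counts.
#' @export
spontaneity_check <- function(m) {
  stopifnot(inherits(m, "docking_matrix"))
  long <- docking_long(m, drop_na = TRUE)
  flagged <- long[long$energy >= 0, , drop = FALSE]
  rownames(flagged) <- NULL
  count_by <- function(keys, all_keys) {
    tab <- table(factor(keys, levels = all_keys))
    setNames(as.integer(tab), all_keys)
  }
  list(flagged = flagged,
       n_flagged = nrow(flagged),
       per_compound = count_by(flagged$compound, rownames(m)),
       per_target = count_by(flagged$target, colnames(m)))
}

#' Write a docking matrix as heatmap-ready TSV
#'
#' Matrix layout (compounds as rows, targets as columns) with an explicit
#' `compound` first column; missing pairs written as `NA`.
#'
#' @param m a `docking_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_docking_matrix <- function(m, path) {
  stopifnot(inherits(m, "docking_matrix"))
  df <- data.frame(compound = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
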