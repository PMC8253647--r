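#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames
NULL

# Gene symbols are matched as bare uppercase strings throughout: mixed
# protein/gene nomenclature (e.g. "ERalpha" vs "ESR1") in source tables makes
# case-sensitive matching non-deterministic, so every reader normalizes first.
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  unique(x[nzchar(x)])
}

#' Construct a gene set
#'
#' A `gene_set` is the package's unit of gene membership: a label, a
#' deduplicated vector of uppercase gene symbols, and a free-text source tag
#' recording where the set came from (a database export, a pathway
#' collection, a generator).
#'
#' @param genes character vector of gene symbols; case-folded to uppercase,
#'   whitespace-stripped and deduplicated.
#' @param label single string naming the set.
#' @param source single string recording provenance.
#' @return An object of class `gene_set` with elements `label`, `genes`
#'   (sorted uppercase character vector) and `source`.
#' @examples
#' gene_set(c("Il6", "IL6", "esr1"), label = "demo")
#' @export
gene_set <- function(genes, label = "gene_set", source = "user") {
  stopifnot(is.character(label), length(label) == 1L,
            is.character(source), length(source) == 1L)
  structure(
    list(label = label, genes = sort(normalize_symbols(genes)), source = source),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%d genes, source: %s)\n",
              x$label, length(x$genes), x$source))
  if (length(x$genes)) {
    shown <- head(x$genes, 8L)
    cat(" ", paste(shown, collapse = ", "),
        if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

default_compound_dialect <- function() {
  c(mol_id = "mol_id", name = "name", ob = "ob", dl = "dl",
    herb = "herb", n_targets = "n_targets")
}

#' Read a herb-compound table
#'
#' Ingests a TSV of compound records carrying oral bioavailability (OB, in
#' percent) and drug-likeness (DL, unitless in \[0, 1\]) attributes, one row
#' per compound with the herb column optionally listing several herbs
#' separated by `sep`. Multi-herb rows are expanded to one record per
#' (mol_id, herb) pair; the per-compound attributes (name, ob, dl,
#' n_targets) are carried unchanged onto every expanded record.
#'
#' Header wording varies between database exports, so column names are
#' resolved through `dialect`, a named character vector mapping the
#' canonical names `mol_id`, `name`, `ob`, `dl`, `herb` (and optionally
#' `n_targets`) to the headers actually present in the file.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect named character vector mapping canonical column names to
#'   file headers; defaults to the canonical names themselves.
#' @param sep separator for multi-herb cells (default `";"`).
#' @return A `data.frame` of class `compound_table` with columns `mol_id`,
#'   `name`, `ob`, `dl`, `herb`, `n_targets` (NA when absent), one row per
#'   (mol_id, herb) pair.
#' @export
read_compound_table <- function(path, dialect = NULL, sep = ";") {
  if (!file.exists(path)) stop("compound table not found: ", path)
  dia <- default_compound_dialect()
  if (!is.null(dialect)) dia[names(dialect)] <- dialect
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
  required <- c("mol_id", "name", "ob", "dl", "herb")
  missing_cols <- required[!dia[required] %in% names(raw)]
  if (length(missing_cols)) {
    stop("compound table ", path, " lacks required column(s): ",
         paste(sprintf("%s (expected header '%s')", missing_cols,
                       dia[missing_cols]), collapse = ", "))
  }
  df <- data.frame(
    mol_id = trimws(as.character(raw[[dia[["mol_id"]]]])),
    name   = trimws(as.character(raw[[dia[["name"]]]])),
    ob     = raw[[dia[["ob"]]]],
    dl     = raw[[dia[["dl"]]]],
    herb   = as.character(raw[[dia[["herb"]]]]),
    stringsAsFactors = FALSE
  )
  df$n_targets <- if (dia[["n_targets"]] %in% names(raw)) {
    raw[[dia[["n_targets"]]]]
  } else NA
  for (col in c("ob", "dl", "n_targets")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v) & nzchar(trimws(as.character(df[[col]]))))
    if (length(bad)) {
      stop(sprintf("unparseable %s value %s at line %d of %s",
                   col, dQuote(df[[col]][bad[1L]]), bad[1L] + 1L, path))
    }
    df[[col]] <- v
  }
  # expand multi-herb cells into one record per (mol_id, herb)
  herbs <- strsplit(df$herb, sep, fixed = TRUE)
  herbs <- lapply(herbs, function(h) { h <- trimws(h); h[nzchar(h)] })
  idx <- rep.int(seq_len(nrow(df)), lengths(herbs))
  out <- df[idx, , drop = FALSE]
  out$herb <- as.character(unlist(herbs))
  rownames(out) <- NULL
  validate_compound_table(out)
}

validate_compound_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("mol_id", "name", "ob", "dl", "herb")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("compound table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"n_targets" %in% names(df)) df$n_targets <- NA_real_
  if (nrow(df)) {
    if (any(!nzchar(df$mol_id))) stop("empty mol_id in compound table")
    if (any(df$ob < 0 | df$ob > 100, na.rm = TRUE))
      stop("ob outside [0, 100] in compound table")
    if (any(df$dl < 0 | df$dl > 1, na.rm = TRUE))
      stop("dl outside [0, 1] in compound table")
    if (any(df$n_targets < 0, na.rm = TRUE))
      stop("negative n_targets in compound table")
  }
  class(df) <- c("compound_table", "data.frame")
  df
}

#' Write a compound table to TSV
#'
#' Inverse of [read_compound_table()] for single-herb-per-row tables; rows
#' read back with [read_compound_table()] reproduce the same records.
#'
#' @param df a compound table (`data.frame` with the canonical columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(df, path) {
  cols <- intersect(c("mol_id", "name", "ob", "dl", "n_targets", "herb", "herbs"),
                    names(df))
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines ignored; symbols are uppercased,
#' whitespace-stripped and deduplicated. An empty result raises a warning
#' (the pipeline continues) rather than an error.
#'
#' @param path path to the text file.
#' @param label,source passed to [gene_set()]; `label` defaults to the file
#'   name.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, label = basename(path), source = path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  gs <- gene_set(lines, label = label, source = source)
  if (!length(gs$genes)) warning("gene list ", path, " is empty")
  gs
}

#' Write a gene list (one symbol per line)
#' @param genes a `gene_set` or character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  if (inherits(genes, "gene_set")) genes <- genes$genes
  writeLines(normalize_symbols(genes), path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: `name<TAB>description<TAB>gene1<TAB>gene2...`, one set per
#' line. Genes are normalized as in [read_gene_list()]. A line with fewer
#' than three fields is a row-level error naming the line.
#'
#' @param path path to the GMT file.
#' @return A list of [gene_set()] objects; each `source` holds the GMT
#'   description field.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d of %s has %d field(s); need name, description and >= 1 gene",
                   i, path, length(fields)))
    }
    out[[i]] <- gene_set(fields[-(1:2)], label = fields[[1L]], source = fields[[2L]])
  }
  out
}

#' Write a GMT gene-set collection
#' @param sets list of `gene_set` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$label, s$source, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a compound-to-target map
#'
#' Long-format TSV with header columns `mol_id` and `gene` (one pair per
#' row). Gene symbols are normalized and deduplicated per compound.
#'
#' @param path path to the TSV.
#' @return A named list mapping `mol_id` to a character vector of gene
#'   symbols (a target map).
#' @export
read_target_map <- function(path) {
  if (!file.exists(path)) stop("target map not found: ", path)
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("mol_id", "gene")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("target map lacks column(s): ", paste(miss, collapse = ", "))
  split_genes <- split(raw$gene, raw$mol_id)
  lapply(split_genes, function(g) sort(normalize_symbols(g)))
}

#' Write a compound-to-target map as long-format TSV
#' @param target_map named list of gene-symbol vectors keyed by mol_id.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(target_map, path) {
  df <- data.frame(
    mol_id = rep(names(target_map), lengths(target_map)),
    gene = unlist(target_map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
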