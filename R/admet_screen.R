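#' Screening configuration for OB/DL thresholds
#'
#' Active compounds are selected by oral bioavailability (OB, percent) and
#' drug-likeness (DL, unitless). The conventional thresholds in TCMSP-based
#' work are OB >= 30% and DL >= 0.18, applied inclusively; a strict (`>`)
#' mode is available but not the default.
#'
#' @param ob_min minimum OB in percent, in \[0, 100\] (default 30).
#' @param dl_min minimum DL, in \[0, 1\] (default 0.18).
#' @param inclusive logical; if `TRUE` (default) thresholds are `>=`,
#'   otherwise strict `>`.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(ob_min = 30, dl_min = 0.18, inclusive = TRUE) {
  stopifnot(is.numeric(ob_min), length(ob_min) == 1L, ob_min >= 0, ob_min <= 100,
            is.numeric(dl_min), length(dl_min) == 1L, dl_min >= 0, dl_min <= 1,
            is.logical(inclusive), length(inclusive) == 1L)
  structure(list(ob_min = ob_min, dl_min = dl_min, inclusive = inclusive),
            class = "screen_config")
}

#' Screen compounds by OB and DL thresholds
#'
#' Retains exactly the records with `ob >= ob_min` and `dl >= dl_min`
#' (or strict `>` when `config$inclusive` is `FALSE`), preserving input
#' order. Idempotent: screening a screened table changes nothing.
#'
#' @param records a compound table (see [read_compound_table()]).
#' @param config a [screen_config()].
#' @return The retained rows as a `compound_table` (possibly empty).
#' @export
screen_compounds <- function(records, config = screen_config()) {
  records <- validate_compound_table(records)
  if (!nrow(records)) return(records)
  keep <- if (config$inclusive) {
    records$ob >= config$ob_min & records$dl >= config$dl_min
  } else {
    records$ob > config$ob_min & records$dl > config$dl_min
  }
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse cross-herb repeats of the same compound
#'
#' A compound listed under several herbs appears once per herb in a
#' herb-expanded table. Deduplication keeps one representative per `mol_id`
#' (the first occurrence), merges the herb memberships onto it as a
#' semicolon-joined `herbs` column, and counts every listing beyond the
#' first as one removed duplicate, so
#' `nrow(unique) + n_removed == n input listings`.
#'
#' If the same `mol_id` carries conflicting OB/DL values across listings, a
#' warning is raised and the first occurrence wins.
#'
#' @param records a herb-expanded compound table.
#' @param sep separator used to join herb memberships (default `";"`).
#' @return A list with `unique` (one row per mol_id, with a `herbs` column)
#'   and `n_removed` (integer count of collapsed duplicate listings).
#' @export
dedupe_compounds <- function(records, sep = ";") {
  records <- validate_compound_table(records)
  if (!nrow(records)) {
    empty <- records[0, c("mol_id", "name", "ob", "dl", "n_targets")]
    empty$herbs <- character(0L)
    return(list(unique = empty, n_removed = 0L))
  }
  first <- !duplicated(records$mol_id)
  uniq <- as.data.frame(records)[first, c("mol_id", "name", "ob", "dl", "n_targets")]
  conflicts <- vapply(split(records[, c("ob", "dl")], records$mol_id), function(d) {
    nrow(unique(d)) > 1L
  }, logical(1L))
  if (any(conflicts)) {
    warning("conflicting ob/dl for mol_id(s) ",
            paste(names(conflicts)[conflicts], collapse = ", "),
            "; keeping first occurrence")
  }
  herb_lists <- lapply(split(records$herb, records$mol_id), unique)
  uniq$herbs <- vapply(herb_lists[uniq$mol_id], paste, character(1L), collapse = sep)
  uniq$n_herbs <- lengths(herb_lists[uniq$mol_id])
  rownames(uniq) <- NULL
  list(unique = uniq, n_removed = nrow(records) - nrow(uniq))
}

#' Per-herb screening summary
#'
#' Builds the per-herb summary table: total compounds catalogued, compounds
#' passing the OB/DL screen, and size of the union of predicted targets over
#' that herb's screened compounds. Herbs with zero surviving compounds are
#' reported as explicit zero rows, never dropped.
#'
#' @param all_records the full (pre-screen) compound table.
#' @param screened_records the output of [screen_compounds()].
#' @param target_map optional named list mapping mol_id to target genes;
#'   when `NULL`, `n_targets` is reported as `NA`.
#' @return A `data.frame` with columns `herb`, `n_compounds`, `n_bioactive`,
#'   `n_targets`, one row per herb present in `all_records`.
#' @export
summarize_by_herb <- function(all_records, screened_records, target_map = NULL) {
  all_records <- validate_compound_table(all_records)
  screened_records <- validate_compound_table(screened_records)
  herbs <- unique(all_records$herb)
  if (!length(herbs)) {
    return(data.frame(herb = character(0L), n_compounds = integer(0L),
                      n_bioactive = integer(0L), n_targets = integer(0L)))
  }
  rows <- lapply(herbs, function(h) {
    scr <- screened_records[screened_records$herb == h, , drop = FALSE]
    nt <- if (is.null(target_map)) NA_integer_ else {
      length(unique(unlist(target_map[unique(scr$mol_id)], use.names = FALSE)))
    }
    data.frame(herb = h,
               n_compounds = sum(all_records$herb == h),
               n_bioactive = nrow(scr),
               n_targets = nt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
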