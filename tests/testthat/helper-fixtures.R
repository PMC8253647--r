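# in-code fixture builders shared across test files

make_compound_df <- function(mol_id, ob, dl, herb, name = mol_id, n_targets = NA) {
  data.frame(mol_id = mol_id, name = rep_len(name, length(mol_id)),
             ob = rep_len(ob, length(mol_id)), dl = rep_len(dl, length(mol_id)),
             herb = rep_len(herb, length(mol_id)),
             n_targets = rep_len(n_targets, length(mol_id)),
             stringsAsFactors = FALSE)
}

write_tsv_tmp <- function(df, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = envir)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random compound table used by property-style tests
random_compound_df <- function(n, seed) {
  set.seed(seed)
  make_compound_df(
    mol_id = sprintf("MOLR%04d", seq_len(n)),
    ob = round(runif(n, 0, 100), 2),
    dl = round(runif(n, 0, 1), 3),
    herb = sample(sprintf("Herb%d", 1:5), n, replace = TRUE)
  )
}

# deterministic graph with exactly n nodes and m edges (first m pairs)
fixed_gnm_edges <- function(n, m, labels = sprintf("N%02d", seq_len(n))) {
  pairs <- utils::combn(labels, 2L)
  stopifnot(m <= ncol(pairs))
  pairs[, seq_len(m), drop = FALSE]
}
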