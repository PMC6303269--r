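# In-code fixtures shared across test files. No data files: everything is
# generated programmatically under fixed seeds.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT <- c("A", "C", "G", "T")

rand_seq <- function(L, alphabet = AA) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# an alignment drawn from a small pool with per-residue mutations, so
# duplicate and near-duplicate patterns occur (as in real catalogues)
rand_aln_strings <- function(n, L = 47, pool = 6, mut = 0.02) {
  base <- replicate(pool, rand_seq(L))
  out <- vapply(seq_len(n), function(i) {
    ch <- strsplit(base[sample.int(pool, 1)], "", fixed = TRUE)[[1]]
    hit <- which(runif(L) < mut)
    for (j in hit) ch[j] <- sample(setdiff(AA, ch[j]), 1)
    paste(ch, collapse = "")
  }, character(1))
  names(out) <- sprintf("s%03d", seq_len(n))
  out
}

# naive quadratic deduplicator: first-occurrence ids by all-pairs compare
brute_pattern_ids <- function(strings) {
  ids <- integer(length(strings))
  reps <- character(0)
  for (i in seq_along(strings)) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (identical(reps[k], strings[[i]])) { hit <- k; break }
    }
    if (hit == 0L) { reps <- c(reps, strings[[i]]); hit <- length(reps) }
    ids[i] <- hit
  }
  ids
}

# write a FASTA file from a named character vector, plain text
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}

# partition labels as a canonical set-of-sets signature (for comparing
# clusterings up to relabelling)
partition_signature <- function(labels, ids = names(labels)) {
  groups <- split(ids, labels)
  groups <- lapply(groups, sort)
  sort(unname(vapply(groups, paste, character(1), collapse = "|")))
}
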