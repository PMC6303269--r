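# Reading, validating and writing the region alignment and its tables.

normalize_aa <- function(x) {
  x <- toupper(x)
  chartr_map <- c(AA20, "-", "X")
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    ch[!(ch %in% chartr_map)] <- "X"
    paste(ch, collapse = "")
  }, character(1))
}

normalize_nt <- function(x) {
  x <- toupper(x)
  keep <- c(NT4, "-", "N")
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    ch[!(ch %in% keep)] <- "N"
    paste(ch, collapse = "")
  }, character(1))
}

#' Construct a region alignment from character vectors
#'
#' `region_alignment()` is the in-memory constructor behind
#' [read_region_alignment()]; it validates the invariants every downstream
#' stage relies on: equal-length amino acid rows, unique sample ids, and
#' (when present) nucleotide companions of length `3 * region_length + 2`
#' (two untranslated leading bases, then one codon per aligned column).
#'
#' @param aa Character vector of aligned amino acid sequences (gaps `-`
#'   allowed; non-standard residues are mapped to `X`). Names, if set, are
#'   used as sample ids.
#' @param sample_id Character vector of unique sample ids.
#' @param group_label Character vector of organismal group labels (recycled;
#'   default `"unknown"`).
#' @param nt Optional character vector of aligned nucleotide sequences
#'   (characters outside `A,C,G,T,-` are mapped to `N`), or `NULL`.
#' @return An object of class `region_alignment`: a list with elements
#'   `records` (data frame with columns `sample_id`, `group_label`, `aa`,
#'   `nt`) and `region_length`.
#' @export
#' @examples
#' aln <- region_alignment(c(s1 = "GAGVVG", s2 = "GAGVIG"))
#' aln$region_length
region_alignment <- function(aa, sample_id = names(aa),
                             group_label = "unknown", nt = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sprintf("seq%d", seq_along(aa))
  }
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  aa <- normalize_aa(unname(aa))
  lens <- nchar(aa)
  if (length(unique(lens)) > 1L) {
    bad <- sample_id[lens != lens[1L]]
    stop("alignment rows differ in length; offending record(s): ",
         paste(bad, collapse = ", "))
  }
  region_length <- lens[1L]
  if (!is.null(nt)) {
    nt <- normalize_nt(unname(nt))
    expected_nt <- 3L * region_length + 2L
    ok <- is.na(nt) | nchar(nt) == expected_nt
    if (!all(ok)) {
      stop("nucleotide sequence length must be ", expected_nt,
           " (3 x region length + 2); offending record(s): ",
           paste(sample_id[!ok], collapse = ", "))
    }
  } else {
    nt <- rep(NA_character_, length(aa))
  }
  records <- data.frame(
    sample_id = sample_id,
    group_label = rep_len(as.character(group_label), length(aa)),
    aa = aa,
    nt = nt,
    stringsAsFactors = FALSE
  )
  structure(list(records = records, region_length = region_length),
            class = "region_alignment")
}

#' @export
print.region_alignment <- function(x, ...) {
  cat("Region alignment: ", nrow(x$records), " records x ",
      x$region_length, " columns\n", sep = "")
  cat("  nucleotide companions: ", sum(!is.na(x$records$nt)), "\n", sep = "")
  grp <- table(x$records$group_label)
  cat("  groups: ",
      paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

read_fasta_strings <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  stats::setNames(as.character(set), ids)
}

#' Read a gapped region alignment from FASTA
#'
#' Reads the aligned protein FASTA (and, optionally, the companion aligned
#' nucleotide FASTA) of the conserved FAD-binding region. Sequences are
#' upper-cased; protein characters outside the 20 standard residues, `-`
#' and `X` are mapped to `X`; nucleotide characters outside `A,C,G,T,-`
#' are mapped to `N`. Nucleotide records are matched to protein records by
#' identical FASTA id (the description after the first whitespace is
#' ignored). Input record order is preserved.
#'
#' @param protein_fasta Path to the aligned protein FASTA.
#' @param nt_fasta Optional path to the aligned nucleotide FASTA.
#' @param expected_aa_length Expected number of alignment columns
#'   (default 47, the conserved FAD-binding region).
#' @return A [region_alignment()] object.
#' @export
read_region_alignment <- function(protein_fasta, nt_fasta = NULL,
                                  expected_aa_length = 47L) {
  aa <- read_fasta_strings(protein_fasta)
  if (anyDuplicated(names(aa))) {
    stop("duplicate FASTA id(s) in ", protein_fasta, ": ",
         paste(unique(names(aa)[duplicated(names(aa))]), collapse = ", "))
  }
  bad <- names(aa)[nchar(aa) != expected_aa_length]
  if (length(bad)) {
    stop("sequence length != expected ", expected_aa_length,
         " for record(s): ", paste(bad, collapse = ", "))
  }
  nt <- NULL
  if (!is.null(nt_fasta)) {
    nts <- read_fasta_strings(nt_fasta)
    orphan <- setdiff(names(nts), names(aa))
    if (length(orphan)) {
      stop("nucleotide record(s) with no protein counterpart: ",
           paste(orphan, collapse = ", "))
    }
    nt <- unname(nts[match(names(aa), names(nts))])
  }
  region_alignment(aa, sample_id = names(aa), nt = nt)
}

#' Write a region alignment to FASTA
#'
#' @param aln A [region_alignment()] object.
#' @param protein_fasta Output path for the protein FASTA.
#' @param nt_fasta Optional output path for the nucleotide FASTA (records
#'   lacking a nucleotide sequence are omitted from it).
#' @return Invisibly, the vector of paths written.
#' @export
write_region_alignment <- function(aln, protein_fasta, nt_fasta = NULL) {
  stopifnot(inherits(aln, "region_alignment"))
  rec <- aln$records
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(rec$aa, rec$sample_id)),
    protein_fasta)
  paths <- protein_fasta
  if (!is.null(nt_fasta)) {
    keep <- !is.na(rec$nt)
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(stats::setNames(rec$nt[keep],
                                             rec$sample_id[keep])),
      nt_fasta)
    paths <- c(paths, nt_fasta)
  }
  invisible(paths)
}

#' Attach sample metadata from a TSV file
#'
#' The TSV must contain columns `sample_id` and `group_label`. Records
#' absent from the TSV keep/get the label `"unknown"` (with a warning);
#' TSV rows naming unknown samples are ignored with a warning.
#'
#' @param aln A [region_alignment()] object.
#' @param tsv Path to a tab-separated metadata file with a header row.
#' @return The alignment with `group_label` filled in.
#' @export
attach_metadata <- function(aln, tsv) {
  stopifnot(inherits(aln, "region_alignment"))
  meta <- read.delim(tsv, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = "character")
  if (!all(c("sample_id", "group_label") %in% names(meta))) {
    stop("metadata TSV must have columns 'sample_id' and 'group_label'")
  }
  ghost <- setdiff(meta$sample_id, aln$records$sample_id)
  if (length(ghost)) {
    warning("metadata row(s) for unknown sample id(s): ",
            paste(ghost, collapse = ", "))
  }
  idx <- match(aln$records$sample_id, meta$sample_id)
  missing <- aln$records$sample_id[is.na(idx)]
  if (length(missing)) {
    warning("no metadata for record(s), labelled 'unknown': ",
            paste(missing, collapse = ", "))
  }
  aln$records$group_label <-
    ifelse(is.na(idx), "unknown", meta$group_label[idx])
  aln
}

#' Write pattern catalogue and five-digit code tables
#'
#' Serializes a [catalog_patterns()] result as one TSV per scope (columns
#' `pattern_id`, `pattern_string`, `n_samples`, `member_ids`,
#' `member_groups`; rows ordered by `pattern_id`) plus one TSV of
#' per-sample five-digit codes.
#'
#' @param catalog A `pattern_catalog`.
#' @param codes The five-digit code matrix from [encode_five_digit()]
#'   (computed from `catalog` when `NULL`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_tables <- function(catalog, codes = NULL, out_dir = ".") {
  stopifnot(inherits(catalog, "pattern_catalog"))
  if (is.null(codes)) codes <- encode_five_digit(catalog)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (scope in names(catalog$scopes)) {
    sc <- catalog$scopes[[scope]]
    tab <- data.frame(
      pattern_id = sc$patterns$pattern_id,
      pattern_string = sc$patterns$pattern,
      n_samples = sc$patterns$n_samples,
      member_ids = vapply(sc$members, paste, character(1), collapse = ","),
      member_groups = vapply(sc$groups, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE
    )
    p <- file.path(out_dir, paste0("patterns_", gsub("[^A-Za-z0-9]+", "_",
                                                     scope), ".tsv"))
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[paste0("patterns_", scope)] <- p
  }
  code_tab <- data.frame(sample_id = rownames(codes),
                         as.data.frame(codes),
                         full_pattern_id =
                           catalog$assignments[rownames(codes), "full"],
                         stringsAsFactors = FALSE)
  p <- file.path(out_dir, "five_digit_codes.tsv")
  write.table(code_tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["five_digit_codes"] <- p
  invisible(paths)
}

#' Read back a pattern table written by [write_tables()]
#'
#' @param path Path to a `patterns_<scope>.tsv` file.
#' @return Data frame with columns `pattern_id`, `pattern_string`,
#'   `n_samples`, `member_ids`, `member_groups`.
#' @export
read_pattern_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(pattern_id = "integer",
                            pattern_string = "character",
                            n_samples = "integer",
                            member_ids = "character",
                            member_groups = "character"))
}
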