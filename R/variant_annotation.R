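# Nucleotide-vs-reference substitution detection and silent/missense
# classification under the region's reading frame.

#' Reading frame of the amplified region
#'
#' The amplicon starts mid-codon: its first `untranslated_prefix`
#' nucleotides (2 by default) complete an upstream codon and are excluded
#' from translation, so codon `i` spans nucleotide positions
#' `3i .. 3i + 2` (1-based) under the default. For the default 143-nt
#' region this yields 141 translated nucleotides = 47 codons, matching the
#' 47 alignment columns.
#'
#' @param untranslated_prefix Number of leading untranslated nucleotides
#'   (non-negative integer, default 2).
#' @return An object of class `reading_frame`.
#' @export
#' @examples
#' reading_frame()          # the region default
#' reading_frame(0)         # a plain in-frame sequence
reading_frame <- function(untranslated_prefix = 2L) {
  untranslated_prefix <- as.integer(untranslated_prefix)
  stopifnot(length(untranslated_prefix) == 1L, untranslated_prefix >= 0L)
  structure(list(untranslated_prefix = untranslated_prefix),
            class = "reading_frame")
}

#' @export
print.reading_frame <- function(x, ...) {
  cat("Reading frame: untranslated prefix of", x$untranslated_prefix,
      "nt; codon i spans nt", x$untranslated_prefix + 1, "+ 3(i-1) ..",
      x$untranslated_prefix, "+ 3i\n")
  invisible(x)
}

#' Map a nucleotide position to its codon and within-codon offset
#'
#' Under the default frame (prefix 2), nucleotide position 48 lies in codon
#' 16 at codon position 1, and position 88 in codon 29 at codon position 2
#' -- the frame under which the region's paired nucleotide/protein variant
#' positions are mutually consistent.
#'
#' @param nt_position 1-based nucleotide position(s) within the region.
#' @param frame A [reading_frame()].
#' @param region_length Optional region length in nt for upper-bound
#'   validation.
#' @return Data frame with columns `nt_position`, `aa_position` (1-based
#'   codon index) and `codon_sub_position` (1, 2 or 3).
#' @seealso [aa_to_nt_position()] for the exact inverse.
#' @export
#' @examples
#' map_nt_to_aa(48)   # codon 16, first base
#' map_nt_to_aa(88)   # codon 29, second base
map_nt_to_aa <- function(nt_position, frame = reading_frame(),
                         region_length = NULL) {
  stopifnot(inherits(frame, "reading_frame"))
  nt_position <- as.integer(nt_position)
  p <- frame$untranslated_prefix
  if (any(nt_position <= p)) {
    stop("nt position(s) ",
         paste(nt_position[nt_position <= p], collapse = ", "),
         " fall in the untranslated ", p, "-nt prefix")
  }
  if (!is.null(region_length) && any(nt_position > region_length)) {
    stop("nt position(s) out of range (> ", region_length, ")")
  }
  off <- nt_position - p - 1L
  data.frame(nt_position = nt_position,
             aa_position = off %/% 3L + 1L,
             codon_sub_position = off %% 3L + 1L)
}

#' Map a codon position back to its nucleotide position
#'
#' Exact inverse of [map_nt_to_aa()] over the translated range.
#'
#' @param aa_position 1-based codon index.
#' @param codon_sub_position Position within the codon (1, 2 or 3).
#' @param frame A [reading_frame()].
#' @return Integer vector of 1-based nucleotide positions.
#' @export
aa_to_nt_position <- function(aa_position, codon_sub_position = 1L,
                              frame = reading_frame()) {
  stopifnot(inherits(frame, "reading_frame"),
            all(codon_sub_position %in% 1:3), all(aa_position >= 1L))
  frame$untranslated_prefix + 3L * (as.integer(aa_position) - 1L) +
    as.integer(codon_sub_position)
}

# Translate one codon string under the standard genetic code.
# "---" renders "-", any other codon containing a gap or an N renders "X".
translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  bad <- is.na(aa)
  if (any(bad)) aa[bad] <- ifelse(codons[bad] == "---", "-", "X")
  aa
}

#' Translate a region nucleotide sequence
#'
#' Translates codon-by-codon under the standard genetic code after
#' discarding the untranslated prefix. Stop codons render `*`; codons
#' containing `N` render `X`; all-gap codons (`---`, as produced when gaps
#' are carried through back-translation) render `-`.
#'
#' @param nt_sequence A single nucleotide string of length
#'   `3k + untranslated_prefix`.
#' @param frame A [reading_frame()].
#' @return Amino acid string of length `k`.
#' @export
#' @examples
#' translate_region("NNTAT", reading_frame(2))  # "Y"
translate_region <- function(nt_sequence, frame = reading_frame()) {
  stopifnot(inherits(frame, "reading_frame"), length(nt_sequence) == 1L)
  nt_sequence <- toupper(nt_sequence)
  p <- frame$untranslated_prefix
  body <- substring(nt_sequence, p + 1L, nchar(nt_sequence))
  if (nchar(body) %% 3L != 0L) {
    stop("sequence length ", nchar(nt_sequence),
         " is not prefix (", p, ") + a whole number of codons")
  }
  if (nchar(body) == 0L) return("")
  starts <- seq(1L, nchar(body), by = 3L)
  codons <- substring(body, starts, starts + 2L)
  paste(translate_codons(codons), collapse = "")
}

#' Detect and classify nucleotide substitutions against a reference
#'
#' Compares every record of the aligned nucleotide companion to the
#' reference record, column by column. A substitution is called where the
#' two bases differ and neither is a gap; positions in the untranslated
#' prefix and gap-containing positions are skipped (with a note). The
#' effect is computed by substituting the alternate base into the
#' *reference* codon and translating both: `silent` if the amino acid is
#' unchanged, `nonsense` if the mutated codon is a stop, else `missense`.
#'
#' @param aln A [region_alignment()] whose compared records carry
#'   nucleotide sequences.
#' @param reference_id Sample id of the reference record (default: the
#'   first record, the natural choice when the first record is the
#'   reference amplicon the primers were designed on).
#' @param frame A [reading_frame()].
#' @return Data frame with one row per (sample, position) substitution:
#'   `sample_id`, `nt_position`, `ref_base`, `alt_base`, `aa_position`,
#'   `codon_sub_position`, `ref_aa`, `alt_aa`, `effect`.
#' @export
find_and_classify_substitutions <- function(aln, reference_id = NULL,
                                            frame = reading_frame()) {
  stopifnot(inherits(aln, "region_alignment"))
  rec <- aln$records
  if (any(is.na(rec$nt))) {
    stop("all records must carry nucleotide sequences; missing for: ",
         paste(rec$sample_id[is.na(rec$nt)], collapse = ", "))
  }
  reference_id <- reference_id %||% rec$sample_id[1L]
  ri <- match(reference_id, rec$sample_id)
  if (is.na(ri)) stop("reference id '", reference_id, "' not found")
  p <- frame$untranslated_prefix
  ref <- strsplit(rec$nt[ri], "", fixed = TRUE)[[1]]
  nt_len <- length(ref)
  out <- list()
  n_skipped_gap <- 0L
  n_skipped_prefix <- 0L
  for (si in seq_len(nrow(rec))[-ri]) {
    smp <- strsplit(rec$nt[si], "", fixed = TRUE)[[1]]
    diff_pos <- which(smp != ref)
    for (pos in diff_pos) {
      if (smp[pos] == "-" || ref[pos] == "-") {
        n_skipped_gap <- n_skipped_gap + 1L
        next
      }
      if (pos <= p) {
        n_skipped_prefix <- n_skipped_prefix + 1L
        next
      }
      m <- map_nt_to_aa(pos, frame, region_length = nt_len)
      codon_start <- aa_to_nt_position(m$aa_position, 1L, frame)
      ref_codon <- ref[codon_start:(codon_start + 2L)]
      alt_codon <- ref_codon
      alt_codon[m$codon_sub_position] <- smp[pos]
      ref_aa <- translate_codons(paste(ref_codon, collapse = ""))
      alt_aa <- translate_codons(paste(alt_codon, collapse = ""))
      effect <- if (identical(ref_aa, alt_aa)) "silent"
                else if (identical(alt_aa, "*")) "nonsense"
                else "missense"
      out[[length(out) + 1L]] <- data.frame(
        sample_id = rec$sample_id[si], nt_position = pos,
        ref_base = ref[pos], alt_base = smp[pos],
        aa_position = m$aa_position,
        codon_sub_position = m$codon_sub_position,
        ref_aa = ref_aa, alt_aa = alt_aa, effect = effect,
        stringsAsFactors = FALSE)
    }
  }
  if (n_skipped_gap > 0L) {
    message(n_skipped_gap,
            " gap-containing position(s) skipped (indels are not called)")
  }
  if (n_skipped_prefix > 0L) {
    message(n_skipped_prefix,
            " substitution(s) in the untranslated prefix skipped")
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(0), nt_position = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      aa_position = integer(0),
                      codon_sub_position = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      effect = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
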