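# Sub-region partitioning, pattern cataloguing, five-digit encoding,
# property profiling and consensus-motif derivation.

#' Motif-anchored sub-region scheme
#'
#' An ordered set of named, contiguous, non-overlapping 1-based inclusive
#' intervals covering the whole region. The default partitions the 47-aa
#' FAD-binding region around its two conserved motifs: bFAD 1-5 (before
#' the FAD-binding motif), FAD 6-11 (the GxGxxG motif), FAD-GG 12-32
#' (between the motifs), GG 33-40 (the GG motif) and aGG 41-47 (after it).
#'
#' @param name Character vector of sub-region names.
#' @param start,end Integer vectors of 1-based inclusive bounds.
#' @return Object of class `subregion_scheme` (a data frame with columns
#'   `name`, `start`, `end`, `length`).
#' @export
#' @examples
#' default_subregion_scheme()
subregion_scheme <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(name) == length(start), length(start) == length(end),
            all(end >= start))
  if (anyDuplicated(name)) stop("sub-region names must be unique")
  if (start[1L] != 1L || any(start[-1L] != end[-length(end)] + 1L)) {
    stop("sub-regions must be contiguous and start at column 1")
  }
  structure(data.frame(name = as.character(name), start = start, end = end,
                       length = end - start + 1L, stringsAsFactors = FALSE),
            class = c("subregion_scheme", "data.frame"))
}

#' @rdname subregion_scheme
#' @export
default_subregion_scheme <- function() {
  subregion_scheme(c("bFAD", "FAD", "FAD-GG", "GG", "aGG"),
                   start = c(1L, 6L, 12L, 33L, 41L),
                   end = c(5L, 11L, 32L, 40L, 47L))
}

#' Read a sub-region scheme from a TSV file
#'
#' @param path TSV with header columns `name`, `start`, `end`.
#' @return A [subregion_scheme()].
#' @export
read_subregion_scheme <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  subregion_scheme(tab$name, tab$start, tab$end)
}

scheme_region_length <- function(scheme) scheme$end[nrow(scheme)]

check_scheme_covers <- function(scheme, region_length) {
  stopifnot(inherits(scheme, "subregion_scheme"))
  if (scheme_region_length(scheme) != region_length) {
    stop("scheme covers 1..", scheme_region_length(scheme),
         " but the region has ", region_length, " columns")
  }
}

aln_sequences <- function(x) {
  if (inherits(x, "region_alignment")) {
    stats::setNames(x$records$aa, x$records$sample_id)
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("seq%d", seq_along(x))
    x
  } else {
    stop("expected a region_alignment or a character vector of sequences")
  }
}

#' Split aligned sequences into sub-region strings
#'
#' The concatenation of a sequence's sub-region strings in scheme order
#' equals the full sequence.
#'
#' @param x A [region_alignment()] or named character vector of
#'   equal-length aligned sequences.
#' @param scheme A [subregion_scheme()] covering the region.
#' @return Character matrix: one row per sequence, one column per
#'   sub-region.
#' @export
extract_subregions <- function(x, scheme = default_subregion_scheme()) {
  seqs <- aln_sequences(x)
  check_scheme_covers(scheme, unique(nchar(seqs)))
  out <- vapply(seq_len(nrow(scheme)), function(i) {
    substring(seqs, scheme$start[i], scheme$end[i])
  }, character(length(seqs)))
  out <- matrix(out, nrow = length(seqs),
                dimnames = list(names(seqs), scheme$name))
  out
}

#' Catalogue unique patterns per scope
#'
#' Deduplicates the full-region sequence and each sub-region string across
#' samples. Pattern ids are dense, 1-based and assigned by first occurrence
#' in input order, making the catalogue deterministic and stable under
#' re-runs. Gaps (`-`) and `X` are literal characters for pattern identity,
#' so a bacterial-style deletion inside FAD-GG forms its own pattern.
#'
#' @param aln A [region_alignment()].
#' @param scheme A [subregion_scheme()].
#' @return Object of class `pattern_catalog`: list with `scheme`,
#'   `sample_id`, `group_label`, `assignments` (integer matrix sample x
#'   scope of pattern ids; scopes are `"full"` plus the sub-region names)
#'   and `scopes` (per scope: `patterns` data frame with `pattern_id`,
#'   `pattern`, `n_samples`; `members` and `groups` lists indexed by
#'   pattern id).
#' @export
catalog_patterns <- function(aln, scheme = default_subregion_scheme()) {
  stopifnot(inherits(aln, "region_alignment"))
  check_scheme_covers(scheme, aln$region_length)
  seqs <- aln_sequences(aln)
  sub <- extract_subregions(aln, scheme)
  strings <- cbind(full = unname(seqs), sub)
  rownames(strings) <- names(seqs)
  scopes <- list()
  assignments <- matrix(0L, nrow = length(seqs), ncol = ncol(strings),
                        dimnames = list(names(seqs), colnames(strings)))
  for (scope in colnames(strings)) {
    s <- strings[, scope]
    u <- unique(unname(s))
    id <- match(s, u)
    assignments[, scope] <- id
    f <- factor(id, levels = seq_along(u))
    scopes[[scope]] <- list(
      patterns = data.frame(pattern_id = seq_along(u), pattern = u,
                            n_samples = as.integer(table(f)),
                            stringsAsFactors = FALSE),
      members = split(names(seqs), f),
      groups = split(aln$records$group_label, f)
    )
  }
  structure(list(scheme = scheme, sample_id = names(seqs),
                 group_label = stats::setNames(aln$records$group_label,
                                               names(seqs)),
                 assignments = assignments, scopes = scopes),
            class = "pattern_catalog")
}

#' @export
print.pattern_catalog <- function(x, ...) {
  cat("Pattern catalogue over", length(x$sample_id), "samples\n")
  cnt <- pattern_counts(x)
  for (s in names(cnt)) cat(sprintf("  %-8s %d patterns\n", s, cnt[s]))
  invisible(x)
}

#' Number of unique patterns per scope
#'
#' @param catalog A `pattern_catalog`.
#' @return Named integer vector (scope -> count), scope `"full"` first.
#' @export
pattern_counts <- function(catalog) {
  stopifnot(inherits(catalog, "pattern_catalog"))
  vapply(catalog$scopes, function(s) nrow(s$patterns), integer(1))
}

#' Encode samples (or full patterns) as five-digit codes
#'
#' The five-digit code of a sample is the tuple of its sub-region pattern
#' ids in scheme order. Two samples have equal codes exactly when their
#' full-region sequences are identical. With `by = "pattern"` one code per
#' distinct full-region pattern is returned (rows named by full-pattern
#' id), the representation clustered in the region-level dendrogram.
#'
#' @param catalog A `pattern_catalog`.
#' @param by `"sample"` (default) or `"pattern"`.
#' @return Integer matrix (rows: samples or full patterns; columns: the
#'   sub-regions in scheme order).
#' @export
encode_five_digit <- function(catalog, by = c("sample", "pattern")) {
  stopifnot(inherits(catalog, "pattern_catalog"))
  by <- match.arg(by)
  sub_scopes <- catalog$scheme$name
  codes <- catalog$assignments[, sub_scopes, drop = FALSE]
  if (by == "sample") return(codes)
  full_id <- catalog$assignments[, "full"]
  first <- match(seq_len(max(full_id)), full_id)
  out <- codes[first, , drop = FALSE]
  rownames(out) <- as.character(seq_len(max(full_id)))
  out
}

#' Sub-region strings of the distinct full-region patterns
#'
#' @param catalog A `pattern_catalog`.
#' @param by `"pattern"` (default) or `"sample"`.
#' @return Character matrix parallel to [encode_five_digit()].
#' @export
subregion_strings <- function(catalog, by = c("pattern", "sample")) {
  stopifnot(inherits(catalog, "pattern_catalog"))
  by <- match.arg(by)
  full <- catalog$scopes$full$patterns$pattern
  if (by == "sample") {
    full <- full[catalog$assignments[, "full"]]
    names(full) <- catalog$sample_id
  } else {
    names(full) <- as.character(seq_along(full))
  }
  extract_subregions(full, catalog$scheme)
}

#' Residue and property frequency profile of a pattern set
#'
#' Column-wise counts and frequencies of residues and of the five
#' biochemical property classes (see [amino_acid_classes()]) across a set
#' of equal-length pattern strings. Frequencies are computed across the
#' supplied patterns -- pass the *unique* patterns of a scope to profile
#' pattern diversity rather than sample abundance. Gaps and `X` are
#' excluded from all denominators.
#'
#' @param patterns Character vector of equal-length pattern strings.
#' @return Object of class `property_profile`: list with `residue_counts`
#'   (20 x L), `residue_freq`, `class_counts` (5 x L), `class_freq`,
#'   `n_obs` (non-gap, non-X observations per column) and `class_map`.
#' @export
#' @examples
#' pr <- compute_property_profile(c("LLK", "LVK", "IVR"))
#' pr$class_freq[, 3]   # column 3 is all positively charged
compute_property_profile <- function(patterns) {
  patterns <- aln_sequences(patterns)
  L <- unique(nchar(patterns))
  if (length(L) != 1L) stop("pattern strings must have equal length")
  mat <- do.call(rbind, strsplit(unname(patterns), "", fixed = TRUE))
  cls_of <- property_class_of()
  residue_counts <- vapply(seq_len(L), function(j) {
    table(factor(mat[, j], levels = AA20))
  }, integer(length(AA20)))
  dimnames(residue_counts) <- list(AA20, seq_len(L))
  n_obs <- colSums(residue_counts)
  class_counts <- vapply(seq_len(L), function(j) {
    obs <- mat[, j]
    obs <- obs[obs %in% AA20]
    table(factor(cls_of[obs], levels = names(PROPERTY_CLASSES)))
  }, integer(length(PROPERTY_CLASSES)))
  dimnames(class_counts) <- list(names(PROPERTY_CLASSES), seq_len(L))
  safe_div <- function(m, d) sweep(m, 2L, pmax(d, 1L), "/")
  structure(list(residue_counts = residue_counts,
                 residue_freq = safe_div(residue_counts, n_obs),
                 class_counts = class_counts,
                 class_freq = safe_div(class_counts, n_obs),
                 n_obs = n_obs, class_map = cls_of),
            class = "property_profile")
}

#' Derive a consensus motif from a pattern set
#'
#' Position by position over the included patterns: a position is rendered
#' as a *literal* residue when a single residue reaches
#' `literal_threshold` (and no included pattern has a gap there); failing
#' that, as a bracketed *class* token (the sorted set of observed residues)
#' when a single property class reaches `class_threshold`; otherwise as the
#' wildcard `x`. Outlier patterns (e.g. divergent bacterial ones) are
#' removed via `exclude` rather than by silently lowering thresholds.
#'
#' @param patterns Character vector (optionally named) of equal-length
#'   pattern strings.
#' @param literal_threshold,class_threshold Fractions in (0, 1]; defaults 1.
#' @param exclude Optional names or indices of patterns to drop before
#'   computing.
#' @return Object of class `consensus_motif`: data frame with columns
#'   `position`, `type` (`literal`/`class`/`wildcard`), `token` and
#'   `residues`. Render with [render_motif()] or `format()`.
#' @export
#' @examples
#' m <- derive_consensus(c("GAGVVG", "GSGALG", "GTGYIG"))
#' render_motif(m)  # "G-x-G-x(2)-G"
derive_consensus <- function(patterns, literal_threshold = 1,
                             class_threshold = 1, exclude = NULL) {
  stopifnot(literal_threshold > 0, literal_threshold <= 1,
            class_threshold > 0, class_threshold <= 1)
  patterns <- aln_sequences(patterns)
  if (!is.null(exclude)) {
    patterns <- if (is.character(exclude)) {
      patterns[!(names(patterns) %in% exclude)]
    } else {
      patterns[-as.integer(exclude)]
    }
  }
  if (!length(patterns)) stop("no patterns left to derive a consensus from")
  L <- unique(nchar(patterns))
  if (length(L) != 1L) stop("pattern strings must have equal length")
  mat <- do.call(rbind, strsplit(unname(patterns), "", fixed = TRUE))
  cls_of <- property_class_of()
  rows <- lapply(seq_len(L), function(j) {
    col <- mat[, j]
    has_gap <- any(col == "-")
    obs <- col[col %in% AA20]
    if (!length(obs)) {
      return(data.frame(position = j, type = "wildcard", token = "x",
                        residues = "", stringsAsFactors = FALSE))
    }
    freq <- table(obs) / length(obs)
    if (!has_gap && max(freq) >= literal_threshold) {
      res <- names(freq)[which.max(freq)]
      return(data.frame(position = j, type = "literal", token = res,
                        residues = res, stringsAsFactors = FALSE))
    }
    cfreq <- tapply(rep(1, length(obs)), cls_of[obs], sum) / length(obs)
    if (max(cfreq) >= class_threshold) {
      win <- names(cfreq)[which.max(cfreq)]
      res <- sort(unique(obs[cls_of[obs] == win]))
      return(data.frame(position = j, type = "class",
                        token = paste0("[", paste(res, collapse = ""), "]"),
                        residues = paste(res, collapse = ""),
                        stringsAsFactors = FALSE))
    }
    data.frame(position = j, type = "wildcard", token = "x",
               residues = "", stringsAsFactors = FALSE)
  })
  motif <- do.call(rbind, rows)
  structure(motif, class = c("consensus_motif", "data.frame"),
            literal_threshold = literal_threshold,
            class_threshold = class_threshold,
            n_patterns = length(patterns))
}

#' Render a consensus motif as a string
#'
#' Wildcard runs of length k >= 2 collapse to `x(k)`, adjacent literal
#' residues merge into one token (e.g. `GGR`), and tokens are joined with
#' `-`: the GG-motif consensus renders `"x(2)-GGR-x(2)-T"`, or
#' `"GGR-x(2)-T"` with `trim = TRUE` (dropping flanking wildcards, the
#' conventional printed form).
#'
#' @param motif A `consensus_motif`.
#' @param trim Drop leading/trailing wildcard tokens (default `FALSE`).
#' @return A single motif string.
#' @export
render_motif <- function(motif, trim = FALSE) {
  stopifnot(inherits(motif, "consensus_motif"))
  type <- motif$type
  token <- motif$token
  if (trim) {
    keep <- which(type != "wildcard")
    if (!length(keep)) return("x")
    idx <- keep[1L]:keep[length(keep)]
    type <- type[idx]; token <- token[idx]
  }
  if (!length(type)) return("")
  run <- rle(type)
  pieces <- character(0)
  at <- 0L
  for (i in seq_along(run$lengths)) {
    n <- run$lengths[i]
    toks <- token[at + seq_len(n)]
    at <- at + n
    pieces <- c(pieces, switch(run$values[i],
      wildcard = if (n >= 2L) sprintf("x(%d)", n) else "x",
      literal = paste(toks, collapse = ""),
      class = toks))
  }
  paste(pieces, collapse = "-")
}

#' @export
format.consensus_motif <- function(x, ...) render_motif(x, ...)

#' @export
print.consensus_motif <- function(x, ...) {
  cat("Consensus motif over", attr(x, "n_patterns"), "patterns:\n  ",
      render_motif(x), "\n", sep = "")
  invisible(x)
}

#' Parse a motif string back into its position list
#'
#' Inverse of [render_motif()] (for untrimmed renderings):
#' `parse_motif(render_motif(m))` reproduces the position/type/token table
#' of `m`.
#'
#' @param string Motif string such as `"G-x-G-x(2)-G"` or
#'   `"L-x(3)-G-x(5)-[ILV]-x-E"`.
#' @return Data frame with columns `position`, `type`, `token`.
#' @export
parse_motif <- function(string) {
  stopifnot(length(string) == 1L)
  pieces <- strsplit(string, "-", fixed = TRUE)[[1]]
  rows <- list()
  for (pc in pieces) {
    if (grepl("^x(\\((\\d+)\\))?$", pc)) {
      k <- if (pc == "x") 1L else as.integer(sub("^x\\((\\d+)\\)$", "\\1", pc))
      for (i in seq_len(k)) {
        rows[[length(rows) + 1L]] <- c(type = "wildcard", token = "x")
      }
    } else if (grepl("^\\[[A-Z]+\\]$", pc)) {
      rows[[length(rows) + 1L]] <- c(type = "class", token = pc)
    } else if (grepl("^[A-Z]+$", pc)) {
      for (ch in strsplit(pc, "", fixed = TRUE)[[1]]) {
        rows[[length(rows) + 1L]] <- c(type = "literal", token = ch)
      }
    } else {
      stop("unparseable motif token: '", pc, "'")
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  out$position <- seq_len(nrow(out))
  out[, c("position", "type", "token")]
}
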