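# Secondary-structure conservation coding (0-4) and structural clustering.

#' Construct a set of secondary-structure profiles
#'
#' One string per pattern over the 3-state alphabet H (helix), E (strand),
#' C (coil) plus `-` where the protein pattern has a gap, aligned
#' column-wise to the protein alignment.
#'
#' @param x Named character vector (pattern id -> SS string).
#' @return Object of class `ss_profile` (a validated named character
#'   vector).
#' @export
ss_profile <- function(x) {
  stopifnot(is.character(x))
  if (is.null(names(x))) names(x) <- sprintf("p%d", seq_along(x))
  x <- stats::setNames(toupper(x), names(x))
  if (length(unique(nchar(x))) > 1L) {
    stop("secondary-structure strings differ in length")
  }
  bad <- grepl("[^HEC-]", x)
  if (any(bad)) {
    stop("invalid SS characters (alphabet is H/E/C/-) in: ",
         paste(names(x)[bad], collapse = ", "))
  }
  structure(x, class = "ss_profile")
}

#' @export
print.ss_profile <- function(x, ...) {
  cat("Secondary-structure profiles:", length(x), "patterns x",
      nchar(x[[1]]), "columns\n")
  invisible(x)
}

#' Read secondary-structure profiles from a FASTA-like file
#'
#' Records are FASTA entries whose id is the pattern id and whose sequence
#' is over H/E/C/-.
#'
#' @param path Input path.
#' @return An [ss_profile()] object.
#' @export
read_ss_profiles <- function(path) {
  ss_profile(read_fasta_strings(path))
}

#' Write secondary-structure profiles to a FASTA-like file
#'
#' @param profiles An [ss_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ss_profiles <- function(profiles, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(as.character(profiles),
                                           names(profiles))), path)
  invisible(path)
}

#' Score residue-wise secondary-structure conservation (0-4)
#'
#' For pattern p at column j with state s, let f be the fraction of
#' profiles sharing state s at column j (a gap counts as its own state).
#' The conservation score is `min(4, floor(5 f))`: 0 marks a residue in a
#' highly structurally variable position, 4 a residue whose local
#' structure is shared by (essentially) all patterns.
#'
#' @param profiles An [ss_profile()] (or named character vector) with at
#'   least 2 profiles.
#' @return Integer matrix (patterns x columns) of scores in 0..4, class
#'   `structural_code`.
#' @export
#' @examples
#' p <- ss_profile(c(a = "HHEE", b = "HHEE", c = "HHCC"))
#' score_structural_conservation(p)
score_structural_conservation <- function(profiles) {
  if (!inherits(profiles, "ss_profile")) profiles <- ss_profile(profiles)
  n <- length(profiles)
  if (n < 2L) stop("need at least 2 profiles to score conservation")
  mat <- do.call(rbind, strsplit(as.character(profiles), "", fixed = TRUE))
  L <- ncol(mat)
  scores <- matrix(0L, n, L, dimnames = list(names(profiles), NULL))
  for (j in seq_len(L)) {
    cnt <- table(mat[, j])
    f5 <- (5L * as.integer(cnt[mat[, j]])) %/% n  # integer floor(5 f)
    scores[, j] <- pmin(4L, f5)
  }
  structure(scores, class = c("structural_code", "matrix", "array"))
}

#' Distance between two structural conservation code vectors
#'
#' Normalized Manhattan distance: mean absolute score difference per
#' column (range 0..4). Scores are ordinal, so the magnitude of
#' disagreement matters, unlike the categorical id-Hamming distance used
#' for five-digit codes.
#'
#' @param a,b Integer vectors of equal length with entries in 0..4.
#' @return A single number in `[0, 4]`.
#' @export
structural_code_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("code vectors differ in length (", length(a), " vs ",
         length(b), ")")
  }
  sum(abs(a - b)) / length(a)
}

#' Pairwise structural distance matrix
#'
#' @param codes A `structural_code` matrix (patterns x columns).
#' @return Symmetric matrix of normalized Manhattan distances.
#' @export
structural_distance_matrix <- function(codes) {
  D <- as.matrix(dist(unclass(codes), method = "manhattan")) / ncol(codes)
  dimnames(D) <- list(rownames(codes), rownames(codes))
  D
}

#' Score, cluster and cut secondary-structure profiles in one call
#'
#' Composes [score_structural_conservation()], a normalized-Manhattan
#' distance matrix, [hierarchical_cluster()] and the nested
#' [cut_subclusters()] cut.
#'
#' @param profiles An [ss_profile()].
#' @param k Number of top-level clusters (default 2).
#' @param subk Sub-clusters for the split cluster (default 2).
#' @param linkage Linkage method (default `"average"`).
#' @param split_cluster Which top-level cluster to subdivide (default 1,
#'   the largest).
#' @return List with `codes`, `distance`, `tree`, `assignment` (the
#'   `cut_and_label()` result) and `subclusters` (the nested-cut data
#'   frame).
#' @export
simplify_and_cluster <- function(profiles, k = 2L, subk = 2L,
                                 linkage = "average", split_cluster = 1L) {
  codes <- score_structural_conservation(profiles)
  D <- structural_distance_matrix(codes)
  tree <- hierarchical_cluster(D, linkage = linkage)
  assignment <- cut_and_label(tree, k)
  subclusters <- if (subk > 1L && assignment$sizes[split_cluster] >= subk) {
    cut_subclusters(tree, k, subk, cluster = split_cluster)
  } else {
    data.frame(item = tree$labels, cluster = unname(assignment$labels),
               subcluster = as.character(unname(assignment$labels)),
               stringsAsFactors = FALSE)
  }
  list(codes = codes, distance = D, tree = tree,
       assignment = assignment, subclusters = subclusters)
}
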