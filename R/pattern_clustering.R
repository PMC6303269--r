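# Distances over five-digit codes, deterministic agglomerative clustering,
# tree cutting and Newick export.

#' Distance between two five-digit codes
#'
#' `id_hamming` counts the sub-regions whose pattern ids differ (integer
#' 0..5 for the default scheme): the codes are treated as purely
#' categorical, as in the region-level dendrogram. `residue` averages, over
#' sub-regions, the fraction of alignment columns at which the underlying
#' sub-region strings disagree (real 0..1), giving a graded distance that
#' is robust to rare substitutions spawning fresh pattern ids.
#'
#' @param code_a,code_b Integer vectors of sub-region pattern ids (equal
#'   length).
#' @param mode `"id_hamming"` (default) or `"residue"`.
#' @param strings_a,strings_b Character vectors of the underlying
#'   sub-region strings (required for `mode = "residue"`).
#' @return A single non-negative number.
#' @export
#' @examples
#' code_distance(c(1, 1, 2, 1, 1), c(1, 1, 3, 1, 1))  # 1
code_distance <- function(code_a, code_b,
                          mode = c("id_hamming", "residue"),
                          strings_a = NULL, strings_b = NULL) {
  mode <- match.arg(mode)
  if (length(code_a) != length(code_b)) {
    stop("codes differ in length (", length(code_a), " vs ",
         length(code_b), ")")
  }
  if (mode == "id_hamming") return(sum(code_a != code_b))
  if (is.null(strings_a) || is.null(strings_b)) {
    stop("residue mode needs the underlying sub-region strings")
  }
  if (length(strings_a) != length(strings_b) ||
      any(nchar(strings_a) != nchar(strings_b))) {
    stop("sub-region strings are not comparable")
  }
  mism <- mapply(function(a, b) {
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(b, "", fixed = TRUE)[[1]]
    mean(ca != cb)
  }, strings_a, strings_b)
  mean(mism)
}

#' Pairwise distance matrix over five-digit codes
#'
#' @param catalog A `pattern_catalog` (codes and strings are taken from
#'   it), or an integer code matrix for `mode = "id_hamming"`.
#' @param mode See [code_distance()].
#' @param by Cluster distinct full-region `"pattern"`s (default, as in the
#'   region-level dendrogram) or individual `"sample"`s.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = item
#'   ids.
#' @export
code_distance_matrix <- function(catalog,
                                 mode = c("id_hamming", "residue"),
                                 by = c("pattern", "sample")) {
  mode <- match.arg(mode)
  by <- match.arg(by)
  if (inherits(catalog, "pattern_catalog")) {
    codes <- encode_five_digit(catalog, by = by)
    strings <- if (mode == "residue") subregion_strings(catalog, by = by)
  } else {
    codes <- as.matrix(catalog)
    if (mode == "residue") {
      stop("residue mode needs a pattern_catalog, not a bare code matrix")
    }
  }
  n <- nrow(codes)
  if (mode == "id_hamming") {
    D <- matrix(0, n, n)
    for (r in seq_len(ncol(codes))) {
      D <- D + outer(codes[, r], codes[, r], "!=")
    }
  } else {
    scheme <- catalog$scheme
    D <- matrix(0, n, n)
    for (r in seq_len(ncol(strings))) {
      ch <- do.call(rbind, strsplit(strings[, r], "", fixed = TRUE))
      Dr <- matrix(0, n, n)
      for (j in seq_len(ncol(ch))) {
        Dr <- Dr + outer(ch[, j], ch[, j], "!=")
      }
      D <- D + Dr / ncol(ch)
    }
    D <- D / ncol(strings)
  }
  dimnames(D) <- list(rownames(codes), rownames(codes))
  D
}

validate_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (is.null(rownames(d))) {
    dimnames(d) <- list(sprintf("item%d", seq_len(nrow(d))),
                        sprintf("item%d", seq_len(nrow(d))))
  }
  d
}

#' Agglomerative hierarchical clustering with a deterministic tie rule
#'
#' Standard Lance-Williams agglomeration (average/UPGMA, complete or single
#' linkage) with one addition: when several pairs are at the minimal
#' distance, the pair whose smallest contained leaf id (item ids compared
#' in sorted order) is smallest -- then whose other smallest leaf id is
#' smallest -- merges first. Because the rule keys on item identity rather
#' than input position, the tree (not just its heights) is invariant to
#' input permutation, and identical data give byte-identical dendrograms
#' on any machine.
#'
#' @param d Symmetric distance matrix (or `dist` object) with item names.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return Object of class `linkage_tree`: list with `merge` ((n-1) x 2
#'   matrix in `hclust` convention: negative = leaf index, positive =
#'   earlier merge), `height`, `labels` and `linkage`. Convert with
#'   [as.hclust()] for plotting or `cutree()`.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete",
                                                "single")) {
  linkage <- match.arg(linkage)
  D <- validate_distance_matrix(d)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 items to cluster")
  labels <- rownames(D)
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  # leaf identity rank: position of each label in sorted label order, so
  # tie-breaking does not depend on input order
  minleaf <- match(labels, sort(labels, method = "radix"))
  node <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  diag(D) <- Inf
  for (m in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    dmin <- min(sub)
    cand <- which(sub == dmin, arr.ind = TRUE)
    ci <- act[cand[, 1L]]
    cj <- act[cand[, 2L]]
    key1 <- pmin(minleaf[ci], minleaf[cj])
    key2 <- pmax(minleaf[ci], minleaf[cj])
    pick <- order(key1, key2)[1L]
    i <- ci[pick]; j <- cj[pick]
    if (minleaf[j] < minleaf[i]) { tmp <- i; i <- j; j <- tmp }
    merge[m, ] <- c(node[i], node[j])
    height[m] <- dmin
    for (k in which(active)) {
      if (k == i || k == j) next
      D[i, k] <- switch(linkage,
        average = (size[i] * D[i, k] + size[j] * D[j, k]) /
                  (size[i] + size[j]),
        complete = max(D[i, k], D[j, k]),
        single = min(D[i, k], D[j, k]))
      D[k, i] <- D[i, k]
    }
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    node[i] <- m
  }
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage, n = n),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat("Linkage tree:", x$n, "leaves,", x$linkage, "linkage; merge heights",
      format(min(x$height), digits = 4), "..",
      format(max(x$height), digits = 4), "\n")
  invisible(x)
}

# leaf indices under each merge node (list of length n-1)
tree_members <- function(tree) {
  members <- vector("list", nrow(tree$merge))
  get <- function(code) if (code < 0L) -code else members[[code]]
  for (m in seq_len(nrow(tree$merge))) {
    members[[m]] <- c(get(tree$merge[m, 1L]), get(tree$merge[m, 2L]))
  }
  members
}

#' @export
as.hclust.linkage_tree <- function(x, ...) {
  ord <- integer(0)
  walk <- function(code) {
    if (code < 0L) {
      ord <<- c(ord, -code)
    } else {
      walk(x$merge[code, 1L])
      walk(x$merge[code, 2L])
    }
  }
  walk(nrow(x$merge))
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels,
                 method = switch(x$linkage, average = "average",
                                 complete = "complete", single = "single"),
                 call = match.call(), dist.method = "user"),
            class = "hclust")
}

#' Cut a linkage tree into k clusters
#'
#' Removes the k-1 highest merges (equivalently, applies only the first
#' n-k merges) and labels the resulting clusters 1..k by decreasing size,
#' ties broken by smallest contained leaf index.
#'
#' @param tree A `linkage_tree`.
#' @param k Number of clusters (1..n).
#' @return Object of class `cluster_assignment`: list with `labels` (named
#'   integer vector item -> cluster), `k` and `sizes`.
#' @export
cut_and_label <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- tree$n
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  members <- tree_members(tree)
  kept <- seq_len(n - k)
  used_as_child <- tree$merge[kept, , drop = FALSE]
  roots_merge <- setdiff(kept, used_as_child[used_as_child > 0L])
  roots_leaf <- setdiff(seq_len(n), -used_as_child[used_as_child < 0L])
  groups <- c(lapply(roots_merge, function(m) members[[m]]),
              as.list(roots_leaf))
  lab_rank <- match(tree$labels, sort(tree$labels, method = "radix"))
  ord <- order(-lengths(groups),
               vapply(groups, function(g) min(lab_rank[g]), numeric(1)))
  groups <- groups[ord]
  labels <- integer(n)
  for (g in seq_along(groups)) labels[groups[[g]]] <- g
  names(labels) <- tree$labels
  structure(list(labels = labels, k = k,
                 sizes = lengths(groups)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment: k =", x$k, "; sizes",
      paste(x$sizes, collapse = "/"), "\n")
  invisible(x)
}

#' Nested cut: split one cluster into sub-clusters
#'
#' After a k-cut, subdivides the chosen cluster (by default the largest)
#' into `subk` sub-clusters by removing the subk-1 highest merges internal
#' to it. Sub-cluster labels are `"<cluster>.<i>"` ordered by decreasing
#' size.
#'
#' @param tree A `linkage_tree`.
#' @param k Number of top-level clusters.
#' @param subk Number of sub-clusters for the split cluster.
#' @param cluster Label (integer) of the cluster to split; default 1 (the
#'   largest).
#' @return Data frame with columns `item`, `cluster`, `subcluster`
#'   (`subcluster` equals `cluster` for unsplit clusters).
#' @export
cut_subclusters <- function(tree, k, subk, cluster = 1L) {
  top <- cut_and_label(tree, k)
  leaf_idx <- which(top$labels == cluster)
  if (length(leaf_idx) < subk) {
    stop("cluster ", cluster, " has ", length(leaf_idx),
         " items; cannot cut into ", subk)
  }
  members <- tree_members(tree)
  internal <- which(vapply(members, function(mm) all(mm %in% leaf_idx),
                           logical(1)))
  kept <- if (subk - 1L > 0L && length(internal)) {
    internal[seq_len(max(0L, length(internal) - (subk - 1L)))]
  } else internal
  used_as_child <- tree$merge[kept, , drop = FALSE]
  roots_merge <- setdiff(kept, used_as_child[used_as_child > 0L])
  roots_merge <- roots_merge[vapply(roots_merge, function(m)
    all(members[[m]] %in% leaf_idx), logical(1))]
  roots_leaf <- setdiff(leaf_idx, -used_as_child[used_as_child < 0L])
  groups <- c(lapply(roots_merge, function(m) members[[m]]),
              as.list(roots_leaf))
  lab_rank <- match(tree$labels, sort(tree$labels, method = "radix"))
  ord <- order(-lengths(groups),
               vapply(groups, function(g) min(lab_rank[g]), numeric(1)))
  groups <- groups[ord]
  sub <- as.character(top$labels)
  for (g in seq_along(groups)) {
    sub[groups[[g]]] <- sprintf("%d.%d", cluster, g)
  }
  data.frame(item = tree$labels, cluster = unname(top$labels),
             subcluster = sub, stringsAsFactors = FALSE)
}

fmt_branch <- function(x) {
  s <- formatC(x, digits = 10, format = "g")
  gsub("\\s+", "", s)
}

#' Serialize a linkage tree as Newick
#'
#' Branch lengths are height differences between a node and its parent
#' (leaves sit at height 0), so leaf-to-root depth equals the root merge
#' height.
#'
#' @param tree A `linkage_tree`.
#' @return A single Newick string ending in `";"`.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "linkage_tree"))
  lab <- gsub("[^A-Za-z0-9_.|-]+", "_", tree$labels)
  node_str <- function(code, parent_h) {
    if (code < 0L) {
      paste0(lab[-code], ":", fmt_branch(parent_h))
    } else {
      h <- tree$height[code]
      paste0("(",
             node_str(tree$merge[code, 1L], h), ",",
             node_str(tree$merge[code, 2L], h),
             "):", fmt_branch(parent_h - h))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(",
         node_str(tree$merge[root, 1L], h), ",",
         node_str(tree$merge[root, 2L], h),
         ");")
}
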