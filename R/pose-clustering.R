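# Ward clustering of bound ligand poses on pairwise all-atom RMSD, with
# merge heights reported as delta = sqrt(increase in total within-cluster
# sum of squares), and threshold-based dendrogram cutting.

#' Pairwise all-atom ligand RMSD between bound frames
#'
#' Frames are assumed to be already superposed on the receptor (poses live
#' in the receptor frame); the RMSD is computed over ligand atoms with no
#' further superposition, so rigid displacements of the pose are part of
#' the signal. A warning is raised when the receptor does not appear
#' superposed.
#'
#' @param bound A bound-state `ensemble`.
#' @param warn_tol Receptor C-alpha RMSD (A) between frames above which the
#'   input is flagged as unsuperposed.
#' @return Symmetric matrix of RMSD values, A.
#' @export
pairwise_ligand_rmsd <- function(bound, warn_tol = 0.5) {
  lig <- select_atoms(bound, chains = bound$ligand_chain)
  if (!length(lig)) abort("ligand chain is empty")
  tt <- n_frames(bound)
  rec_ca <- receptor_calpha_idx(bound)
  if (tt > 1 && length(rec_ca) >= 3) {
    r1 <- matrix(bound$coords[1, rec_ca, ], ncol = 3)
    worst <- max(vapply(seq_len(tt), function(t)
      coord_rmsd(matrix(bound$coords[t, rec_ca, ], ncol = 3), r1),
      numeric(1)))
    if (worst > warn_tol) {
      warn(sprintf(paste0("receptor C-alpha RMSD between frames reaches ",
                          "%.2f A; poses do not appear superposed"), worst))
    }
  }
  flat <- matrix(bound$coords[, lig, , drop = FALSE], nrow = tt)
  g <- tcrossprod(flat)
  sq <- diag(g)
  d2 <- (outer(sq, sq, `+`) - 2 * g) / length(lig)
  sqrt(pmax(d2, 0))
}

#' Ward linkage with sum-of-squares merge heights
#'
#' Agglomerative Ward clustering of a distance matrix. The reported merge
#' height is `delta = sqrt(increase in total within-cluster sum of
#' squares)`, so merging two singletons a, b gives `delta = |a - b| /
#' sqrt(2)`. (This equals the common Ward.D2 linkage height divided by
#' sqrt(2).)
#'
#' @param distances Symmetric non-negative matrix with zero diagonal.
#' @return Object of class `"linkage_tree"`: `merges` tibble (cluster_u,
#'   cluster_v, delta, size; hclust merge convention), `leaf_count`, and
#'   the underlying `hclust` object.
#' @export
ward_linkage <- function(distances) {
  distances <- as.matrix(distances)
  if (any(!is.finite(distances)) || any(distances < 0)) {
    abort("distances must be finite and non-negative")
  }
  if (max(abs(distances - t(distances))) > 1e-8 ||
      any(abs(diag(distances)) > 1e-8)) {
    abort("distances must be symmetric with zero diagonal")
  }
  hc <- stats::hclust(stats::as.dist(distances), method = "ward.D2")
  n <- nrow(distances)
  # merged-cluster sizes by walking the merge table
  msize <- integer(n - 1)
  for (k in seq_len(n - 1)) {
    m <- hc$merge[k, ]
    msize[k] <- sum(ifelse(m < 0, 1L, msize[pmax(m, 1)]))
  }
  structure(list(
    merges = tibble(cluster_u = hc$merge[, 1], cluster_v = hc$merge[, 2],
                    delta = hc$height / sqrt(2), size = msize),
    leaf_count = n, hclust = hc, distances = distances
  ), class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %d leaves, root delta %.3f A\n",
              x$leaf_count, max(x$merges$delta)))
  invisible(x)
}

#' Cut a linkage tree at a delta threshold
#'
#' Clusters are the connected components after removing merges with
#' `delta > threshold` (equivalently `cutree` at the corresponding Ward.D2
#' height). Cluster ids are ordered by decreasing size, ties by smallest
#' member leaf index; each cluster's centroid is its medoid (the leaf
#' minimizing the summed squared RMSD to the other members).
#'
#' @param tree A [ward_linkage()] result.
#' @param threshold Cut height in delta units (A); mutually exclusive with
#'   `n_clusters`.
#' @param n_clusters Request a fixed number of clusters instead.
#' @return Object of class `"cluster_assignment"`: `labels` (leaf ->
#'   cluster id), `threshold`, `n_clusters`, `sizes`, `centroid_leaf`.
#' @export
cut_tree <- function(tree, threshold = NULL, n_clusters = NULL) {
  if (is.null(threshold) == is.null(n_clusters)) {
    abort("supply exactly one of threshold or n_clusters")
  }
  if (!is.null(threshold)) {
    if (threshold <= 0) abort("threshold must be positive")
    raw <- stats::cutree(tree$hclust, h = threshold * sqrt(2))
  } else {
    raw <- stats::cutree(tree$hclust, k = n_clusters)
  }
  sizes <- table(raw)
  first_leaf <- vapply(names(sizes), function(g)
    which(raw == as.integer(g))[1], integer(1))
  ord <- order(-as.integer(sizes), first_leaf)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  labels <- relabel[raw]
  centroid <- vapply(seq_along(ord), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1) return(members)
    d2 <- tree$distances[members, members, drop = FALSE]^2
    members[which.min(rowSums(d2))]
  }, integer(1))
  structure(list(labels = labels, threshold = threshold,
                 n_clusters = length(ord),
                 sizes = as.integer(sizes[ord]),
                 centroid_leaf = centroid),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d clusters (sizes %s)%s\n",
              x$n_clusters, paste(x$sizes, collapse = ", "),
              if (!is.null(x$threshold))
                sprintf(", cut at delta = %g A", x$threshold) else ""))
  invisible(x)
}

#' Merge selected clusters into one sub-ensemble
#'
#' @param bound The bound-state ensemble that was clustered (frames are the
#'   leaves, in order).
#' @param assignment A [cut_tree()] result.
#' @param keep_ids Cluster ids to keep.
#' @return Ensemble of the kept frames, in original frame order, provenance
#'   preserved.
#' @export
merge_clusters <- function(bound, assignment, keep_ids) {
  if (!length(keep_ids)) abort("keep_ids is empty")
  if (!all(keep_ids %in% seq_len(assignment$n_clusters))) {
    abort("keep_ids contains unknown cluster ids")
  }
  if (length(assignment$labels) != n_frames(bound)) {
    abort("assignment does not match the ensemble's frame count")
  }
  keep <- which(assignment$labels %in% keep_ids)
  out <- subset_frames(bound, sort(keep))
  out$times <- out$times - out$times[1]
  out
}
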