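# Hierarchical clustering of the similarity matrix, matrix ordering, and
# threshold-based species/genus assignment. The dendrogram is used only to
# order the heatmap and to cut at the demarcation thresholds; it is NOT a
# phylogeny and is never rendered as one.

CLUSTER_METHODS <- c("complete", "single", "average", "mcquitty",
                     "ward.D", "ward.D2", "centroid", "median")

check_sim_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    input_stop("similarity matrix must be square")
  }
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    input_stop("similarity matrix must have matching row/column genome ids")
  }
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    input_stop("similarity matrix is not symmetric")
  }
  if (any(abs(diag(m) - 100) > 1e-8)) {
    input_stop("similarity matrix diagonal must be exactly 100")
  }
  if (any(m < -1e-8) || any(m > 100 + 1e-8)) {
    input_stop("similarity values must lie in [0, 100]")
  }
  invisible(m)
}

#' Hierarchically cluster a similarity matrix
#'
#' Agglomerative clustering on the distance matrix `D = 100 - sim`. The
#' default agglomeration method is `"complete"`; the other methods of
#' [stats::hclust()] are available. The returned leaf order is what orders
#' the rows/columns of the written matrix and the heatmap.
#'
#' @param m square symmetric similarity matrix (percent scale, diagonal 100)
#'   with genome ids as dimnames, e.g. `compute_matrix(...)$sim`.
#' @param method agglomeration method, one of `"complete"`, `"single"`,
#'   `"average"`, `"mcquitty"`, `"ward.D"`, `"ward.D2"`, `"centroid"`,
#'   `"median"`.
#' @return List of class `igsim_clust` with `hclust` (the merge tree),
#'   `order` (genome ids in leaf order) and `method`.
#' @export
cluster_matrix <- function(m, method = "complete") {
  check_sim_matrix(m)
  if (nrow(m) < 2L) input_stop("clustering needs at least 2 genomes")
  if (!method %in% CLUSTER_METHODS) {
    input_stop(paste0("unknown agglomeration method '", method, "'; use one of: ",
                      paste(CLUSTER_METHODS, collapse = ", ")))
  }
  d <- stats::as.dist(100 - m)
  hc <- stats::hclust(d, method = method)
  structure(
    list(hclust = hc, order = rownames(m)[hc$order], method = method),
    class = "igsim_clust"
  )
}

#' Assign species/genus clusters by threshold
#'
#' Cuts the dendrogram at height `100 - threshold` for each level, so that
#' (under complete linkage) all members of a cluster are pairwise at least
#' `threshold` percent similar. Defaults follow the ICTV Bacterial and
#' Archaeal Viruses Subcommittee demarcations: 95 for species, 70 for genus.
#' Because both cuts come from one tree, species clusters nest inside genus
#' clusters whenever `species_thr >= genus_thr`. Labels are consecutive
#' integers in leaf order. Borderline pairs near a threshold can end up as
#' sub-clusters of what the eye groups in the heatmap; the assignments are
#' tentative and the user decides in such cases.
#'
#' @param m similarity matrix (validated as in [cluster_matrix()]).
#' @param clust an `igsim_clust` from [cluster_matrix()]; computed from `m`
#'   with the default method when omitted.
#' @param species_thr,genus_thr similarity thresholds in percent,
#'   `0 <= genus_thr <= species_thr <= 100`.
#' @return Data frame (class `igsim_cluster_table`) with one row per genome
#'   in leaf order: `genome_id`, `species_cluster`, `genus_cluster`;
#'   thresholds and method recorded as attributes.
#' @export
assign_clusters <- function(m, clust = NULL, species_thr = 95, genus_thr = 70) {
  check_sim_matrix(m)
  if (is.na(species_thr) || is.na(genus_thr) ||
      genus_thr < 0 || species_thr > 100 || genus_thr > species_thr) {
    input_stop("thresholds must satisfy 0 <= genus_thr <= species_thr <= 100")
  }
  if (is.null(clust)) clust <- cluster_matrix(m)
  if (!inherits(clust, "igsim_clust")) {
    input_stop("'clust' must come from cluster_matrix()")
  }
  hc <- clust$hclust
  leaf_order <- clust$order
  relabel <- function(raw) {
    # consecutive integers by first appearance along the leaf order
    first <- raw[leaf_order]
    map <- stats::setNames(seq_along(unique(first)), unique(first))
    stats::setNames(as.integer(map[as.character(raw)]), names(raw))
  }
  sp <- relabel(stats::cutree(hc, h = 100 - species_thr))
  ge <- relabel(stats::cutree(hc, h = 100 - genus_thr))
  # nestedness: species clusters may not straddle genus clusters
  if (length(unique(paste(sp, ge))) != length(unique(sp))) {
    internal_stop("species clusters straddle genus clusters")
  }
  out <- data.frame(
    genome_id = leaf_order,
    species_cluster = unname(sp[leaf_order]),
    genus_cluster = unname(ge[leaf_order]),
    stringsAsFactors = FALSE
  )
  attr(out, "species_thr") <- species_thr
  attr(out, "genus_thr") <- genus_thr
  attr(out, "method") <- clust$method
  class(out) <- c("igsim_cluster_table", "data.frame")
  out
}

#' Reorder a similarity matrix
#'
#' Permutes rows and columns identically (typically by the clustering leaf
#' order), preserving symmetry and cell contents.
#'
#' @param m similarity matrix.
#' @param order character vector: a permutation of the matrix's genome ids,
#'   e.g. `cluster_matrix(m)$order`.
#' @return The permuted matrix.
#' @export
order_matrix <- function(m, order) {
  check_sim_matrix(m)
  if (length(order) != nrow(m) || !setequal(order, rownames(m)) ||
      anyDuplicated(order)) {
    input_stop("'order' must be a permutation of the matrix genome ids")
  }
  m[order, order, drop = FALSE]
}
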