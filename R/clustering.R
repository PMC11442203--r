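#' Hierarchical clustering of compounds on a fingerprint distance matrix
#'
#' Agglomerative clustering via [stats::hclust()]. For reproducible
#' merge order the distance matrix is first sorted by compound id, so
#' identical inputs always yield byte-identical trees regardless of the
#' order compounds were loaded in.
#'
#' @param D Square symmetric distance matrix with dimnames, values in
#'   \[0, 1\], zero diagonal for self-similar compounds.
#' @param linkage One of `"complete"` (default), `"average"`, `"single"`,
#'   `"ward"` (Ward D2 on the distances).
#' @return An object of class `cfp_dendrogram` wrapping the `hclust`
#'   fit; fields `hc`, `linkage`, `labels`.
#' @export
hcluster <- function(D, linkage = c("complete", "average", "single", "ward")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(D), nrow(D) == ncol(D), !is.null(rownames(D)))
  if (nrow(D) < 2) stop("need at least 2 compounds to cluster")
  if (max(abs(D - t(D))) > 1e-10) stop("distance matrix is not symmetric")
  ord <- order(rownames(D))
  D <- D[ord, ord, drop = FALSE]
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::as.dist(D), method = method)
  structure(list(hc = hc, linkage = linkage, labels = rownames(D)),
            class = "cfp_dendrogram")
}

#' @export
print.cfp_dendrogram <- function(x, ...) {
  cat("<cfp_dendrogram> ", length(x$labels), " leaves, ", x$linkage,
      " linkage; merge heights ", sprintf("%.3f", min(x$hc$height)), "-",
      sprintf("%.3f", max(x$hc$height)), "\n", sep = "")
  invisible(x)
}

#' Cut a dendrogram into k labeled groups
#'
#' Groups are numbered 1..k by the order of their leftmost leaf in the
#' dendrogram's canonical leaf order, so labels are stable and readable
#' off a plotted tree left to right.
#'
#' @param dend A `cfp_dendrogram`.
#' @param k Number of groups, between 1 and the number of leaves.
#' @return Tibble with columns `compound_id`, `group` (integer 1..k).
#' @export
cut_tree <- function(dend, k) {
  stopifnot(inherits(dend, "cfp_dendrogram"))
  n <- length(dend$labels)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n) {
    stop("k must be between 1 and the number of leaves (", n, ")")
  }
  raw <- stats::cutree(dend$hc, k = as.integer(k))
  leaf_order <- dend$hc$labels[dend$hc$order]
  first_seen <- raw[leaf_order][!duplicated(raw[leaf_order])]
  relabel <- setNames(seq_along(first_seen), first_seen)
  tibble::tibble(
    compound_id = names(raw),
    group = as.integer(relabel[as.character(raw)])
  ) |> dplyr::arrange(.data$compound_id)
}

#' Consistency filter: drop drugs isolated in the cluster tree
#'
#' Clusters the comparator (western) drugs alone, cuts at `k`, and
#' removes every drug that does not share a tree branch with at least
#' `min_cosize - 1` other drugs — i.e. members of groups smaller than
#' `min_cosize`. This is the library-cleaning step applied before
#' comparing a drug library against the preparation's components.
#'
#' @param D_wm Distance matrix restricted to the western drugs.
#' @param k Number of groups to cut into.
#' @param min_cosize Minimum group size to survive (default 2:
#'   singletons are eliminated).
#' @param linkage Passed to [hcluster()].
#' @return Character vector of retained drug ids (sorted).
#' @export
consistency_filter <- function(D_wm, k, min_cosize = 2, linkage = "complete") {
  assignment <- cut_tree(hcluster(D_wm, linkage = linkage), k = k)
  sizes <- assignment |> dplyr::count(.data$group, name = "size")
  keep_groups <- sizes$group[sizes$size >= min_cosize]
  retained <- assignment$compound_id[assignment$group %in% keep_groups]
  dropped <- setdiff(assignment$compound_id, retained)
  if (length(dropped) > 0) {
    message("consistency filter removed ", length(dropped), " of ",
            nrow(assignment), " drugs in groups smaller than ", min_cosize)
  }
  sort(retained)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are the merge-height differences along the tree, so
#' leaf depths reproduce merge heights.
#'
#' @param dend A `cfp_dendrogram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "cfp_dendrogram"))
  phy <- ape::as.phylo(dend$hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @exportS3Method generics::tidy
tidy.cfp_dendrogram <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$hc$height),
    height = x$hc$height,
    merge1 = x$hc$merge[, 1],
    merge2 = x$hc$merge[, 2]
  )
}

#' @exportS3Method generics::glance
glance.cfp_dendrogram <- function(x, ...) {
  tibble::tibble(
    n_leaves = length(x$labels),
    linkage = x$linkage,
    min_height = min(x$hc$height),
    max_height = max(x$hc$height)
  )
}
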