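#' Hierarchical clustering of gene expression profiles
#'
#' Agglomerative clustering of a gene subset from pairwise profile distances,
#' cut into k groups. Default distance is one minus the Pearson correlation of
#' expression profiles (the expression-profile convention); complete linkage
#' is available alongside the default average linkage.
#'
#' @param m an \code{\link{expr_matrix}} (log2-normalized).
#' @param genes character vector of gene ids to cluster (default all).
#' @param linkage \code{"average"} (default) or \code{"complete"}.
#' @param distance \code{"one_minus_pearson"} (default) or \code{"euclidean"}.
#' @param k number of clusters to cut the tree into.
#' @return A \code{cluster_result} list: \code{assignment} (named cluster
#'   labels), \code{merge}, \code{height} (the agglomeration history),
#'   \code{linkage}, \code{distance}, \code{k}, and the \code{hclust} object.
#' @export
hierarchical_cluster <- function(m, genes = NULL,
                                 linkage = c("average", "complete"),
                                 distance = c("one_minus_pearson", "euclidean"),
                                 k = 2L) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  chk(inherits(m, "expr_matrix"), "m must be an expr_matrix")
  genes <- genes %||% rownames(m$values)
  miss <- setdiff(genes, rownames(m$values))
  chk(length(miss) == 0L, "genes not in matrix: ", paste(miss, collapse = ", "))
  x <- m$values[genes, , drop = FALSE]
  chk(all(is.finite(x)), "missing values are not supported")
  chk(is_count(k) && k <= nrow(x), "k must be a positive integer <= number of genes")
  if (distance == "one_minus_pearson") {
    sds <- apply(x, 1L, stats::sd)
    chk(all(sds > 0),
        "zero-variance profiles cannot be clustered with the correlation ",
        "distance; use distance = \"euclidean\"")
    d <- stats::as.dist(1 - stats::cor(t(x)))
  } else {
    d <- stats::dist(x)
  }
  hc <- stats::hclust(d, method = linkage)
  assignment <- stats::cutree(hc, k = k)
  structure(
    list(assignment = assignment, merge = hc$merge, height = hc$height,
         linkage = linkage, distance = distance, k = k, hclust = hc),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d genes, k = %d (%s linkage, %s distance)\n",
              length(x$assignment), x$k, x$linkage, x$distance))
  print(table(x$assignment))
  invisible(x)
}
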