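#' Row-wise z-score standardization
#'
#' Standardizes each row to mean 0 and standard deviation 1 (sample sd,
#' n - 1 denominator), the normalization applied to reaction activities
#' before heatmap display so tissues are compared within, not across,
#' reactions. Rows with zero variance are mapped to all zeros and flagged.
#'
#' @param m Numeric matrix with at least 2 columns.
#' @param population_sd Use the n-denominator (population) sd instead of
#'   the default sample sd (default `FALSE`).
#' @return Matrix of the same shape with attribute `zero_variance_rows`
#'   (character vector of flagged row names).
#' @examples
#' zscore_rows(rbind(a = c(1, 2, 3)))  # -1 0 1
#' @export
zscore_rows <- function(m, population_sd = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("'m' must be a numeric matrix")
  if (ncol(m) < 2L) stop("z-scores need at least 2 columns")
  mu <- rowMeans(m)
  centered <- m - mu
  denom <- if (population_sd) ncol(m) else ncol(m) - 1L
  s <- sqrt(rowSums(centered^2) / denom)
  flat <- s == 0
  s[flat] <- 1  # avoid 0/0; flat rows become all zeros
  out <- centered / s
  attr(out, "zero_variance_rows") <-
    if (is.null(rownames(m))) as.character(which(flat)) else
      rownames(m)[flat]
  out
}

#' Pairwise Pearson correlation of gene expression across samples
#'
#' Correlates the expression vectors of the selected genes across the
#' columns (tissues/samples) of the matrix, the quantity behind gene-gene
#' co-expression heatmaps. Genes observed in fewer than 3 samples cannot be
#' correlated meaningfully and zero-variance genes have undefined r; both
#' are dropped and flagged.
#'
#' @param m A `gag_expr` object or numeric matrix.
#' @param genes Character vector of row names to correlate; default all.
#' @return Symmetric correlation matrix (class `gag_cor`) with unit
#'   diagonal and attribute `dropped_genes`.
#' @export
pearson_matrix <- function(m, genes = rownames(m)) {
  vals <- unclass(m)
  unknown <- setdiff(genes, rownames(vals))
  if (length(unknown) > 0L)
    stop("genes absent from matrix: ", paste(unknown, collapse = ", "))
  vals <- vals[genes, , drop = FALSE]
  if (ncol(vals) < 3L)
    stop("Pearson correlation needs at least 3 samples per gene")
  v <- apply(vals, 1, stats::var)
  dropped <- rownames(vals)[v == 0]
  vals <- vals[v > 0, , drop = FALSE]
  if (nrow(vals) < 2L)
    stop("fewer than 2 genes with nonzero variance")
  r <- stats::cor(t(vals), method = "pearson")
  structure(r, dropped_genes = dropped,
            class = c("gag_cor", "matrix", "array"))
}

#' @export
print.gag_cor <- function(x, ...) {
  cat("Pearson correlation matrix: ", nrow(x), " genes\n", sep = "")
  invisible(x)
}

#' Agglomerative hierarchical clustering of matrix rows or columns
#'
#' Euclidean distance with complete linkage (the common default of R
#' heatmap tooling), applied to the rows or columns of a (typically
#' z-scored) matrix. Items are ordered by label before clustering so that
#' merges tied in height resolve deterministically by label.
#'
#' @param m Numeric matrix.
#' @param axis Cluster `"cols"` (default; e.g. tissues) or `"rows"`.
#' @param method Linkage method passed to [stats::hclust()].
#' @return An object of class `gag_clust`: list with `hclust` (the merge
#'   tree), `order` (leaf order as labels) and `labels`.
#' @export
hierarchical_cluster <- function(m, axis = c("cols", "rows"),
                                 method = "complete") {
  axis <- match.arg(axis)
  x <- if (axis == "cols") t(unclass(m)) else unclass(m)
  if (nrow(x) < 2L) stop("clustering needs at least 2 items")
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  x <- x[order(rownames(x)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = method)
  structure(list(hclust = hc, order = hc$labels[hc$order],
                 labels = rownames(x)),
            class = "gag_clust")
}

#' Cut a cluster tree into k groups
#'
#' @param cl A `gag_clust` object.
#' @param k Number of groups.
#' @return Named integer vector of group memberships (1..k).
#' @export
cut_clusters <- function(cl, k) {
  stopifnot(inherits(cl, "gag_clust"))
  stats::cutree(cl$hclust, k = k)
}

#' @export
print.gag_clust <- function(x, ...) {
  cat("Hierarchical clustering of ", length(x$labels),
      " items (", x$hclust$method, " linkage)\n", sep = "")
  invisible(x)
}

#' Draw a clustered z-score heatmap of reaction activity
#'
#' Convenience wrapper around \pkg{pheatmap}: rows are z-scored reactions,
#' columns are tissues/samples, both axes clustered with Euclidean distance
#' and complete linkage.
#'
#' @param activity A `gag_activity` matrix (see [reaction_activity()]).
#' @param file Optional output file (png/pdf, by extension); `NULL` draws
#'   to the active device.
#' @param ... Passed on to [pheatmap::pheatmap()].
#' @return The z-scored matrix, invisibly.
#' @export
plot_reaction_heatmap <- function(activity, file = NULL, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("package 'pheatmap' is required for heatmap drawing")
  z <- zscore_rows(unclass(activity))
  args <- list(mat = z, clustering_distance_rows = "euclidean",
               clustering_distance_cols = "euclidean",
               clustering_method = "complete", ...)
  if (!is.null(file)) args$filename <- file
  do.call(pheatmap::pheatmap, args)
  invisible(z)
}
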