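#' Z-score the rows of an expression matrix
#'
#' Standard heat-map preprocessing: each row is centred to mean 0 and scaled
#' to unit sample standard deviation (n - 1 denominator). Constant rows have
#' no scale and are dropped with a warning.
#'
#' @param m numeric matrix with at least 2 columns.
#' @return the row-standardized matrix; dropped constant rows are recorded in
#'   attribute `dropped`.
#' @examples
#' zscore_rows(rbind(g1 = c(1, 3), g2 = c(5, 2)))
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 columns to standardize rows")
  sds <- apply(m, 1L, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant row(s): ",
            paste(rownames(m)[const], collapse = ", "))
    m <- m[!const, , drop = FALSE]
    sds <- sds[!const]
  }
  out <- sweep(sweep(m, 1L, rowMeans(m), "-"), 1L, sds, "/")
  attr(out, "dropped") <- names(const)[const] %||% character(0)
  out
}

#' Hierarchically cluster expression profiles (rows)
#'
#' Builds the dendrogram that orders heat-map rows. Rows are first sorted by
#' label so the tree topology does not depend on input order (distance ties
#' are then resolved identically for any permutation of the same rows).
#'
#' @param m numeric matrix (typically z-scored) with rownames.
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param metric distance for [stats::dist()] (default `"euclidean"`).
#' @return list of class `"profile_clust"`: `tree` (an `hclust`), `order`
#'   (row labels in leaf order) and the clustered `matrix` in leaf order.
#' @export
cluster_rows <- function(m, linkage = "average", metric = "euclidean") {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  if (any(apply(m, 1L, stats::sd) == 0) && metric == "correlation")
    stop("correlation distance undefined on constant rows")
  m <- m[order(rownames(m)), , drop = FALSE]   # deterministic tie-breaking
  tree <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  leaf <- rownames(m)[tree$order]
  structure(list(tree = tree, order = leaf,
                 matrix = m[leaf, , drop = FALSE]),
            class = "profile_clust")
}

#' @export
print.profile_clust <- function(x, ...) {
  cat("Profile clustering of", length(x$order), "genes (",
      x$tree$method, "linkage )\n")
  cat("leaf order:", paste(utils::head(x$order, 8), collapse = ", "),
      if (length(x$order) > 8) "..." else "", "\n")
  invisible(x)
}

#' Classify expression direction of genes
#'
#' Direction is the sign of the log2 ratio: `up` for positive, `down` for
#' negative, `ambiguous` for exactly zero (flagged, not silently assigned).
#'
#' @param de a `"de_table"` (or data frame with `gene` and `log2_ratio`).
#' @param genes optional subset of gene ids; all must be present in `de`.
#' @return data frame with `gene` and `direction`; attribute `partition`
#'   gives the up/down/ambiguous counts.
#' @export
classify_direction <- function(de, genes = NULL) {
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, de$gene)
    if (length(missing_g))
      stop("genes absent from the DE table: ", paste(missing_g, collapse = ", "))
    de <- de[match(genes, de$gene), , drop = FALSE]
  }
  dir <- ifelse(de$log2_ratio > 0, "up",
                ifelse(de$log2_ratio < 0, "down", "ambiguous"))
  out <- data.frame(gene = de$gene, direction = dir)
  attr(out, "partition") <- c(up = sum(dir == "up"),
                              down = sum(dir == "down"),
                              ambiguous = sum(dir == "ambiguous"))
  out
}

#' Build clustered expression profiles for key genes
#'
#' Produces the heat-map stage output for a set of key genes: per-sample
#' log2(FPKM + 1) values, row z-scoring, hierarchical clustering, and
#' up/down direction classification consistent with the DE table.
#'
#' @param de a `"de_table"` from [de_analysis()] (its `fpkm` attribute
#'   provides the per-sample expression).
#' @param genes gene ids to profile; default the key genes of `de`.
#' @param linkage,metric passed to [cluster_rows()].
#' @return list of class `"expression_profiles"`: z-scored `matrix` in leaf
#'   order, `clustering` (a `"profile_clust"`), `direction`
#'   (per-gene up/down), and `dropped` (constant rows excluded).
#' @export
expression_profiles <- function(de, genes = NULL, linkage = "average",
                                metric = "euclidean") {
  fk <- attr(de, "fpkm")
  if (is.null(fk)) stop("the DE table carries no per-sample FPKM matrix")
  if (is.null(genes)) genes <- de$gene[de$key_gene]
  if (length(genes) < 2L) stop("need at least 2 genes to profile")
  m <- log2(fk[genes, , drop = FALSE] + 1)
  z <- zscore_rows(m)
  cl <- cluster_rows(z, linkage = linkage, metric = metric)
  dir <- classify_direction(de, genes = rownames(cl$matrix))
  structure(list(matrix = cl$matrix, clustering = cl, direction = dir,
                 dropped = attr(z, "dropped")),
            class = "expression_profiles")
}

#' @export
print.expression_profiles <- function(x, ...) {
  p <- attr(x$direction, "partition")
  cat("Expression profiles:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples;", p[["up"]], "up /", p[["down"]], "down\n")
  invisible(x)
}

#' @export
plot.expression_profiles <- function(x, ...) {
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(x$matrix, cluster_rows = FALSE, cluster_cols = FALSE,
                       ...)
  } else {
    stats::heatmap(x$matrix, Rowv = NA, Colv = NA, scale = "none", ...)
  }
  invisible(x)
}

#' Export a row dendrogram as Newick
#'
#' @param clust a `"profile_clust"` (or `"expression_profiles"`) object.
#' @param path file to write; `NULL` returns the Newick string.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(clust, path = NULL) {
  if (inherits(clust, "expression_profiles")) clust <- clust$clustering
  phy <- ape::as.phylo(clust$tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
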