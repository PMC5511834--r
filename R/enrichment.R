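#' Hypergeometric upper-tail probability
#'
#' The over-representation p-value: drawing `n` genes (the DE set) without
#' replacement from a universe of `N` genes of which `K` belong to the
#' pathway, the probability of seeing at least the observed overlap,
#' \eqn{P(X \ge k)}. Computed with the exact hypergeometric distribution
#' (numerically stable tail evaluation); equivalent to the one-sided
#' Fisher's exact test for enrichment.
#'
#' @param N universe size.
#' @param K pathway size within the universe.
#' @param n number of DE genes.
#' @param k observed overlap between the DE set and the pathway; vectorized
#'   over all four arguments.
#' @return p-value(s) in (0, 1\].
#' @examples
#' hypergeom_upper_tail(N = 10, K = 5, n = 5, k = 5)  # 1/choose(10, 5)
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(K > N) || any(n > N)) stop("K and n cannot exceed the universe size N")
  if (any(k > pmin(n, K)))
    stop("impossible configuration: overlap k exceeds min(n, K)")
  if (any(k < pmax(0, n + K - N)))
    stop("impossible configuration: overlap k below max(0, n + K - N)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway over-representation analysis of a DE gene set
#'
#' Tests every pathway in a gene-set collection for over-representation of
#' the differentially expressed genes by the hypergeometric upper-tail test.
#' Pathway members are first intersected with the universe; pathways with no
#' member in the universe are dropped. Rows are sorted by ascending p-value
#' (ties keep input order). By default no multiple-testing correction is
#' applied to the pathway p-values — the significance split is on the raw
#' p — but BH adjustment can be switched on.
#'
#' @param de_genes character vector of DE gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector of background gene ids.
#' @param collection named list of gene-id vectors (e.g. from [read_gmt()]
#'   or [gen_pathways()]).
#' @param alpha significance threshold on the p-value (default 0.05).
#' @param adjust if `TRUE`, flag significance on BH-adjusted p-values instead
#'   (an extra `q_value` column is added).
#' @return data frame of class `"enrichment_table"` with columns `Pathway`,
#'   `Gene_numbers` (overlap k), `Set_size` (K in universe), `P_value` and
#'   `Significant`; attributes `n_de` and `universe_size`.
#' @examples
#' universe <- paste0("g", 1:100)
#' sets <- list(PW1 = paste0("g", 1:10), PW2 = paste0("g", 51:70))
#' enrich(paste0("g", 1:10), universe, sets)
#' @export
enrich <- function(de_genes, universe, collection, alpha = 0.05,
                   adjust = FALSE) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("the gene universe is empty")
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe))
    stop("DE genes must be a subset of the universe")
  N <- length(universe)
  n <- length(de_genes)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(unique(collection[[id]]), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, de_genes))
    data.frame(Pathway = id, Gene_numbers = k, Set_size = K,
               P_value = hypergeom_upper_tail(N, K, n, k))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pathway has members in the universe")
  out <- out[order(out$P_value), , drop = FALSE]   # stable: ties keep input order
  if (adjust) {
    out$q_value <- bh_adjust(out$P_value)
    out$Significant <- out$q_value < alpha
  } else {
    out$Significant <- out$P_value < alpha
  }
  rownames(out) <- NULL
  attr(out, "n_de") <- n
  attr(out, "universe_size") <- N
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("Pathway over-representation:", nrow(x), "pathways;",
      sum(x$Significant), "significant;",
      attr(x, "n_de"), "DE genes in a universe of",
      attr(x, "universe_size"), "\n")
  df <- as.data.frame(x)
  df$P_value <- signif(df$P_value, 3)
  print.data.frame(utils::head(df, 10), ...)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}
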