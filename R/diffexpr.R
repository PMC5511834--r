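#' FPKM expression values from a count matrix
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' \deqn{FPKM = count \times 10^9 / (length_{bp} \times librarySize)}
#' Library sizes are the column sums of the count matrix (counts are the
#' pipeline's entry point; no mapped-read or effective-length correction).
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param lengths gene lengths in bp, one per row (recycled from a named
#'   vector matched by rowname when names are present).
#' @return numeric matrix of FPKM values, same shape as `counts`.
#' @examples
#' fpkm(matrix(10, 1, 1, dimnames = list("g", "s")), lengths = 1000)
#' @export
fpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts))
    stop("need one gene length per row of the count matrix")
  if (any(lengths <= 0) || anyNA(lengths)) stop("gene lengths must be positive")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size: a sample has no counts")
  sweep(counts / lengths, 2L, lib, "/") * 1e9
}

#' Log2 expression ratio between conditions
#'
#' \deqn{log_2((t + \epsilon) / (c + \epsilon))} where the pseudocount
#' \eqn{\epsilon} keeps ratios finite when one mean expression is zero while
#' preserving the sign of the change.
#'
#' @param treated,control mean expression (e.g. mean FPKM) per gene in the
#'   treated and control condition; vectorized.
#' @param pseudocount small positive constant added to both means (default
#'   0.125 FPKM); may be 0 only if no gene has both means zero.
#' @return numeric vector of log2 ratios.
#' @examples
#' log2_ratio(4, 1, pseudocount = 0)  # 2
#' @export
log2_ratio <- function(treated, control, pseudocount = 0.125) {
  if (length(treated) != length(control))
    stop("treated and control must have the same length")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(treated == 0 & control == 0))
    stop("both means are zero for some gene; use a positive pseudocount")
  log2((treated + pseudocount) / (control + pseudocount))
}

#' Per-gene differential-expression test
#'
#' Welch's two-sample t-test on replicate log2(FPKM + 1) values — a simple
#' variance analysis honouring the replicated two-condition design. When both
#' groups have zero variance and equal means the statistic is undefined; the
#' p-value is then 1 by convention and flagged via the `"degenerate"`
#' attribute.
#'
#' @param treated,control numeric vectors of per-replicate log expression,
#'   length >= 2 each.
#' @return two-sided p-value in (0, 1\].
#' @export
de_test <- function(treated, control) {
  if (length(treated) < 2L || length(control) < 2L)
    stop("need at least 2 replicates per group")
  if (stats::sd(treated) == 0 && stats::sd(control) == 0) {
    if (mean(treated) == mean(control))
      return(structure(1, degenerate = TRUE))
    # zero within-group variance, different means: infinitely strong evidence
    return(structure(.Machine$double.xmin, degenerate = TRUE))
  }
  stats::t.test(treated, control, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q-values are monotone along the sorted p-values
#' and never smaller than the raw p.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of BH q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential-expression status under a threshold cascade
#'
#' Applies the filter cascade to a per-gene statistics table: a gene is
#' called `up` when `log2_ratio >= lfc` with `p < p` and `q <= fdr`, `down`
#' symmetrically, otherwise `not_significant`. A `key_gene` flag additionally
#' requires expression above an FPKM floor in at least one condition.
#' Volcano-plot coordinates (`log2_ratio`, `-log10 p`) come along for free in
#' the returned table.
#'
#' @param table data frame with columns `gene`, `fpkm_control`, `fpkm_salt`,
#'   `log2_ratio`, `p_value`, `q_value`.
#' @param p,fdr,lfc,fpkm_floor thresholds: raw p-value cut (default 0.05),
#'   BH q-value cut (default 0.001), minimum |log2 fold change| (default 1),
#'   and the FPKM floor for the key-gene screen (default 0.05).
#' @return the table with `status` and `key_gene` columns added, of class
#'   `"de_table"`; attributes `thresholds` and `counts` (up/down/ns).
#' @export
call_de <- function(table, p = 0.05, fdr = 0.001, lfc = 1, fpkm_floor = 0.05) {
  need <- c("gene", "fpkm_control", "fpkm_salt", "log2_ratio", "p_value",
            "q_value")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  sig <- table$p_value < p & table$q_value <= fdr & abs(table$log2_ratio) >= lfc
  table$status <- ifelse(sig & table$log2_ratio > 0, "up",
                         ifelse(sig, "down", "not_significant"))
  table$key_gene <- table$status != "not_significant" &
    pmax(table$fpkm_control, table$fpkm_salt) > fpkm_floor &
    abs(table$log2_ratio) >= lfc
  attr(table, "thresholds") <- c(p = p, fdr = fdr, lfc = lfc,
                                 fpkm_floor = fpkm_floor)
  attr(table, "counts") <- c(up = sum(table$status == "up"),
                             down = sum(table$status == "down"),
                             not_significant = sum(table$status == "not_significant"))
  class(table) <- c("de_table", "data.frame")
  table
}

#' Differential-expression analysis of a two-condition count matrix
#'
#' The full stage: FPKM quantification, per-condition means, log2 ratio with
#' pseudocount, per-gene variance analysis across replicates (Welch's t on
#' log2(FPKM + 1) by default), Benjamini-Hochberg FDR adjustment, and the
#' threshold cascade of [call_de()].
#'
#' @param counts genes x samples count matrix (or a `"sim_counts"` object,
#'   in which case `lengths` and `condition` are taken from it).
#' @param lengths gene lengths in bp.
#' @param condition character vector assigning each sample to `"control"` or
#'   `"salt"` (any two labels work; the second level in sort order is treated
#'   as the treatment unless `treated` is given).
#' @param treated label of the treated condition; default `"salt"` when
#'   present, else the second sorted level.
#' @param p,fdr,lfc,fpkm_floor thresholds passed to [call_de()].
#' @param pseudocount FPKM pseudocount for [log2_ratio()].
#' @param test_fun per-gene test; any
#'   `function(treated_reps, control_reps) -> p` (default [de_test()]).
#' @return a `"de_table"` (see [call_de()]) carrying the per-sample FPKM
#'   matrix in attribute `fpkm`.
#' @examples
#' sim <- gen_count_matrix(de_truth(n_genes = 50, lib_sizes = rep(1e5, 6)))
#' de <- de_analysis(sim)
#' attr(de, "counts")
#' @export
de_analysis <- function(counts, lengths = NULL, condition = NULL,
                        treated = NULL, p = 0.05, fdr = 0.001, lfc = 1,
                        fpkm_floor = 0.05, pseudocount = 0.125,
                        test_fun = de_test) {
  if (inherits(counts, "sim_counts")) {
    lengths <- counts$lengths
    condition <- counts$samples$condition
    counts <- counts$counts
  }
  if (is.null(lengths) || is.null(condition))
    stop("supply 'lengths' and 'condition' (or a sim_counts object)")
  counts <- as.matrix(counts)
  if (length(condition) != ncol(counts))
    stop("need one condition label per sample")
  lv <- sort(unique(condition))
  if (length(lv) != 2L) stop("exactly two conditions are required")
  if (is.null(treated)) treated <- if ("salt" %in% lv) "salt" else lv[2]
  ctrl <- setdiff(lv, treated)
  if (sum(condition == treated) < 2L || sum(condition == ctrl) < 2L)
    stop("both conditions need at least 2 replicates")

  fk <- fpkm(counts, lengths)
  lf <- log2(fk + 1)
  t_idx <- condition == treated
  mean_t <- rowMeans(fk[, t_idx, drop = FALSE])
  mean_c <- rowMeans(fk[, !t_idx, drop = FALSE])
  pv <- vapply(seq_len(nrow(fk)), function(i) {
    as.numeric(test_fun(lf[i, t_idx], lf[i, !t_idx]))
  }, numeric(1))
  tab <- data.frame(
    gene = rownames(counts) %||% paste0("gene", seq_len(nrow(counts))),
    fpkm_control = mean_c,
    fpkm_salt = mean_t,
    log2_ratio = log2_ratio(mean_t, mean_c, pseudocount),
    p_value = pv,
    q_value = bh_adjust(pv),
    row.names = NULL
  )
  out <- call_de(tab, p = p, fdr = fdr, lfc = lfc, fpkm_floor = fpkm_floor)
  attr(out, "fpkm") <- fk
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.de_table <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("Differential expression:", nrow(x), "genes;",
      cnt[["up"]], "up,", cnt[["down"]], "down,",
      cnt[["not_significant"]], "not significant;",
      sum(x$key_gene), "key genes\n")
  th <- attr(x, "thresholds")
  cat(sprintf("thresholds: p < %g, q <= %g, |log2FC| >= %g, FPKM > %g\n",
              th[["p"]], th[["fdr"]], th[["lfc"]], th[["fpkm_floor"]]))
  invisible(x)
}

#' Volcano-plot coordinates for a DE table
#'
#' @param de a `"de_table"`.
#' @return data frame with `gene`, `log2_ratio`, `neg_log10_p` (raw p-value
#'   axis, the conventional choice) and `status`.
#' @export
volcano_data <- function(de) {
  data.frame(gene = de$gene, log2_ratio = de$log2_ratio,
             neg_log10_p = -log10(pmax(de$p_value, .Machine$double.xmin)),
             status = de$status)
}

#' @export
plot.de_table <- function(x, ...) {
  vd <- volcano_data(x)
  col <- c(up = "firebrick", down = "steelblue", not_significant = "grey60")
  graphics::plot(vd$log2_ratio, vd$neg_log10_p, pch = 16, cex = 0.5,
                 col = col[vd$status],
                 xlab = expression(log[2] ~ ratio),
                 ylab = expression(-log[10] ~ italic(p)),
                 main = "Differentially expressed genes", ...)
  invisible(x)
}

#' Screen key regulatory genes
#'
#' Subsets the significant genes passing the extra expression and fold-change
#' floors (FPKM above `fpkm_floor` in at least one condition and
#' |log2 fold change| at least `lfc_floor`), optionally grouped by pathway
#' annotation in a pathway / gene / direction report layout.
#'
#' @param de a `"de_table"`.
#' @param annotation optional data frame with columns `gene` and `pathway`
#'   (or `category`).
#' @param fpkm_floor,lfc_floor the two screening floors (defaults 0.05 and 1).
#' @return data frame of key genes (with a `pathway` column when annotation
#'   is given; genes in several pathways appear once per pathway).
#' @export
screen_key_genes <- function(de, annotation = NULL, fpkm_floor = 0.05,
                             lfc_floor = 1) {
  keep <- de$status != "not_significant" &
    pmax(de$fpkm_control, de$fpkm_salt) > fpkm_floor &
    abs(de$log2_ratio) >= lfc_floor
  out <- as.data.frame(de)[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(annotation)) {
    pw_col <- intersect(c("pathway", "category"), names(annotation))[1]
    if (is.na(pw_col)) stop("annotation needs a 'pathway' or 'category' column")
    ann <- annotation[annotation$gene %in% out$gene, c("gene", pw_col)]
    names(ann)[2] <- "pathway"
    out <- merge(ann, out, by = "gene", sort = FALSE)
    out <- out[order(out$pathway, out$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Tally genes per functional category
#'
#' Counts how many of the given genes fall in each annotation category
#' (GO-classification style); a gene annotated to several categories counts
#' in each, and genes with no annotation are tallied as `"unclassified"`.
#'
#' @param gene_ids character vector of gene ids.
#' @param annotation data frame with columns `gene` and `category`.
#' @return data frame with `category` and `count`, sorted by decreasing
#'   count.
#' @export
tally_categories <- function(gene_ids, annotation) {
  if (!all(c("gene", "category") %in% names(annotation)))
    stop("annotation needs 'gene' and 'category' columns")
  ann <- annotation[annotation$gene %in% gene_ids, , drop = FALSE]
  tab <- table(ann$category)
  unclassified <- sum(!gene_ids %in% annotation$gene)
  out <- data.frame(category = names(tab), count = as.integer(tab))
  if (unclassified > 0)
    out <- rbind(out, data.frame(category = "unclassified",
                                 count = unclassified))
  out <- out[order(-out$count, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
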