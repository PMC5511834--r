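#' Relative quantification by the 2^-ddCt method
#'
#' For each target gene, replicate Ct values are averaged within each group,
#' normalized against the designated reference (housekeeping) gene
#' (\eqn{\Delta Ct = Ct_{target} - Ct_{reference}}), and the salt-vs-control
#' difference taken (\eqn{\Delta\Delta Ct = \Delta Ct_{salt} -
#' \Delta Ct_{control}}); the fold change is \eqn{2^{-\Delta\Delta Ct}}
#' (amplification efficiency fixed at 2, as the method's name implies).
#'
#' @param ct data frame with columns `gene`, `group` (`control`/`salt`),
#'   `replicate`, `Ct` (e.g. from [gen_ct_table()] or [read_ct_table()]).
#' @param reference_gene reference gene id; defaults to the table's
#'   `reference_gene` attribute.
#' @return data frame of class `"relquant"` with one row per target gene:
#'   `gene`, `dCt_control`, `dCt_salt`, `ddCt`, `fold`, `direction`
#'   (`up` if fold > 1, `down` if fold < 1, `unchanged` at exactly 1).
#' @examples
#' ct <- gen_ct_table(c(gA = "up"), lfc_magnitude = 1, noise_sd = 0)
#' ddct(ct)  # fold exactly 2
#' @export
ddct <- function(ct, reference_gene = attr(ct, "reference_gene")) {
  need <- c("gene", "group", "replicate", "Ct")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (is.null(reference_gene))
    stop("a reference gene must be designated")
  if (any(ct$Ct <= 0)) stop("Ct values must be positive")
  groups <- c("control", "salt")
  if (!all(groups %in% ct$group))
    stop("Ct table must contain both 'control' and 'salt' groups")
  ref_ct <- vapply(groups, function(g) {
    v <- ct$Ct[ct$gene == reference_gene & ct$group == g]
    if (length(v) == 0L)
      stop("reference gene '", reference_gene, "' missing from the ", g,
           " group")
    mean(v)
  }, numeric(1))
  # the reference is kept as a (trivial) target row: normalized against
  # itself its dCt is 0 in both groups, so its fold is exactly 1 — a useful
  # sanity check on the normalization
  targets <- unique(ct$gene)
  rows <- lapply(targets, function(g) {
    dct <- vapply(groups, function(grp) {
      v <- ct$Ct[ct$gene == g & ct$group == grp]
      if (length(v) == 0L)
        stop("gene '", g, "' has no Ct in the ", grp, " group")
      mean(v) - ref_ct[[grp]]
    }, numeric(1))
    dd <- dct[["salt"]] - dct[["control"]]
    fold <- 2^(-dd)
    data.frame(gene = g, dCt_control = dct[["control"]],
               dCt_salt = dct[["salt"]], ddCt = dd, fold = fold,
               direction = if (fold > 1) "up" else if (fold < 1) "down"
                           else "unchanged")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_gene") <- reference_gene
  class(out) <- c("relquant", "data.frame")
  out
}

#' @export
print.relquant <- function(x, ...) {
  cat("2^-ddCt relative quantification of", nrow(x), "genes (reference:",
      attr(x, "reference_gene"), ")\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round_half_up, 3)
  print.data.frame(df, ...)
  invisible(x)
}

#' Concordance between qPCR and RNA-seq expression directions
#'
#' A gene is concordant when the sign of its qPCR log2 fold change
#' (`-ddCt`) agrees with the sign of its RNA-seq log2 ratio. Genes present
#' on only one platform are excluded and reported.
#'
#' @param relquant a `"relquant"` table from [ddct()].
#' @param de a `"de_table"` (or data frame with `gene` and `log2_ratio`).
#' @return data frame with `gene`, `qpcr_log2fc`, `rnaseq_log2fc`,
#'   `concordant`; attributes `fraction_concordant` and `excluded` (gene ids
#'   missing from either side).
#' @export
concordance <- function(relquant, de) {
  shared <- intersect(relquant$gene, de$gene)
  excluded <- union(setdiff(relquant$gene, de$gene),
                    setdiff(de$gene, relquant$gene))
  if (length(shared) == 0L) stop("no genes shared between qPCR and RNA-seq")
  rq <- relquant[match(shared, relquant$gene), ]
  dd <- de[match(shared, de$gene), ]
  out <- data.frame(gene = shared,
                    qpcr_log2fc = log2(rq$fold),
                    rnaseq_log2fc = dd$log2_ratio)
  out$concordant <- sign(out$qpcr_log2fc) == sign(out$rnaseq_log2fc)
  attr(out, "fraction_concordant") <- mean(out$concordant)
  attr(out, "excluded") <- excluded
  class(out) <- c("concordance", "data.frame")
  out
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("qPCR / RNA-seq concordance: %d/%d genes (%.1f%%)\n",
              sum(x$concordant), nrow(x),
              100 * attr(x, "fraction_concordant")))
  ex <- attr(x, "excluded")
  if (length(ex)) cat("excluded (one platform only):",
                      paste(ex, collapse = ", "), "\n")
  invisible(x)
}
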