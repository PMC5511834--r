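# Readers and writers for the pipeline's plain-text formats. Everything is
# diff-able TSV/CSV/GMT; no binary formats.

#' Read / write an indicator panel
#'
#' The panel CSV has alternatives as rows (first column = label) and
#' criteria as columns (header row).
#'
#' @param path file path.
#' @return for `read_panel`, a [decision_matrix()].
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  decision_matrix(as.matrix(df))
}

#' @param panel a [decision_matrix()].
#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(alternative = rownames(panel), unclass(panel),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a gene-level count matrix
#'
#' Counts TSV: `gene_id` column plus one integer column per sample.
#'
#' @param path file path.
#' @return for `read_counts`, an integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @param counts genes x samples matrix with dimnames.
#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write_tsv(df, path)
}

#' Read / write gene lengths
#'
#' Lengths TSV: columns `gene_id`, `length_bp`.
#'
#' @param path file path.
#' @return for `read_lengths`, a named numeric vector of lengths in bp.
#' @export
read_lengths <- function(path) {
  df <- utils::read.delim(path)
  stats::setNames(df$length_bp, df$gene_id)
}

#' @param lengths named vector of gene lengths.
#' @rdname read_lengths
#' @export
write_lengths <- function(lengths, path) {
  write_tsv(data.frame(gene_id = names(lengths), length_bp = unname(lengths)),
            path)
}

#' Read / write a sample sheet
#'
#' Sample sheet TSV: columns `sample`, `condition`, `replicate`.
#'
#' @param path file path.
#' @return for `read_samples`, a data frame.
#' @export
read_samples <- function(path) utils::read.delim(path)

#' @param samples sample-sheet data frame.
#' @rdname read_samples
#' @export
write_samples <- function(samples, path) write_tsv(samples, path)

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line — set id, description, then tab-separated member
#' gene ids.
#'
#' @param path file path.
#' @return for `read_gmt`, a named list of gene-id vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' @param sets named list of gene-id vectors; an optional `descriptions`
#'   character vector (recycled `"na"`) fills the second GMT field.
#' @param descriptions per-set description strings.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(id, desc, members) {
    paste(c(id, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a qPCR Ct table
#'
#' Ct TSV: columns `gene`, `group`, `replicate`, `Ct`.
#'
#' @param path file path.
#' @param reference_gene reference gene id attached to the returned table.
#' @return for `read_ct_table`, a `"ct_table"` data frame.
#' @export
read_ct_table <- function(path, reference_gene = NULL) {
  df <- utils::read.delim(path)
  attr(df, "reference_gene") <- reference_gene
  class(df) <- c("ct_table", "data.frame")
  df
}

#' @param ct a Ct data frame.
#' @rdname read_ct_table
#' @export
write_ct_table <- function(ct, path) write_tsv(as.data.frame(ct), path)

#' Write a data frame as headered TSV
#'
#' @param df data frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a headered TSV written by this package
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) utils::read.delim(path, check.names = FALSE)
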