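# FPKM computation and two-fold expression-change classification for
# two-phase RNA-seq count tables.

#' Construct a two-phase expression table
#'
#' @param counts Integer matrix of fragment counts, genes x samples.
#' @param lengths Exon lengths in bases (one per gene).
#' @param phase Character vector (`"I"` / `"II"`), one entry per sample
#'   column.
#' @param gene_ids Gene identifiers (default: rownames of `counts`).
#' @param total_mapped Total mapped fragments per sample (the "per million
#'   fragments mapped" denominator).  Defaults to the column sums, the only
#'   estimate available when the table covers the whole annotation; supply
#'   the true library depths when known.
#' @return A list of class `expression_table` with `counts`, `lengths`,
#'   `phase`, `gene`, `total_mapped`.
#' @export
expression_table <- function(counts, lengths, phase, gene_ids = rownames(counts),
                             total_mapped = NULL) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) stop("gene ids required")
  if (length(lengths) != nrow(counts)) stop("one length per gene required")
  if (length(phase) != ncol(counts)) stop("one phase label per sample required")
  if (!all(phase %in% c("I", "II"))) stop("phase labels must be 'I' or 'II'")
  if (any(lengths <= 0)) stop("exon lengths must be positive")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (is.null(total_mapped)) total_mapped <- colSums(counts)
  if (length(total_mapped) != ncol(counts) || any(total_mapped <= 0))
    stop("one positive total_mapped value per sample required")
  structure(list(counts = counts, lengths = lengths, phase = phase,
                 gene = gene_ids, total_mapped = total_mapped),
            class = "expression_table")
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' `count / (length/1000) / (total/1e6)`.
#'
#' @param count Fragment count(s) for the gene.
#' @param exon_length_bases Exon length in bases.
#' @param total_mapped_fragments Total mapped fragments in the sample.
#' @return FPKM value(s).
#' @export
fpkm <- function(count, exon_length_bases, total_mapped_fragments) {
  if (any(exon_length_bases <= 0)) stop("exon length must be positive")
  if (any(total_mapped_fragments <= 0)) stop("total mapped fragments must be positive")
  count / (exon_length_bases / 1000) / (total_mapped_fragments / 1e6)
}

#' Per-sample FPKM matrix of an expression table
#'
#' @param table An `expression_table`.
#' @return Numeric matrix of FPKM values, genes x samples.
#' @export
fpkm_matrix <- function(table) {
  totals <- table$total_mapped
  out <- sweep(table$counts, 1, table$lengths / 1000, "/")
  sweep(out, 2, totals / 1e6, "/")
}

#' Classify expression changes by the two-fold FPKM rule
#'
#' Per-phase FPKM is the arithmetic mean over replicates; the fold change
#' is `log2((fpkm_II + pseudo) / (fpkm_I + pseudo))`.  Genes are classified
#' `up` when the log2 fold change is at least 1 (a minimum two-fold
#' increase), `down` when at most -1, otherwise `NSE` (not significantly
#' expressed differently).  Genes whose mean FPKM stays below
#' `expression_floor` in both phases are flagged not expressed and excluded
#' from the regulated-gene tallies.
#'
#' @param table An `expression_table`.
#' @param pseudo Pseudo-FPKM added to both phases before the ratio
#'   (default 0.1).
#' @param expression_floor Minimum mean FPKM (in at least one phase) for a
#'   gene to count as expressed (default 1).
#' @return A data frame of class `fold_change_result` with columns `gene`,
#'   `fpkm_I`, `fpkm_II`, `log2fc`, `expressed`, `class`.
#' @export
classify_fold_change <- function(table, pseudo = 0.1, expression_floor = 1) {
  fk <- fpkm_matrix(table)
  if (!any(table$phase == "I") || !any(table$phase == "II"))
    stop("need at least one replicate per phase")
  f1 <- rowMeans(fk[, table$phase == "I", drop = FALSE])
  f2 <- rowMeans(fk[, table$phase == "II", drop = FALSE])
  lfc <- log2((f2 + pseudo) / (f1 + pseudo))
  expressed <- f1 >= expression_floor | f2 >= expression_floor
  cls <- ifelse(lfc >= 1, "up", ifelse(lfc <= -1, "down", "NSE"))
  cls[!expressed] <- "not_expressed"
  res <- data.frame(gene = table$gene, fpkm_I = f1, fpkm_II = f2,
                    log2fc = lfc, expressed = expressed,
                    class = factor(cls, levels = c("up", "down", "NSE",
                                                   "not_expressed")),
                    stringsAsFactors = FALSE)
  class(res) <- c("fold_change_result", "data.frame")
  res
}

#' Tally regulated genes
#'
#' @param result A `fold_change_result`.
#' @return Named integer vector `c(n_up, n_down, n_expressed)`.
#' @export
count_regulated <- function(result) {
  c(n_up = sum(result$class == "up"),
    n_down = sum(result$class == "down"),
    n_expressed = sum(result$expressed))
}
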