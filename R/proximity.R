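#' Read / write a gene-coordinate table
#'
#' A GFF3-like tab table with columns `contig`, `start`, `end`, `strand`,
#' `gene_id`; coordinates are 1-based inclusive.
#'
#' @param path TSV file.
#' @return data.frame of loci.
#' @export
read_loci <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "strand", "gene_id")
  if (!all(need %in% names(df)))
    stop("loci table needs columns: ", paste(need, collapse = ", "))
  if (any(df$start > df$end)) stop("loci with start > end")
  df[, need]
}

#' @rdname read_loci
#' @param loci data.frame of loci.
#' @export
write_loci <- function(loci, path) {
  write.table(loci[, c("contig", "start", "end", "strand", "gene_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genes within k loci of an anchor gene
#'
#' The proximity candidate track: fungal transporters are often encoded near
#' the biosynthesis genes of their substrate, so the screen admits the `k`
#' genes up- and downstream of the citrate synthase gene *citA*. Distance is
#' measured in gene ordinals after sorting each contig by coordinates (not in
#' base pairs, and ignoring strand); the anchor itself is excluded and the
#' window is truncated at contig ends.
#'
#' @param loci data.frame as from [read_loci()]; row order is irrelevant.
#' @param anchor gene id present exactly once.
#' @param k window half-width in genes (default 10).
#' @return character vector of gene ids (at most `2k`).
#' @export
neighbourhood <- function(loci, anchor, k = 10) {
  if (k < 0) stop("k must be >= 0")
  hits <- which(loci$gene_id == anchor)
  if (length(hits) == 0) stop("anchor gene not found: ", anchor)
  if (length(hits) > 1) stop("anchor gene duplicated: ", anchor)
  ctg <- loci$contig[hits]
  sub <- loci[loci$contig == ctg, , drop = FALSE]
  sub <- sub[order(sub$start, sub$end, sub$gene_id), , drop = FALSE]
  a <- which(sub$gene_id == anchor)
  d <- abs(seq_len(nrow(sub)) - a)
  sub$gene_id[d >= 1 & d <= k]
}
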