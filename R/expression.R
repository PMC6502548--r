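#' Construct an expression matrix for the five-condition study
#'
#' Bundles a gene x sample integer count matrix with the sample metadata
#' (condition label + replicate index per sample), per-gene lengths and the
#' read length. These are the inputs needed by [cpm()], [av_nt_cov()] and
#' [de_contrast()].
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param sample_meta data.frame with columns `sample`, `condition` (display
#'   labels from [study_conditions()]) and `replicate`; one row per column of
#'   `counts`.
#' @param gene_lengths named numeric vector of gene lengths in nucleotides.
#' @param read_length read length in nucleotides (default 100).
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, sample_meta, gene_lengths,
                              read_length = 100) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  if (!all(c("sample", "condition", "replicate") %in% names(sample_meta)))
    stop("sample_meta needs columns sample, condition, replicate")
  if (!setequal(sample_meta$sample, colnames(counts)) ||
      nrow(sample_meta) != ncol(counts))
    stop("sample_meta$sample must match the columns of counts")
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample), ,
                             drop = FALSE]
  bad <- setdiff(unique(sample_meta$condition), study_conditions())
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         "; valid labels are: ", paste(study_conditions(), collapse = ", "))
  if (!all(rownames(counts) %in% names(gene_lengths)))
    stop("gene_lengths missing for some genes")
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(gene_lengths <= 0)) stop("gene_lengths must be positive")
  structure(list(gene_ids = rownames(counts),
                 counts = counts,
                 sample_meta = sample_meta,
                 gene_lengths = gene_lengths,
                 read_length = read_length),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d conditions)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sample_meta$condition))))
  invisible(x)
}

samples_of <- function(m, condition) {
  s <- m$sample_meta$sample[m$sample_meta$condition == condition]
  if (!length(s))
    stop("unknown condition label: ", condition,
         "; conditions present: ",
         paste(unique(m$sample_meta$condition), collapse = ", "))
  s
}

#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / libsize[s] * 1e6`, where the library size is
#' the column sum. A gene is considered expressed when its CPM is at least 1.
#'
#' @param m an [expression_matrix()].
#' @return numeric gene x sample matrix of CPM values.
#' @export
cpm <- function(m) {
  libsize <- colSums(m$counts)
  zero <- libsize == 0
  if (any(zero))
    stop("sample(s) with zero total counts: ",
         paste(colnames(m$counts)[zero], collapse = ", "))
  sweep(m$counts, 2, libsize, "/") * 1e6
}

#' Average nucleotide coverage per condition
#'
#' For each replicate, `cov = counts * read_length / gene_length` (the mean
#' per-base read depth over the gene); the mean and sample standard deviation
#' across the condition's replicates are returned (sd 0 for one replicate).
#' This is the expression unit of the candidate filter cascade: candidates
#' require avNtCov >= 1 in all conditions and >= 50 in the two key
#' citrate-producing conditions.
#'
#' @param m an [expression_matrix()].
#' @param condition a condition display label present in `m`.
#' @return data.frame with columns `gene_id`, `mean`, `sd`.
#' @export
av_nt_cov <- function(m, condition) {
  smp <- samples_of(m, condition)
  cov <- m$counts[, smp, drop = FALSE] * m$read_length / m$gene_lengths
  data.frame(gene_id = m$gene_ids,
             mean = rowMeans(cov),
             sd = if (length(smp) > 1) apply(cov, 1, sd) else 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential-expression contrast between two conditions
#'
#' Computes, per gene, `log2fc = log2((meanCPM_test + pc) / (meanCPM_ref +
#' pc))` with pseudocount `pc`, a two-sided exact conditional binomial test on
#' the pooled replicate counts (conditioning on the gene's total, with success
#' probability the test group's share of the summed library sizes; doubled
#' smaller-tail convention), and Benjamini-Hochberg FDR over all genes in the
#' matrix. Genes with zero pooled counts in both groups get `NA` log2fc,
#' p-value and FDR, mirroring the undefined ("#N/A") entries of the published
#' shortlist.
#'
#' @param m an [expression_matrix()].
#' @param test,ref condition display labels (test vs reference).
#' @param pseudocount pseudocount added to both mean CPMs (default 0.5).
#' @return a `contrast_result` data.frame with columns `gene_id`, `log2fc`,
#'   `pvalue`, `fdr`, `mean_cov_test`, `sd_cov_test`, `mean_cov_ref`,
#'   `sd_cov_ref`; attributes `test` and `ref` carry the condition labels.
#' @export
de_contrast <- function(m, test, ref, pseudocount = 0.5) {
  if (identical(test, ref)) stop("test and ref conditions must differ")
  st <- samples_of(m, test)
  sr <- samples_of(m, ref)
  cp <- cpm(m)
  mean_t <- rowMeans(cp[, st, drop = FALSE])
  mean_r <- rowMeans(cp[, sr, drop = FALSE])
  log2fc <- log2((mean_t + pseudocount) / (mean_r + pseudocount))

  xt <- rowSums(m$counts[, st, drop = FALSE])
  xr <- rowSums(m$counts[, sr, drop = FALSE])
  Nt <- sum(colSums(m$counts)[st])
  Nr <- sum(colSums(m$counts)[sr])
  p0 <- Nt / (Nt + Nr)
  n <- xt + xr
  # exact conditional binomial test, doubled smaller tail
  lower <- pbinom(xt, n, p0)
  upper <- pbinom(xt - 1, n, p0, lower.tail = FALSE)
  pvalue <- pmin(1, 2 * pmin(lower, upper))
  undef <- n == 0
  pvalue[undef] <- NA_real_
  log2fc[undef] <- NA_real_
  fdr <- rep(NA_real_, length(pvalue))
  ok <- !is.na(pvalue)
  fdr[ok] <- p.adjust(pvalue[ok], method = "BH")

  ct <- av_nt_cov(m, test)
  cr <- av_nt_cov(m, ref)
  out <- data.frame(gene_id = m$gene_ids, log2fc = log2fc, pvalue = pvalue,
                    fdr = fdr,
                    mean_cov_test = ct$mean, sd_cov_test = ct$sd,
                    mean_cov_ref = cr$mean, sd_cov_ref = cr$sd,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "test") <- test
  attr(out, "ref") <- ref
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Is a gene up-regulated in a contrast?
#'
#' Two admission modes are used by the filter cascade:
#' * `"lenient"`: `log2fc > 0`. The default: the published shortlist keeps
#'   rows with small and non-significant fold-changes, so the strict
#'   differential-expression threshold cannot have been the gate for every
#'   track.
#' * `"strict"`: `log2fc >= 0.58` and `fdr <= 0.05`, the thresholds used to
#'   call genome-wide differential expression.
#'
#' Undefined (NA) fold-changes are never up-regulated.
#'
#' @param cr a `contrast_result` from [de_contrast()].
#' @param gene a gene id present in `cr`.
#' @param mode `"lenient"` or `"strict"`.
#' @return logical scalar.
#' @export
is_upregulated <- function(cr, gene, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  i <- match(gene, cr$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene)
  lfc <- cr$log2fc[i]
  if (is.na(lfc)) return(FALSE)
  if (mode == "lenient") lfc > 0 else lfc >= 0.58 && !is.na(cr$fdr[i]) && cr$fdr[i] <= 0.05
}

#' Write a contrast result as TSV
#'
#' Columns mirror the published shortlist layout: coverages are formatted as
#' `"mean ± sd"` with two decimals.
#'
#' @param cr a `contrast_result`.
#' @param path output file path.
#' @export
write_contrast <- function(cr, path) {
  fmt <- function(m, s) ifelse(is.na(m), "− ± −",
                               sprintf("%.2f ± %.2f", m, s))
  out <- data.frame(gene_id = cr$gene_id,
                    log2fc = round(cr$log2fc, 4),
                    pvalue = signif(cr$pvalue, 4),
                    fdr = signif(cr$fdr, 4),
                    cov_test = fmt(cr$mean_cov_test, cr$sd_cov_test),
                    cov_ref = fmt(cr$mean_cov_ref, cr$sd_cov_ref),
                    stringsAsFactors = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# contrast: %s vs %s", attr(cr, "test"), attr(cr, "ref")),
             con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
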