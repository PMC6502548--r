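#' Read a protein FASTA file
#'
#' Ids are header text truncated at the first whitespace; sequences are
#' upper-cased and validated against the 20-letter amino-acid alphabet
#' (plus `-`/`.` gap symbols when `aligned = TRUE`). Duplicate ids and
#' illegal residues are errors; an empty file gives an empty map.
#'
#' @param path FASTA file.
#' @param aligned allow gap characters (for aligned FASTA).
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(setNames(character(), character()))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  allowed <- c(aa_alphabet(), if (aligned) c("-", "."))
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1]]), allowed)
    if (length(bad))
      stop("illegal residue(s) ", paste(bad, collapse = ", "),
           " in record '", ids[i], "'")
  }
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write an expression matrix as a counts TSV
#'
#' Layout: a `# read_length:` comment, then a header of `gene_id`, `length`
#' and one column per sample named `<condition token>_r<replicate>`, then
#' one row of integer counts per gene.
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @export
write_counts <- function(m, path) {
  df <- data.frame(gene_id = m$gene_ids,
                   length = unname(m$gene_lengths),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m$counts)))
    df[[colnames(m$counts)[j]]] <- as.integer(m$counts[, j])
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(sprintf("# read_length: %d", as.integer(m$read_length)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts TSV into an expression matrix
#'
#' The inverse of [write_counts()]: sample columns must be named
#' `<condition token>_r<replicate>` over the five-condition vocabulary
#' (see [study_conditions()]); counts must be non-negative integers.
#'
#' @param path counts TSV.
#' @param read_length read length in nt; overrides the file's
#'   `# read_length:` comment when given.
#' @return an [expression_matrix()].
#' @export
read_counts <- function(path, read_length = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(read_length)) {
    read_length <- if (grepl("^# read_length:", first))
      as.integer(sub("^# read_length:\\s*", "", first)) else 100L
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!all(c("gene_id", "length") %in% names(df)))
    stop("counts table needs gene_id and length columns")
  sample_cols <- setdiff(names(df), c("gene_id", "length"))
  tok <- sub("_r[0-9]+$", "", sample_cols)
  rep_idx <- suppressWarnings(as.integer(sub("^.*_r", "", sample_cols)))
  bad <- sample_cols[!tok %in% .condition_map$token | is.na(rep_idx)]
  if (length(bad))
    stop("sample column(s) with unknown condition token: ",
         paste(bad, collapse = ", "),
         "; valid tokens are: ", paste(.condition_map$token, collapse = ", "))
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  if (any(is.na(counts)) || any(counts != round(counts)) || any(counts < 0))
    stop("counts must be non-negative integers")
  rownames(counts) <- df$gene_id
  expression_matrix(
    counts,
    data.frame(sample = sample_cols, condition = condition_label(tok),
               replicate = rep_idx, stringsAsFactors = FALSE),
    setNames(df$length, df$gene_id),
    read_length = read_length)
}

#' Read a pipeline configuration file
#'
#' A YAML (or plain `key: value`) file whose keys override the defaults of
#' [shortlist_config()] and, under `sim:`, of [sim_config()].
#'
#' @param path YAML file.
#' @return list with fields `shortlist` (a [shortlist_config()]) and `sim`
#'   (a list of [sim_config()] overrides).
#' @export
read_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  sc_args <- raw[intersect(names(raw),
                           names(formals(shortlist_config)))]
  list(shortlist = do.call(shortlist_config, sc_args),
       sim = raw$sim %||% list())
}

file_hashes <- function(paths) {
  h <- tools::md5sum(paths[file.exists(paths)])
  as.list(h)
}
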