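#' Kyte-Doolittle hydropathy scale
#'
#' @return named numeric vector over the 20 standard amino acids.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}

#' Count putative transmembrane helices by sliding-window hydropathy
#'
#' A simple deterministic stand-in for an external transmembrane-topology
#' predictor: scan left to right; on reaching a window of `window` residues
#' whose mean Kyte-Doolittle hydropathy exceeds `threshold`, first advance
#' to the local maximum of the window mean (so a helix is counted at its
#' core rather than at the first boundary window that scrapes past the
#' threshold), then count it and consume the whole window before scanning
#' on. Counting at the local maximum makes the count invariant to prepended
#' hydrophilic sequence.
#'
#' @param seq protein sequence (single string over the 20-letter alphabet).
#' @param window window width in residues (19, a typical helix span).
#' @param threshold mean-hydropathy cutoff (1.6).
#' @return integer helix count; sequences shorter than `window` give 0 with a
#'   warning.
#' @export
hydropathy_tm_count <- function(seq, window = 19L, threshold = 1.6) {
  aa <- strsplit(seq, "")[[1]]
  if (length(aa) < window) {
    warning("sequence shorter than window (", length(aa), " < ", window,
            "); returning 0")
    return(0L)
  }
  kd <- kyte_doolittle()
  bad <- setdiff(unique(aa), names(kd))
  if (length(bad))
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  h <- unname(kd[aa])
  cs <- c(0, cumsum(h))
  wmean <- (cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]) / window
  n <- 0L
  i <- 1L
  last <- length(wmean)
  while (i <= last) {
    if (wmean[i] > threshold) {
      while (i < last && wmean[i + 1] > wmean[i]) i <- i + 1L
      n <- n + 1L
      i <- i + window
    } else i <- i + 1L
  }
  n
}

#' Parse a transmembrane-topology prediction table
#'
#' Expects a TSV with columns `protein_id`, `tm_helices` and optionally
#' `localisation` (defaulting to `"unknown"` when absent). Helix counts must
#' be non-negative integers; duplicate protein ids are an error.
#'
#' @param path TSV file.
#' @return data.frame with columns `protein_id`, `tm_helices`,
#'   `localisation`.
#' @export
parse_topology_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  empty <- data.frame(protein_id = character(), tm_helices = integer(),
                      localisation = character(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- "protein_id" %in% header
  body <- if (has_header) lines[-1] else lines
  if (!length(body)) return(empty)
  parts <- strsplit(body, "\t", fixed = TRUE)
  offset <- if (has_header) 1L else 0L
  recs <- lapply(seq_along(parts), function(i) {
    f <- parts[[i]]
    if (length(f) < 2)
      stop("line ", i + offset, ": expected at least 2 tab-separated fields")
    tm <- suppressWarnings(as.numeric(f[2]))
    if (is.na(tm) || tm < 0 || tm != round(tm))
      stop("line ", i + offset, ": tm_helices must be a non-negative integer, got '",
           f[2], "'")
    data.frame(protein_id = f[1], tm_helices = as.integer(tm),
               localisation = if (length(f) >= 3 && nzchar(f[3])) f[3] else "unknown",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  dup <- out$protein_id[duplicated(out$protein_id)]
  if (length(dup))
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  out
}

#' Write a topology table (inverse of [parse_topology_table()])
#'
#' @param df data.frame with columns `protein_id`, `tm_helices` and
#'   optionally `localisation`.
#' @param path output TSV path.
#' @export
write_topology_table <- function(df, path) {
  if (!"localisation" %in% names(df)) df$localisation <- "unknown"
  write.table(df[, c("protein_id", "tm_helices", "localisation")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Does a protein have at least one predicted transmembrane helix?
#'
#' The first stringent criterion of the homology track: a transporter must be
#' membrane-embedded.
#'
#' @param record one row of a topology table (list or data.frame row with a
#'   `tm_helices` field), or a bare helix count.
#' @return logical scalar.
#' @export
has_tm <- function(record) {
  tm <- if (is.numeric(record)) record else record$tm_helices
  tm >= 1
}
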