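#' Construct a profile hidden Markov model
#'
#' Low-level constructor; most users build models from a seed alignment with
#' [build_phmm()]. The model is a classic match/insert/delete profile with
#' per-state transition distributions over `{M->M, M->I, M->D}`,
#' `{I->M, I->I}` and `{D->M, D->D}` (transition index `k = 0` is the begin
#' state; `M_{K+1}` is the end state; `D->D` and `M->D` out of the last
#' column are structural zeros). Insert states emit the background
#' distribution. Scoring ([forward_bits()]) adds free flanking insert states
#' at both ends, so a full-length multi-domain protein is aligned globally to
#' the model but pays nothing for unaligned termini.
#'
#' @param match_emissions K x 20 matrix of match emission probabilities
#'   (columns in alphabetical amino-acid order).
#' @param background length-20 background amino-acid distribution.
#' @param trans list with numeric fields `tMM`, `tMI`, `tMD`, `tIM`, `tII`
#'   (length K+1, index k+1 holds transitions out of state k = 0..K) and
#'   `tDM`, `tDD` (length K, transitions out of `D_k`, k = 1..K).
#' @return an object of class `profile_hmm`.
#' @export
profile_hmm <- function(match_emissions, background, trans) {
  match_emissions <- as.matrix(match_emissions)
  K <- nrow(match_emissions)
  if (K < 1) stop("model must have at least one match state")
  if (ncol(match_emissions) != 20 || length(background) != 20)
    stop("emissions must be over the 20-letter amino-acid alphabet")
  tol <- 1e-9
  if (any(abs(rowSums(match_emissions) - 1) > tol))
    stop("match emission rows must sum to 1")
  if (abs(sum(background) - 1) > tol) stop("background must sum to 1")
  if (any(background <= 0)) stop("background must be strictly positive")
  need <- c("tMM", "tMI", "tMD", "tIM", "tII", "tDM", "tDD")
  if (!all(need %in% names(trans))) stop("trans needs fields: ",
                                         paste(need, collapse = ", "))
  for (f in c("tMM", "tMI", "tMD", "tIM", "tII"))
    if (length(trans[[f]]) != K + 1) stop(f, " must have length K+1")
  for (f in c("tDM", "tDD"))
    if (length(trans[[f]]) != K) stop(f, " must have length K")
  m_sum <- trans$tMM + trans$tMI + trans$tMD
  i_sum <- trans$tIM + trans$tII
  d_sum <- trans$tDM + trans$tDD
  if (any(abs(m_sum - 1) > tol) || any(abs(i_sum - 1) > tol) ||
      any(abs(d_sum - 1) > tol))
    stop("each per-state transition distribution must sum to 1")
  if (trans$tMD[K + 1] > tol || trans$tDD[K] > tol)
    stop("transitions into D beyond the last match column must be 0")
  structure(list(n_match = K,
                 alphabet = aa_alphabet(),
                 match_emissions = unname(match_emissions),
                 background = unname(background),
                 trans = lapply(trans[need], unname)),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm: %d match states over the 20-letter alphabet\n",
              x$n_match))
  invisible(x)
}

msa_to_matrix <- function(msa) {
  if (is(msa, "AAStringSet")) msa <- setNames(as.character(msa), names(msa))
  if (length(msa) < 2) stop("need at least 2 aligned sequences")
  if (length(unique(nchar(msa))) != 1)
    stop("ragged alignment: sequences have unequal aligned lengths")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  m[m == "."] <- "-"
  bad <- setdiff(unique(as.vector(m)), c(aa_alphabet(), "-"))
  if (length(bad))
    stop("alignment contains non-amino-acid symbol(s): ",
         paste(bad, collapse = ", "))
  m
}

#' Build a profile HMM from a seed multiple alignment
#'
#' Columns whose gap fraction is below `gap_threshold` become match states;
#' other columns are treated as inserts. Emission and transition
#' probabilities are maximum-likelihood counts with a Laplace pseudocount.
#' The background distribution is the overall amino-acid frequency of the
#' alignment (gaps excluded, same pseudocount). Alignment paths that would
#' require the `I->D` or `D->I` transitions (absent from this model's
#' transition set) contribute their counts to `I->M` and `D->M`.
#'
#' @param msa named character vector (or `AAStringSet`) of equal-length
#'   aligned sequences over the 20 amino acids plus `-`/`.` gaps.
#' @param gap_threshold columns with gap fraction below this become match
#'   states (default 0.5).
#' @param pseudocount Laplace pseudocount for emissions and transitions
#'   (default 1).
#' @return a [profile_hmm()].
#' @export
build_phmm <- function(msa, gap_threshold = 0.5, pseudocount = 1.0) {
  m <- msa_to_matrix(msa)
  n_seq <- nrow(m)
  gap_frac <- colMeans(m == "-")
  is_match <- gap_frac < gap_threshold
  K <- sum(is_match)
  if (K == 0) stop("no match columns: every column is at/above the gap threshold")
  alpha <- aa_alphabet()

  # emissions
  em <- matrix(pseudocount, K, 20)
  match_cols <- which(is_match)
  for (j in seq_len(K)) {
    col <- m[, match_cols[j]]
    tab <- table(factor(col[col != "-"], levels = alpha))
    em[j, ] <- em[j, ] + as.numeric(tab)
  }
  em <- em / rowSums(em)

  bg_tab <- table(factor(m[m != "-"], levels = alpha))
  background <- (as.numeric(bg_tab) + pseudocount) /
    (sum(bg_tab) + 20 * pseudocount)

  # transition counts along each sequence's implied state path
  cMM <- cMI <- cMD <- cIM <- cII <- rep(0, K + 1)
  cDM <- cDD <- rep(0, K)
  col_state <- ifelse(is_match, "match", "insert")
  col_k <- cumsum(is_match) # match index reached at/after each column
  for (s in seq_len(n_seq)) {
    path <- list() # sequence of c(type, k)
    for (j in seq_len(ncol(m))) {
      res <- m[s, j] != "-"
      if (col_state[j] == "match") {
        path[[length(path) + 1]] <- c(if (res) "M" else "D", col_k[j])
      } else if (res) {
        path[[length(path) + 1]] <- c("I", col_k[j])
      }
    }
    full <- c(list(c("M", 0)), path, list(c("M", K + 1))) # begin and end
    for (t in seq_len(length(full) - 1)) {
      a <- full[[t]]; b <- full[[t + 1]]
      k <- as.integer(a[2])
      ab <- paste0(a[1], b[1])
      if (a[1] == "M") {
        if (ab == "MM") cMM[k + 1] <- cMM[k + 1] + 1
        else if (ab == "MI") cMI[k + 1] <- cMI[k + 1] + 1
        else cMD[k + 1] <- cMD[k + 1] + 1
      } else if (a[1] == "I") {
        if (ab == "II") cII[k + 1] <- cII[k + 1] + 1
        else cIM[k + 1] <- cIM[k + 1] + 1 # I->M; I->D folded in
      } else {
        if (ab == "DD") cDD[k] <- cDD[k] + 1
        else cDM[k] <- cDM[k] + 1 # D->M; D->I folded in
      }
    }
  }
  # Laplace pseudocount over each state's allowed transition set; the final
  # column cannot transition into a delete state
  pM <- cbind(cMM, cMI, cMD) + pseudocount
  pM[K + 1, 3] <- 0
  pM <- pM / rowSums(pM)
  pI <- cbind(cIM, cII) + pseudocount
  pI <- pI / rowSums(pI)
  pD <- cbind(cDM, cDD) + pseudocount
  pD[K, 2] <- 0
  pD <- pD / rowSums(pD)

  profile_hmm(em, background,
              list(tMM = pM[, 1], tMI = pM[, 2], tMD = pM[, 3],
                   tIM = pI[, 1], tII = pI[, 2],
                   tDM = pD[, 1], tDD = pD[, 2]))
}

seq_to_idx <- function(hmm, seq) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq))
    stop("sequence must be a single non-empty string")
  aa <- strsplit(toupper(seq), "")[[1]]
  idx <- match(aa, hmm$alphabet)
  if (anyNA(idx))
    stop("unknown residue(s): ",
         paste(unique(aa[is.na(idx)]), collapse = ", "))
  idx - 1L
}

phmm_em_odds <- function(hmm) {
  sweep(hmm$match_emissions, 2, hmm$background, "/")
}

#' Forward log-odds score of a sequence under a profile HMM
#'
#' `log2(P(seq | hmm) / P(seq | background))`, summing over all alignments of
#' the sequence to the model (forward recursion) with free flanking inserts
#' at both ends. [viterbi_bits()] scores only the single best alignment and
#' is therefore a lower bound on the forward score.
#'
#' @param hmm a [profile_hmm()].
#' @param seq a single non-empty protein string; unknown residues are an
#'   error, never skipped.
#' @return log-odds score in bits.
#' @export
forward_bits <- function(hmm, seq) {
  idx <- seq_to_idx(hmm, seq)
  t <- hmm$trans
  phmm_forward_bits_cpp(idx, phmm_em_odds(hmm), t$tMM, t$tMI, t$tMD,
                        t$tIM, t$tII, t$tDM, t$tDD)
}

#' @rdname forward_bits
#' @export
viterbi_bits <- function(hmm, seq) {
  idx <- seq_to_idx(hmm, seq)
  t <- hmm$trans
  phmm_viterbi_bits_cpp(idx, phmm_em_odds(hmm), t$tMM, t$tMI, t$tMD,
                        t$tIM, t$tII, t$tDM, t$tDD)
}

#' Scan a proteome with a profile HMM
#'
#' Scores every protein with [forward_bits()] and returns the top `top_n`
#' hits sorted by descending score, ties broken by ascending protein id.
#'
#' @param hmm a [profile_hmm()].
#' @param proteome named character vector of protein sequences.
#' @param top_n number of hits to keep (at most the proteome size).
#' @return data.frame with columns `protein_id`, `bits`, `rank`.
#' @export
scan_proteome <- function(hmm, proteome, top_n) {
  if (length(proteome) == 0) stop("proteome is empty")
  if (is.null(names(proteome)) || any(!nzchar(names(proteome))))
    stop("proteome sequences must be named")
  if (top_n < 1) stop("top_n must be >= 1")
  bits <- vapply(proteome, function(s) forward_bits(hmm, s), 0)
  ord <- order(-bits, names(proteome))
  n <- min(top_n, length(proteome))
  data.frame(protein_id = names(proteome)[ord][seq_len(n)],
             bits = unname(bits[ord][seq_len(n)]),
             rank = seq_len(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialise / deserialise a profile HMM as plain text
#'
#' Format: a comment header, `K`, `ALPHABET`, a `BG` line (20 background
#' probabilities), one `MATCH k` line per match state (20 emission
#' probabilities) and one `TRANS k` line per state k = 0..K with the seven
#' transition probabilities `tMM tMI tMD tIM tII tDM tDD` (`tDM`/`tDD` are
#' `NA` for k = 0, which has no delete state). Probabilities are written in
#' full precision and round-trip exactly.
#'
#' @param hmm a [profile_hmm()].
#' @param path file path.
#' @return `write_phmm` the path invisibly; `read_phmm` a [profile_hmm()].
#' @export
write_phmm <- function(hmm, path) {
  num <- function(x) paste(format(x, digits = 17), collapse = " ")
  K <- hmm$n_match
  lines <- c("# cexscreen profile HMM v1",
             paste("K", K),
             paste("ALPHABET", paste(hmm$alphabet, collapse = "")),
             paste("BG", num(hmm$background)),
             vapply(seq_len(K), function(k)
               paste("MATCH", k, num(hmm$match_emissions[k, ])), ""),
             vapply(0:K, function(k) {
               t <- hmm$trans
               dm <- if (k == 0) "NA" else format(t$tDM[k], digits = 17)
               dd <- if (k == 0) "NA" else format(t$tDD[k], digits = 17)
               paste("TRANS", k,
                     format(t$tMM[k + 1], digits = 17),
                     format(t$tMI[k + 1], digits = 17),
                     format(t$tMD[k + 1], digits = 17),
                     format(t$tIM[k + 1], digits = 17),
                     format(t$tII[k + 1], digits = 17), dm, dd)
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phmm
#' @export
read_phmm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, " +")
  tag <- vapply(fields, `[`, "", 1)
  K <- as.integer(fields[[which(tag == "K")]][2])
  bg <- as.numeric(fields[[which(tag == "BG")]][-1])
  em <- matrix(0, K, 20)
  for (f in fields[tag == "MATCH"])
    em[as.integer(f[2]), ] <- as.numeric(f[-(1:2)])
  tMM <- tMI <- tMD <- tIM <- tII <- rep(0, K + 1)
  tDM <- tDD <- rep(0, K)
  for (f in fields[tag == "TRANS"]) {
    k <- as.integer(f[2])
    v <- suppressWarnings(as.numeric(f[3:9]))
    tMM[k + 1] <- v[1]; tMI[k + 1] <- v[2]; tMD[k + 1] <- v[3]
    tIM[k + 1] <- v[4]; tII[k + 1] <- v[5]
    if (k >= 1) { tDM[k] <- v[6]; tDD[k] <- v[7] }
  }
  profile_hmm(em, bg, list(tMM = tMM, tMI = tMI, tMD = tMD,
                           tIM = tIM, tII = tII, tDM = tDM, tDD = tDD))
}
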