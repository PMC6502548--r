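# Independent brute-force oracles. These deliberately re-derive results by
# exhaustive enumeration or by the textbook formula, sharing no code with the
# implementations they check.

# ---- profile HMM: forward probability by explicit path enumeration ---------

# Sum of odds over all core paths emitting exactly `sub` (vector of 1-based
# alphabet indices), entering at the begin state M_0 and leaving at E =
# M_{K+1}. Recursion over (state type, state index, residues emitted).
oracle_core_odds <- function(hmm, sub) {
  K <- hmm$n_match
  t <- hmm$trans
  em <- sweep(hmm$match_emissions, 2, hmm$background, "/")
  n <- length(sub)
  rec <- function(type, k, pos) {
    if (type == "M" && k == K + 1) return(if (pos == n) 1 else 0)
    out <- 0
    if (type == "M") {
      if (k + 1 == K + 1) {
        out <- out + t$tMM[k + 1] * rec("M", K + 1, pos)
      } else if (pos < n) {
        out <- out + t$tMM[k + 1] * em[k + 1, sub[pos + 1]] *
          rec("M", k + 1, pos + 1)
      }
      if (pos < n) out <- out + t$tMI[k + 1] * rec("I", k, pos + 1)
      if (k + 1 <= K) out <- out + t$tMD[k + 1] * rec("D", k + 1, pos)
    } else if (type == "I") {
      if (k + 1 == K + 1) {
        out <- out + t$tIM[k + 1] * rec("M", K + 1, pos)
      } else if (pos < n) {
        out <- out + t$tIM[k + 1] * em[k + 1, sub[pos + 1]] *
          rec("M", k + 1, pos + 1)
      }
      if (pos < n) out <- out + t$tII[k + 1] * rec("I", k, pos + 1)
    } else { # D_k
      if (k + 1 == K + 1) {
        out <- out + t$tDM[k] * rec("M", K + 1, pos)
      } else if (pos < n) {
        out <- out + t$tDM[k] * em[k + 1, sub[pos + 1]] *
          rec("M", k + 1, pos + 1)
      }
      if (k + 1 <= K) out <- out + t$tDD[k] * rec("D", k + 1, pos)
    }
    out
  }
  rec("M", 0, 0)
}

# Forward odds with free flanks: sum over every split of the sequence into
# N-flank prefix / core / C-flank suffix (flank residues contribute odds 1).
oracle_forward_bits <- function(hmm, seq) {
  idx <- match(strsplit(seq, "")[[1]], hmm$alphabet)
  L <- length(idx)
  total <- 0
  for (i in 0:L) {
    for (j in i:L) {
      total <- total + oracle_core_odds(hmm, if (j > i) idx[(i + 1):j] else
        integer())
    }
  }
  log2(total)
}

# Core-model probability of emitting exactly `seq` (no flanks): used for the
# "probabilities of a fixed length sum to <= 1" property.
oracle_core_prob <- function(hmm, seq) {
  idx <- match(strsplit(seq, "")[[1]], hmm$alphabet)
  odds <- oracle_core_odds(hmm, idx)
  odds * prod(hmm$background[idx])
}

# ---- pairwise alignment: exhaustive global affine-gap enumeration ----------

# Enumerates every global alignment of a and b, scoring with the affine
# convention "a gap run of length L costs gap_open + L * gap_extend", and
# returns the best score plus the set of percent identities among
# score-optimal alignments (identity = matches / alignment length, gaps
# included).
oracle_align <- function(a, b, submat, gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best <- new.env(parent = emptyenv())
  best$score <- -Inf
  best$idents <- numeric()
  walk <- function(i, j, prev, score, nm, len) {
    if (i > la && j > lb) {
      if (score > best$score + 1e-9) {
        best$score <- score
        best$idents <- 100 * nm / len
      } else if (abs(score - best$score) <= 1e-9) {
        best$idents <- unique(c(best$idents, 100 * nm / len))
      }
      return(invisible())
    }
    if (i <= la && j <= lb)
      walk(i + 1, j + 1, "M", score + submat[av[i], bv[j]],
           nm + (av[i] == bv[j]), len + 1)
    if (i <= la)
      walk(i + 1, j, "GA",
           score - gap_extend - if (prev == "GA") 0 else gap_open,
           nm, len + 1)
    if (j <= lb)
      walk(i, j + 1, "GB",
           score - gap_extend - if (prev == "GB") 0 else gap_open,
           nm, len + 1)
  }
  walk(1, 1, "start", 0, 0, 0)
  list(score = best$score, identities = best$idents)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# ---- Benjamini-Hochberg by the hand formula --------------------------------

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# ---- misc fixtures ----------------------------------------------------------

random_protein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                  "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a small hand-set profile HMM for oracle comparisons
tiny_hmm <- function(K = 2, seed = 1) {
  set.seed(seed)
  em <- matrix(stats::rgamma(K * 20, 1), K, 20)
  em <- em / rowSums(em)
  bg <- stats::rgamma(20, 2); bg <- bg / sum(bg)
  rdist <- function(n) { x <- stats::rgamma(n, 1) + 0.05; x / sum(x) }
  tMM <- tMI <- tMD <- tIM <- tII <- numeric(K + 1)
  for (k in 0:K) {
    m <- if (k == K) c(rdist(2), 0) else rdist(3)
    tMM[k + 1] <- m[1]; tMI[k + 1] <- m[2]; tMD[k + 1] <- m[3]
    i2 <- rdist(2)
    tIM[k + 1] <- i2[1]; tII[k + 1] <- i2[2]
  }
  tDM <- tDD <- numeric(K)
  for (k in seq_len(K)) {
    d <- if (k == K) c(1, 0) else rdist(2)
    tDM[k] <- d[1]; tDD[k] <- d[2]
  }
  profile_hmm(em, bg, list(tMM = tMM, tMI = tMI, tMD = tMD,
                           tIM = tIM, tII = tII, tDM = tDM, tDD = tDD))
}

# minimal five-condition expression matrix from a matrix of per-condition
# mean counts (2 replicates each, equal library scaling)
tiny_expression <- function(cond_means, gene_lengths = NULL,
                            read_length = 100, seed = 1) {
  set.seed(seed)
  conds <- study_conditions()
  stopifnot(ncol(cond_means) == 5)
  colnames(cond_means) <- conds
  n <- nrow(cond_means)
  if (is.null(rownames(cond_means)))
    rownames(cond_means) <- sprintf("g%03d", seq_len(n))
  if (is.null(gene_lengths))
    gene_lengths <- setNames(rep(1000, n), rownames(cond_means))
  meta <- data.frame(sample = paste0(rep(condition_token(conds), each = 2),
                                     "_r", 1:2),
                     condition = rep(conds, each = 2),
                     replicate = rep(1:2, 5), stringsAsFactors = FALSE)
  counts <- matrix(0, n, 10, dimnames = list(rownames(cond_means),
                                             meta$sample))
  for (j in seq_len(10)) counts[, j] <- round(cond_means[, meta$condition[j]])
  expression_matrix(counts, meta, gene_lengths, read_length)
}
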