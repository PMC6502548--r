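test_that("building from identical ungapped sequences gives the closed-form Laplace emissions", {
  msa <- c(s1 = "MKVLF", s2 = "MKVLF", s3 = "MKVLF")
  hmm <- build_phmm(msa)
  expect_equal(hmm$n_match, 5)
  alpha <- hmm$alphabet
  obs <- strsplit("MKVLF", "")[[1]]
  for (k in 1:5) {
    expect_equal(hmm$match_emissions[k, match(obs[k], alpha)], (3 + 1) / (3 + 20))
    expect_equal(sum(hmm$match_emissions[k, ]), 1)
  }
})

test_that("gap-heavy columns become insert states at the threshold", {
  # column 3 has 3/5 gaps (60%): below threshold 0.5 it is not a match state
  msa <- c(a = "MKV", b = "MKV", c = "MK-", d = "MK-", e = "MK-")
  hmm <- build_phmm(msa, gap_threshold = 0.5)
  expect_equal(hmm$n_match, 2)
  # at a permissive threshold it is
  expect_equal(build_phmm(msa, gap_threshold = 0.7)$n_match, 3)
})

test_that("all model distributions normalise on a random alignment", {
  set.seed(42)
  msa <- setNames(vapply(1:4, function(i) {
    s <- strsplit(random_protein(10), "")[[1]]
    s[sample(10, 2)] <- "-"
    paste(s, collapse = "")
  }, ""), paste0("s", 1:4))
  hmm <- build_phmm(msa)
  expect_true(all(abs(rowSums(hmm$match_emissions) - 1) < 1e-9))
  expect_equal(sum(hmm$background), 1)
  t <- hmm$trans
  expect_true(all(abs(t$tMM + t$tMI + t$tMD - 1) < 1e-9))
  expect_true(all(abs(t$tIM + t$tII - 1) < 1e-9))
  expect_true(all(abs(t$tDM + t$tDD - 1) < 1e-9))
})

test_that("degenerate alignments are rejected", {
  expect_error(build_phmm(c(a = "MKV", b = "MK")), "ragged")
  expect_error(build_phmm(c(a = "---", b = "---")), "no match columns")
  expect_error(build_phmm(c(a = "MKV")), "at least 2")
})

test_that("a background-emitting single-state model scores ~0 bits on any single residue", {
  em <- matrix(1 / 20, 1, 20)
  bg <- rep(1 / 20, 20)
  hmm <- profile_hmm(em, bg,
                     list(tMM = c(1, 1), tMI = c(0, 0), tMD = c(0, 0),
                          tIM = c(1, 1), tII = c(0, 0),
                          tDM = 1, tDD = 0))
  for (res in c("A", "W", "K"))
    expect_equal(forward_bits(hmm, res), 0, tolerance = 1e-12)
})

test_that("forward matches brute-force path enumeration on tiny models", {
  alpha <- aa <- strsplit("ACD", "")[[1]] # reduced alphabet for enumeration
  for (K in 1:2) {
    for (seed in 1:3) {
      hmm <- tiny_hmm(K = K, seed = seed)
      seqs <- c(aa, apply(expand.grid(aa, aa), 1, paste, collapse = ""))
      for (s in seqs) {
        expect_equal(forward_bits(hmm, s), oracle_forward_bits(hmm, s),
                     tolerance = 1e-9, label = paste("K", K, "seed", seed, s))
      }
    }
  }
})

test_that("forward dominates Viterbi on random model/sequence pairs", {
  set.seed(7)
  for (i in 1:100) {
    hmm <- tiny_hmm(K = sample(1:4, 1), seed = i)
    s <- random_protein(sample(1:8, 1))
    expect_gte(forward_bits(hmm, s), viterbi_bits(hmm, s) - 1e-9)
  }
})

test_that("core emission probabilities of a fixed length sum to at most 1", {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  hmm <- tiny_hmm(K = 2, seed = 5)
  p1 <- sum(vapply(aa20, function(s) oracle_core_prob(hmm, s), 0))
  expect_lte(p1, 1 + 1e-9)
  pairs <- apply(expand.grid(aa20, aa20), 1, paste, collapse = "")
  p2 <- sum(vapply(pairs, function(s) oracle_core_prob(hmm, s), 0))
  expect_lte(p2, 1 + 1e-9)
  # lengths 0, 1 and 2 together cannot exceed the total probability budget
  p0 <- oracle_core_prob(hmm, "")
  expect_lte(p0 + p1 + p2, 1 + 1e-9)
})

test_that("unknown residues and empty sequences are hard errors", {
  hmm <- tiny_hmm()
  expect_error(forward_bits(hmm, "MKXV"), "unknown residue")
  expect_error(forward_bits(hmm, ""), "non-empty")
  expect_error(profile_hmm(matrix(numeric(0), 0, 20), rep(1 / 20, 20),
                           list()),
               "at least one match state")
})

test_that("proteome scan ranks a consensus-matching protein first", {
  set.seed(11)
  consensus <- random_protein(40)
  msa <- setNames(c(consensus, vapply(1:4, function(i) {
    s <- strsplit(consensus, "")[[1]]
    pos <- sample(40, 4)
    s[pos] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 4, TRUE)
    paste(s, collapse = "")
  }, "")), paste0("m", 0:4))
  hmm <- build_phmm(msa)
  proteome <- c(decoy1 = random_protein(60), target = consensus,
                decoy2 = random_protein(40))
  hits <- scan_proteome(hmm, proteome, top_n = 3)
  expect_equal(hits$protein_id[1], "target")
  # agrees with scoring every protein directly
  direct <- vapply(proteome, function(s) forward_bits(hmm, s), 0)
  expect_equal(hits$bits, unname(sort(direct, decreasing = TRUE)))
})

test_that("scan truncates to the proteome size and tie-breaks by id", {
  hmm <- tiny_hmm()
  prot <- c(b = "MKVL", a = "MKVL")
  hits <- scan_proteome(hmm, prot, top_n = 5)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$bits[1], hits$bits[2])
  expect_equal(hits$protein_id, c("a", "b")) # identical scores, id order
  expect_equal(hits$rank, 1:2)
  expect_error(scan_proteome(hmm, prot, top_n = 0), "top_n")
})

test_that("scores are invariant to protein id and input order", {
  set.seed(3)
  hmm <- tiny_hmm(K = 3, seed = 2)
  prot <- setNames(vapply(1:5, function(i) random_protein(25), ""),
                   paste0("p", 1:5))
  h1 <- scan_proteome(hmm, prot, 5)
  h2 <- scan_proteome(hmm, rev(setNames(prot, paste0("p", 1:5))), 5)
  expect_equal(setNames(h1$bits, h1$protein_id),
               setNames(h2$bits, h2$protein_id))
})

test_that("model serialisation round-trips exactly", {
  set.seed(9)
  msa <- setNames(vapply(1:3, function(i) random_protein(12), ""),
                  paste0("s", 1:3))
  hmm <- build_phmm(msa)
  path <- withr::local_tempfile(fileext = ".phmm")
  write_phmm(hmm, path)
  back <- read_phmm(path)
  expect_equal(back$match_emissions, hmm$match_emissions)
  expect_equal(back$background, hmm$background)
  expect_equal(back$trans, hmm$trans)
  s <- random_protein(20)
  expect_identical(forward_bits(back, s), forward_bits(hmm, s))
})
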