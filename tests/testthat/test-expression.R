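test_that("CPM is counts over library size times a million", {
  m <- tiny_expression(matrix(rep(c(10, 90), 5), nrow = 2))
  x <- cpm(m)
  expect_true(all(abs(x[1, ] - 1e5) < 1e-9))
  expect_true(all(abs(x[2, ] - 9e5) < 1e-9))
  # columns renormalise to exactly one million
  expect_equal(unname(colSums(x)), rep(1e6, 10), tolerance = 1e-6)
})

test_that("all-zero genes get CPM 0 and zero-total samples are named in the error", {
  m <- tiny_expression(matrix(c(0, 0, 0, 0, 0, 5, 5, 5, 5, 5), nrow = 2,
                              byrow = TRUE,
                              dimnames = list(c("dead", "alive"), NULL)))
  x <- cpm(m)
  expect_true(all(x["dead", ] == 0))
  m0 <- tiny_expression(matrix(0, 2, 5))
  expect_error(cpm(m0), "zero total counts")
  expect_error(cpm(m0), "NW305_minusFe_a_r1")
})

test_that("expressed-gene count at CPM >= 1 matches a naive loop recount", {
  ds <- generate_dataset(sim_config(seed = 21, n_genes = 500))
  m <- as_expression_matrix(ds)
  x <- cpm(m)
  fast <- sum(rowMeans(x) >= 1)
  slow <- 0
  libs <- colSums(m$counts)
  for (g in seq_len(nrow(m$counts))) {
    v <- numeric(ncol(m$counts))
    for (s in seq_len(ncol(m$counts)))
      v[s] <- m$counts[g, s] / libs[s] * 1e6
    if (mean(v) >= 1) slow <- slow + 1
  }
  expect_equal(fast, slow)
})

test_that("average nucleotide coverage follows counts * read_length / gene_length", {
  # 100 counts, read length 100, gene length 1000 -> coverage 10 per replicate
  m <- tiny_expression(matrix(100, 1, 5),
                       gene_lengths = c(g001 = 1000))
  cov <- av_nt_cov(m, "NW186 -Fe_a")
  expect_equal(cov$mean, 10)
  expect_equal(cov$sd, 0)
  expect_error(av_nt_cov(m, "no such condition"), "unknown condition")
})

test_that("coverage mean and sd summarise replicates", {
  # replicates 10 and 12 -> mean 11, sd sqrt(2)
  conds <- study_conditions()
  meta <- data.frame(sample = paste0(rep(condition_token(conds), each = 2),
                                     "_r", 1:2),
                     condition = rep(conds, each = 2),
                     replicate = rep(1:2, 5), stringsAsFactors = FALSE)
  counts <- matrix(100, 1, 10, dimnames = list("g1", meta$sample))
  counts[1, "NW186_minusFe_a_r1"] <- 100
  counts[1, "NW186_minusFe_a_r2"] <- 120
  m <- expression_matrix(counts, meta, c(g1 = 1000), read_length = 100)
  cov <- av_nt_cov(m, "NW186 -Fe_a")
  expect_equal(cov$mean, 11)
  expect_equal(cov$sd, sqrt(2))
})

test_that("log2 fold-change follows the pseudocounted mean-CPM ratio", {
  # equal means cancel regardless of pseudocount
  m <- tiny_expression(matrix(50, 3, 5))
  cr <- de_contrast(m, "NW186 -Fe_a", "NW305 -Fe_a")
  expect_equal(cr$log2fc, rep(0, 3))
  # 200 vs 50 with equal library sizes and a negligible pseudocount -> 2.0
  cm <- matrix(50, 3, 5)
  cm[1, ] <- c(50, 50, 200, 50, 50)  # NW186 -Fe_a is condition 3
  cm[3, ] <- c(250, 250, 100, 250, 250) # balancer: equal library sizes
  m2 <- tiny_expression(cm)
  cr2 <- de_contrast(m2, "NW186 -Fe_a", "NW305 -Fe_a", pseudocount = 1e-9)
  expect_equal(cr2$log2fc[1], 2, tolerance = 1e-3)
  expect_error(de_contrast(m, "NW186 -Fe_a", "NW186 -Fe_a"), "must differ")
})

test_that("contrasts are antisymmetric under pseudocounting", {
  ds <- generate_dataset(sim_config(seed = 5, n_genes = 120))
  m <- as_expression_matrix(ds)
  ab <- de_contrast(m, "NW186 -Fe_a", "NW305 -Fe_a")
  ba <- de_contrast(m, "NW305 -Fe_a", "NW186 -Fe_a")
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
  expect_equal(ab$pvalue, ba$pvalue, tolerance = 1e-9)
})

test_that("BH adjustment matches the hand formula", {
  # worked example: p = (.01, .02, .03, .04) all adjust to .04
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(oracle_bh(p), rep(0.04, 4))
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  set.seed(99)
  for (i in 1:500) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("genes with zero counts in both groups are undefined, not zero", {
  cm <- matrix(100, 3, 5)
  cm[2, ] <- 0
  m <- tiny_expression(cm)
  cr <- de_contrast(m, "NW186 -Fe_a", "NW305 -Fe_a")
  expect_true(is.na(cr$log2fc[2]))
  expect_true(is.na(cr$pvalue[2]))
  expect_true(is.na(cr$fdr[2]))
  expect_false(anyNA(cr$log2fc[-2]))
})

test_that("up-regulation thresholds separate lenient from strict calls", {
  cm <- matrix(100, 3, 5)
  m <- tiny_expression(cm)
  cr <- de_contrast(m, "NW186 -Fe_a", "NW305 -Fe_a")
  # splice in the published values for the threshold logic
  cr$log2fc <- c(3.42, 0.00, 0.60)
  cr$fdr <- c(0.00, 1.00, 0.20)
  expect_true(is_upregulated(cr, cr$gene_id[1], "lenient"))
  expect_true(is_upregulated(cr, cr$gene_id[1], "strict"))
  expect_false(is_upregulated(cr, cr$gene_id[2], "lenient"))
  expect_false(is_upregulated(cr, cr$gene_id[2], "strict"))
  expect_true(is_upregulated(cr, cr$gene_id[3], "lenient"))
  expect_false(is_upregulated(cr, cr$gene_id[3], "strict")) # FDR too high
  expect_error(is_upregulated(cr, "nope"), "unknown gene")
})

test_that("planted log2FC estimates recover the planted effect", {
  est <- vapply(1:10, function(s) {
    ds <- generate_dataset(sim_config(seed = s, n_genes = 100))
    m <- as_expression_matrix(ds)
    cr <- de_contrast(m, "NW186 -Fe_a", "NW305 -Fe_a")
    cr$log2fc[match("g_planted_0", cr$gene_id)]
  }, 0)
  expect_lt(abs(mean(est) - 3), 0.5)
})
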