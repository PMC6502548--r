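#' Configuration for the synthetic study generator
#'
#' The generator emulates the design of the citrate-production transcriptome
#' study: five conditions x two biological replicates of bulk RNA-seq counts,
#' a proteome, gene coordinates, homolog databases for five comparator
#' species, a seed alignment of transporter-like proteins, and transmembrane
#' topology / localisation tables. `n_planted` ground-truth exporter genes are
#' planted with the full evidence signature (induction in all three study
#' contrasts, high coverage in the key producing conditions, 12 transmembrane
#' helices, producer-biased homology, proximity to *citA*, and membership in
#' the seed alignment family).
#'
#' @param n_genes number of genes (>= 50).
#' @param seed integer RNG seed; the dataset is a pure function of the config.
#' @param read_length read length in nt.
#' @param gene_length_range nt interval gene lengths are drawn from.
#' @param libsize_range reads interval for per-sample sequencing depth.
#' @param nb_dispersion negative-binomial dispersion shared by all genes.
#' @param planted_effect_log2fc log2 fold-change planted in each of the three
#'   study contrasts. Must exceed the genome-wide differential-expression
#'   threshold of 0.58, or be exactly 0 for a null dataset in which the
#'   "planted" gene carries no expression signature.
#' @param n_planted number of planted exporter genes.
#' @param tm_helix_count_planted transmembrane helices given to each planted
#'   protein.
#' @param producer_identity_gap percentage points by which planted-gene
#'   homologs in citrate-producing species (*A. kawachii*, *Y. lipolytica*)
#'   exceed those in non-producing species in percent identity.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 500, seed = 1, read_length = 100,
                       gene_length_range = c(300, 2400),
                       libsize_range = c(9e5, 1.1e6),
                       nb_dispersion = 0.05,
                       planted_effect_log2fc = 3.0,
                       n_planted = 1,
                       tm_helix_count_planted = 12,
                       producer_identity_gap = 15) {
  if (n_genes < 50) stop("invalid config: n_genes must be >= 50")
  if (n_planted < 0) stop("invalid config: n_planted must be >= 0")
  if (n_planted > n_genes) stop("invalid config: n_planted > n_genes")
  if (planted_effect_log2fc != 0 && planted_effect_log2fc <= 0.58)
    stop("invalid config: planted_effect_log2fc must be 0 (null) or > 0.58")
  if (length(gene_length_range) != 2 || any(gene_length_range <= 0) ||
      gene_length_range[1] > gene_length_range[2])
    stop("invalid config: gene_length_range must be a non-empty interval")
  if (length(libsize_range) != 2 || libsize_range[1] > libsize_range[2] ||
      any(libsize_range <= 0))
    stop("invalid config: libsize_range must be a non-empty interval")
  if (nb_dispersion <= 0) stop("invalid config: nb_dispersion must be > 0")
  if (tm_helix_count_planted < 1)
    stop("invalid config: tm_helix_count_planted must be >= 1")
  structure(list(n_genes = n_genes, seed = seed, read_length = read_length,
                 gene_length_range = gene_length_range,
                 libsize_range = libsize_range,
                 nb_dispersion = nb_dispersion,
                 planted_effect_log2fc = planted_effect_log2fc,
                 n_planted = n_planted,
                 tm_helix_count_planted = tm_helix_count_planted,
                 producer_identity_gap = producer_identity_gap),
            class = "sim_config")
}

# residue pools: helices are strongly hydrophobic, linkers strongly
# hydrophilic, so a 19-residue Kyte-Doolittle window > 1.6 fires exactly once
# per planted helix under the greedy counter
.helix_pool  <- c("A", "I", "L", "V", "F", "M")
.linker_pool <- c("D", "E", "K", "R", "N", "Q")
.background_pool_weights <- c(
  A = 6, C = 1, D = 6, E = 7, F = 3, G = 6, H = 2, I = 4, K = 6, L = 8,
  M = 2, N = 5, P = 5, Q = 5, R = 6, S = 8, T = 6, V = 5, W = 1, Y = 3)

make_tm_protein <- function(n_helix, helix_len = 19, linker_len = 12) {
  parts <- character(2 * n_helix + 1)
  parts[1] <- paste(sample(.linker_pool, linker_len, replace = TRUE),
                    collapse = "")
  for (h in seq_len(n_helix)) {
    parts[2 * h] <- paste(sample(.helix_pool, helix_len, replace = TRUE),
                          collapse = "")
    parts[2 * h + 1] <- paste(sample(.linker_pool, linker_len, replace = TRUE),
                              collapse = "")
  }
  paste(parts, collapse = "")
}

make_background_protein <- function(n_aa) {
  paste(sample(names(.background_pool_weights), n_aa, replace = TRUE,
               prob = .background_pool_weights), collapse = "")
}

# point-mutate to an approximate target percent identity (no indels)
mutate_protein <- function(seq, target_identity) {
  aa <- strsplit(seq, "")[[1]]
  n_mut <- round((1 - target_identity / 100) * length(aa))
  if (n_mut > 0) {
    pos <- sample(length(aa), n_mut)
    alpha <- aa_alphabet()
    aa[pos] <- vapply(aa[pos],
                      function(a) sample(setdiff(alpha, a), 1), "")
  }
  paste(aa, collapse = "")
}

#' Generate a complete synthetic study
#'
#' Produces counts, proteome, gene coordinates, homolog databases, seed
#' alignment, transmembrane-helix counts, localisation labels and the
#' ground-truth planted gene set, deterministically from the config seed.
#' Planted genes receive `+planted_effect_log2fc` in all three study
#' contrasts, average nucleotide coverage >= 50 in `NW186 -Fe_a` and
#' `NW186 +Fe_c`, `tm_helix_count_planted` hydrophobic stretches, homologs
#' that are `producer_identity_gap` points more identical in producer species,
#' and (for the first planted gene) a locus within 10 genes of *citA*.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_dataset` list; see fields in the source. Use
#'   [as_expression_matrix()] to get the count container the expression
#'   module consumes.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pm_background <- 10L
  n_bg <- config$n_genes - config$n_planted - 1L # minus citA
  if (n_bg < n_pm_background + 20L)
    stop("invalid config: n_genes too small for the requested n_planted")

  planted_ids <- if (config$n_planted > 0)
    paste0("g_planted_", seq_len(config$n_planted) - 1L) else character()
  bg_ids <- sprintf("g%04d", seq_len(n_bg))
  pm_bg_ids <- bg_ids[seq_len(n_pm_background)]
  gene_ids <- c(planted_ids, "citA", bg_ids)

  ## --- proteome and gene lengths ------------------------------------------
  proteome <- character(length(gene_ids))
  names(proteome) <- gene_ids
  for (g in planted_ids)
    proteome[g] <- make_tm_protein(config$tm_helix_count_planted)
  pm_helices <- sample(2:14, n_pm_background, replace = TRUE)
  for (i in seq_along(pm_bg_ids))
    proteome[pm_bg_ids[i]] <- make_tm_protein(pm_helices[i])
  plain <- setdiff(gene_ids, c(planted_ids, pm_bg_ids))
  lens_nt <- round(runif(length(plain), config$gene_length_range[1],
                         config$gene_length_range[2]) / 3) * 3
  for (i in seq_along(plain))
    proteome[plain[i]] <- make_background_protein(lens_nt[i] / 3)
  gene_lengths <- nchar(proteome) * 3
  names(gene_lengths) <- gene_ids

  ## --- counts --------------------------------------------------------------
  conds <- study_conditions()
  # per-condition mean-coverage multipliers for planted genes; background
  # genes have no systematic contrast
  e <- config$planted_effect_log2fc
  planted_mult <- c("NW305 ++Fe_a" = 1, "NW305 -Fe_a" = 2^e,
                    "NW186 -Fe_a" = 2^(2 * e), "NW186 +Fe_a" = 2,
                    "NW186 +Fe_c" = 2 * 2^e)
  base_cov <- setNames(rlnorm(length(gene_ids), meanlog = log(71),
                              sdlog = 1.2), gene_ids)
  base_cov[planted_ids] <- 6
  cov_mean <- outer(base_cov, setNames(rep(1, 5), conds))
  for (g in planted_ids) cov_mean[g, ] <- base_cov[g] * planted_mult[conds]
  mu <- cov_mean * gene_lengths / config$read_length # mean counts/replicate

  sample_meta <- data.frame(
    sample = paste0(rep(condition_token(conds), each = 2), "_r", 1:2),
    condition = rep(conds, each = 2),
    replicate = rep(1:2, 5),
    stringsAsFactors = FALSE)
  depth <- runif(nrow(sample_meta), config$libsize_range[1],
                 config$libsize_range[2]) / mean(config$libsize_range)
  counts <- matrix(0L, length(gene_ids), nrow(sample_meta),
                   dimnames = list(gene_ids, sample_meta$sample))
  for (j in seq_len(nrow(sample_meta))) {
    mu_j <- mu[, sample_meta$condition[j]] * depth[j]
    counts[, j] <- rnbinom(length(mu_j), mu = mu_j,
                           size = 1 / config$nb_dispersion)
  }

  ## --- loci: two contigs; planted_0 within 10 loci of citA ------------------
  n1 <- max(25L, floor(length(gene_ids) / 2))
  others <- sample(setdiff(gene_ids, c(planted_ids, "citA")),
                   n1 - 1L - min(1L, config$n_planted))
  # keep >= 10 genes on each side of citA so the neighbourhood is full width
  mid <- sample(11:(length(others) - 9L), 1)
  ctg1_genes <- append(others, "citA", after = mid - 1L) # citA at ordinal mid
  if (config$n_planted > 0) {
    d <- sample(1:10, 1) # ordinal distance of planted_0 from citA
    after <- if (sample(c(TRUE, FALSE), 1)) mid + d - 1L else mid - d
    ctg1_genes <- append(ctg1_genes, planted_ids[1], after = after)
  }
  ctg2_genes <- sample(setdiff(gene_ids, ctg1_genes))
  loci <- do.call(rbind, lapply(
    list(ctg1 = ctg1_genes, ctg2 = ctg2_genes), function(gs) {
      gaps <- sample(200:2000, length(gs), replace = TRUE)
      starts <- cumsum(gaps + c(0, gene_lengths[gs][-length(gs)]))
      data.frame(start = starts,
                 end = starts + gene_lengths[gs] - 1,
                 strand = sample(c("+", "-"), length(gs), replace = TRUE),
                 gene_id = gs, stringsAsFactors = FALSE)
    }))
  loci <- data.frame(contig = sub("\\..*$", "", rownames(loci)), loci,
                     row.names = NULL, stringsAsFactors = FALSE)

  ## --- topology and localisation -------------------------------------------
  tm_counts <- vapply(proteome, hydropathy_tm_count, 0L, USE.NAMES = TRUE)
  localisation <- setNames(rep("other", length(gene_ids)), gene_ids)
  localisation[c(planted_ids, pm_bg_ids)] <- "plasma membrane"

  ## --- homolog databases ----------------------------------------------------
  producers <- c("A_kawachii", "Y_lipolytica")
  species <- comparator_species()
  pm_ids <- c(planted_ids, pm_bg_ids)
  homolog_dbs <- lapply(setNames(species, species), function(sp) {
    db <- vapply(pm_ids, function(g) {
      target <- if (g %in% planted_ids) {
        if (sp %in% producers) 78 else 78 - config$producer_identity_gap
      } else runif(1, 55, 85)
      mutate_protein(proteome[g], target)
    }, "")
    names(db) <- paste0(sp, "_", pm_ids)
    db
  })

  ## --- seed alignment of the transporter family -----------------------------
  family_seed <- if (config$n_planted > 0) proteome[planted_ids[1]] else
    make_tm_protein(config$tm_helix_count_planted)
  msa <- c(seed_ref = unname(family_seed),
           setNames(vapply(1:5, function(i) mutate_protein(family_seed, 88),
                           ""),
                    paste0("seed_hom", 1:5)))
  substr(msa[3], 50, 52) <- "---" # a gappy stretch, below the match threshold

  structure(list(config = config,
                 counts = counts,
                 sample_meta = sample_meta,
                 gene_lengths = gene_lengths,
                 proteome = proteome,
                 loci = loci,
                 homolog_dbs = homolog_dbs,
                 tm_counts = tm_counts,
                 localisation = localisation,
                 seed_msa = msa,
                 truth = planted_ids),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d genes, %d samples, %d planted exporter(s)\n",
    nrow(x$counts), ncol(x$counts), length(x$truth)))
  invisible(x)
}

#' Expression container of a synthetic dataset
#'
#' @param ds a `synthetic_dataset`.
#' @return an [expression_matrix()].
#' @export
as_expression_matrix <- function(ds) {
  expression_matrix(ds$counts, ds$sample_meta, ds$gene_lengths,
                    read_length = ds$config$read_length)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `counts.tsv`, `proteome.fasta`, `loci.tsv`, one
#' `homolog_<species>.fasta` per comparator species, `tm_counts.tsv`,
#' `localisation.tsv`, `seed_msa.afa` and `truth.txt`. All files round-trip
#' losslessly through [read_dataset()].
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  p <- function(f) file.path(dir, f)
  write_counts(as_expression_matrix(ds), p("counts.tsv"))
  write_fasta(ds$proteome, p("proteome.fasta"))
  write_loci(ds$loci, p("loci.tsv"))
  for (sp in names(ds$homolog_dbs))
    write_fasta(ds$homolog_dbs[[sp]], p(paste0("homolog_", sp, ".fasta")))
  write_topology_table(
    data.frame(protein_id = names(ds$tm_counts),
               tm_helices = unname(ds$tm_counts),
               localisation = unname(ds$localisation[names(ds$tm_counts)]),
               stringsAsFactors = FALSE),
    p("tm_counts.tsv"))
  write_fasta(ds$seed_msa, p("seed_msa.afa"))
  writeLines(ds$truth, p("truth.txt"))
  manifest <- c(counts = p("counts.tsv"), proteome = p("proteome.fasta"),
                loci = p("loci.tsv"),
                setNames(p(paste0("homolog_", names(ds$homolog_dbs), ".fasta")),
                         paste0("homolog_", names(ds$homolog_dbs))),
                topology = p("tm_counts.tsv"), seed_msa = p("seed_msa.afa"),
                truth = p("truth.txt"))
  invisible(manifest)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir directory holding the files.
#' @param config optionally, the original [sim_config()] (recorded in the
#'   returned object; files carry everything else).
#' @return a `synthetic_dataset`.
#' @export
read_dataset <- function(dir, config = NULL) {
  p <- function(f) file.path(dir, f)
  m <- read_counts(p("counts.tsv"))
  topo <- parse_topology_table(p("tm_counts.tsv"))
  species <- comparator_species()
  homolog_dbs <- lapply(setNames(species, species), function(sp)
    read_fasta(p(paste0("homolog_", sp, ".fasta"))))
  truth <- readLines(p("truth.txt"))
  truth <- truth[nzchar(truth)]
  structure(list(config = config,
                 counts = m$counts,
                 sample_meta = m$sample_meta,
                 gene_lengths = m$gene_lengths,
                 proteome = read_fasta(p("proteome.fasta")),
                 loci = read_loci(p("loci.tsv")),
                 homolog_dbs = homolog_dbs,
                 tm_counts = setNames(topo$tm_helices, topo$protein_id),
                 localisation = setNames(topo$localisation, topo$protein_id),
                 seed_msa = read_fasta(p("seed_msa.afa"), aligned = TRUE),
                 truth = truth),
            class = "synthetic_dataset")
}
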