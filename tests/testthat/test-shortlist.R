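rec_fixture <- function(cov = c(14.61, 4.73, 139.89, 34.03, 350.11),
                        c1 = list(log2fc = 3.42, fdr = 0.00),
                        c2 = list(log2fc = 3.30, fdr = 0.00),
                        c3 = list(log2fc = -1.75, fdr = 0.00),
                        tm = 12, tracks = "homology",
                        homology = c(A_kawachii = 80, A_flavus = 60,
                                     A_terreus = 55, Y_lipolytica = 70,
                                     S_cerevisiae = 40)) {
  prof <- if (is.null(homology)) NULL else
    structure(list(query_id = "x", identity = homology,
                   best_hit_id = setNames(rep("h", 5), names(homology))),
              class = "homolog_profile")
  candidate_record("1165828", tracks, tm, "plasma membrane",
                   cov = setNames(cov, study_conditions()),
                   cov_sd = setNames(rep(1, 5), study_conditions()),
                   contrasts = list(C1 = c1, C2 = c2, C3 = c3),
                   homology = prof)
}

test_that("a record with the published top-candidate evidence passes the minimal criteria", {
  res <- minimal_criteria(rec_fixture())
  expect_true(res$pass)
  expect_equal(res$log$criterion,
               c("cov_all_conditions", "cov_key_conditions", "up_C1", "up_C2"))
  expect_true(all(res$log$pass))
})

test_that("the cascade short-circuits at the first failing criterion", {
  res <- minimal_criteria(rec_fixture(cov = c(0.5, 4.73, 139.89, 34.03,
                                              350.11)))
  expect_false(res$pass)
  expect_equal(res$log$criterion, "cov_all_conditions") # 2-4 unevaluated
  # boundary: exactly 50 in both key conditions is inclusive
  res50 <- minimal_criteria(rec_fixture(cov = c(14, 4, 50, 34, 50)))
  expect_true(res50$log$pass[2])
  expect_error(minimal_criteria(
    candidate_record("x", "hmm", 1, "other",
                     cov = c("NW305 -Fe_a" = 5),
                     contrasts = list(C1 = list(log2fc = 1, fdr = 0),
                                      C2 = list(log2fc = 1, fdr = 0),
                                      C3 = list(log2fc = 1, fdr = 0)))),
    "coverage missing")
})

test_that("strict mode gates on the differential-expression thresholds", {
  weak <- rec_fixture(c1 = list(log2fc = 0.3, fdr = 0.00))
  expect_true(minimal_criteria(weak, mode = "lenient")$pass)
  expect_false(minimal_criteria(weak, mode = "strict")$pass)
})

test_that("stringent criteria: membrane, asymmetries, and an advisory C3", {
  ok <- stringent_criteria(rec_fixture())
  expect_true(ok$pass)
  # the published top candidate is C3-down: logged as a failure, non-blocking
  expect_equal(ok$log$criterion[4], "up_C3_advisory")
  expect_false(ok$log$pass[4])
  expect_false(stringent_criteria(rec_fixture(), soft_c3 = FALSE)$pass)

  no_tm <- stringent_criteria(rec_fixture(tm = 0))
  expect_false(no_tm$pass)
  expect_equal(no_tm$log$criterion, "tm_helix")

  tied <- stringent_criteria(rec_fixture(
    homology = c(A_kawachii = 60, A_flavus = 60, A_terreus = 50,
                 Y_lipolytica = 70, S_cerevisiae = 40)))
  expect_false(tied$pass)

  expect_error(stringent_criteria(rec_fixture(homology = NULL)),
               "no homology profile")
})

test_that("an empty track set yields an empty but valid shortlist", {
  ds <- generate_dataset(sim_config(seed = 12, n_genes = 100))
  res <- run_pipeline(ds)
  sl <- build_shortlist(list(hmm = character(), homology = character(),
                             proximity = character()),
                        res$evidence)
  expect_s3_class(sl, "shortlist")
  expect_equal(nrow(sl$records), 0)
  expect_equal(sl$provenance$n_candidates, 0)
})

test_that("unknown candidate ids are reported by name", {
  ds <- generate_dataset(sim_config(seed = 12, n_genes = 100))
  res <- run_pipeline(ds)
  expect_error(build_shortlist(list(hmm = c("gX", "gY"),
                                    homology = character(),
                                    proximity = character()),
                               res$evidence),
               "gX, gY")
})

test_that("survivors sort by descending C1 log2FC with id tie-breaking", {
  ds <- generate_dataset(sim_config(seed = 12, n_genes = 100))
  res <- run_pipeline(ds)
  r <- res$shortlist$records
  lfc <- r$c1_log2fc
  defined <- which(!is.na(lfc))
  if (length(defined) > 1)
    expect_true(all(diff(lfc[defined]) <= 1e-12))
  if (anyNA(lfc))
    expect_true(all(which(is.na(lfc)) > max(defined)))
  # synthetic tie: two records with equal C1 keep ascending id order
  ev <- res$evidence
  ids <- r$protein_id[1:2]
  for (cn in c("C1", "C2", "C3")) {
    i <- match(ids, ev$contrasts[[cn]]$gene_id)
    ev$contrasts[[cn]]$log2fc[i] <- 1.5
    ev$contrasts[[cn]]$fdr[i] <- 0
  }
  for (cond in names(ev$cov)) {
    i <- match(ids, ev$cov[[cond]]$gene_id)
    ev$cov[[cond]]$mean[i] <- 100
  }
  sl <- build_shortlist(list(hmm = ids, homology = character(),
                             proximity = character()), ev)
  expect_equal(sl$records$protein_id, sort(ids))
})

test_that("tightening thresholds never grows the shortlist", {
  ds <- generate_dataset(sim_config(seed = 14, n_genes = 120))
  res <- run_pipeline(ds)
  base <- run_pipeline(ds, shortlist_config())$shortlist$records$protein_id
  for (cfg in list(shortlist_config(cov_all = 5),
                   shortlist_config(cov_key = 100),
                   shortlist_config(up_mode = "strict"),
                   shortlist_config(soft_c3 = FALSE))) {
    tightened <- build_shortlist(res$tracks, res$evidence, cfg)
    expect_true(all(tightened$records$protein_id %in% base),
                label = paste("tightened", paste(unlist(cfg), collapse = "/")))
  }
})

test_that("stringent entries appear in the drop-out log exactly for homology-track candidates", {
  ds <- generate_dataset(sim_config(seed = 16, n_genes = 100))
  res <- run_pipeline(ds)
  log <- res$shortlist$dropout
  stringent <- c("tm_helix", "asym_aspergillus", "asym_yeast",
                 "up_C3_advisory")
  hom_ids <- res$tracks$homology
  with_stringent <- unique(log$protein_id[log$criterion %in% stringent])
  expect_true(all(with_stringent %in% hom_ids))
  # a homology candidate that passed the minimal criteria must carry them
  passed_min <- vapply(split(log, log$protein_id), function(d)
    all(d$pass[d$criterion %in% c("cov_all_conditions", "cov_key_conditions",
                                  "up_C1", "up_C2")]) &&
      sum(d$criterion %in% c("cov_all_conditions")) == 1, TRUE)
  cand <- intersect(hom_ids, names(passed_min)[passed_min])
  for (g in cand) {
    d <- log[log$protein_id == g, ]
    if (all(d$pass[d$criterion %in% c("cov_all_conditions",
                                      "cov_key_conditions", "up_C1",
                                      "up_C2")]))
      expect_true(any(d$criterion %in% stringent), label = g)
  }
})

test_that("the published shortlist parses with its NA conventions intact", {
  tab <- read_published_shortlist()
  expect_equal(nrow(tab), 50)
  expect_equal(tab$protein_id[1], "1165828")
  expect_equal(tab$tm_helices[1], 12L)
  expect_equal(tab$c1_log2fc[1], 3.42)
  i <- match("37369", tab$protein_id)
  expect_true(is.na(tab$c1_log2fc[i]))
  expect_true(is.na(tab$c1_covB_mean[i])) # "− ± −" coverage
  expect_false(is.na(tab$c1_covA_mean[i]))
  # negative fold-changes use the typographic minus in the source
  expect_equal(tab$c3_log2fc[1], -1.75)
})

test_that("re-ranking the parsed table by C1 reproduces the published order", {
  tab <- read_published_shortlist()
  ranked <- rank_published_shortlist(tab)
  defined <- !is.na(ranked$c1_log2fc)
  expect_true(all(diff(ranked$c1_log2fc[defined]) <= 0))
  expect_true(all(which(!defined) > max(which(defined))))
  # published order is already C1-descending, up to printed-precision ties
  expect_equal(sort(ranked$c1_log2fc[defined], decreasing = TRUE),
               sort(tab$c1_log2fc[!is.na(tab$c1_log2fc)],
                    decreasing = TRUE))
  expect_equal(ranked$protein_id[1], "1165828")
})

test_that("malformed cells are rejected with their position", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(rep("h", 14), collapse = "\t")
  row <- paste(c("1", "2", rep(c("1.0 ± 0.1", "2.0 ± 0.2", "0.5", "0.01"),
                               3)), collapse = "\t")
  bad <- sub("2.0 ± 0.2", "2.0 / 0.2", row, fixed = TRUE)
  writeLines(c(hdr, row, bad), path)
  expect_error(read_published_shortlist(path), "row 2")
  short <- sub("\t0.01$", "", row)
  writeLines(c(hdr, short), path)
  expect_error(read_published_shortlist(path), "14 fields")
})
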