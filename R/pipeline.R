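#' Run the full candidate-prioritisation pipeline
#'
#' Executes every stage against a `synthetic_dataset` (or a dataset read
#' back from disk with [read_dataset()]): expression summaries and the three
#' study contrasts, the profile-HMM proteome scan seeded from the dataset's
#' alignment, the producer/non-producer homology screen over the predicted
#' plasma-membrane proteins, the topology table, the *citA* neighbourhood,
#' and the fused, ranked shortlist. Deterministic given the dataset.
#'
#' @param ds a `synthetic_dataset`.
#' @param config a [shortlist_config()].
#' @param anchor gene id of the proximity-track anchor (default `"citA"`).
#' @return list with fields `shortlist`, `tracks`, `evidence`, `hmm_hits`,
#'   `homology_table`.
#' @export
run_pipeline <- function(ds, config = shortlist_config(), anchor = "citA") {
  m <- as_expression_matrix(ds)
  contrasts <- lapply(study_contrasts(), function(tr)
    de_contrast(m, tr[1], tr[2]))
  cov <- lapply(setNames(study_conditions(), study_conditions()),
                function(cond) av_nt_cov(m, cond))

  hmm <- build_phmm(ds$seed_msa)
  hits <- scan_proteome(hmm, ds$proteome, top_n = config$top_n)

  pm_ids <- names(ds$localisation)[ds$localisation == "plasma membrane"]
  if (length(ds$homolog_dbs) == 0 && length(pm_ids))
    stop("homology track enabled but no homolog databases in the dataset")
  hom_table <- if (length(pm_ids))
    homology_screen(ds$proteome[pm_ids], ds$homolog_dbs) else NULL
  profiles <- if (is.null(hom_table)) list() else attr(hom_table, "profiles")

  prox <- neighbourhood(ds$loci, anchor, k = config$k)

  topo <- data.frame(protein_id = names(ds$tm_counts),
                     tm_helices = unname(ds$tm_counts),
                     localisation = unname(ds$localisation[names(ds$tm_counts)]),
                     stringsAsFactors = FALSE)
  tracks <- list(hmm = hits$protein_id, homology = pm_ids, proximity = prox)
  evidence <- list(cov = cov, contrasts = contrasts, topology = topo,
                   homology_profiles = profiles)
  sl <- build_shortlist(tracks, evidence, config)
  list(shortlist = sl, tracks = tracks, evidence = evidence,
       hmm_hits = hits, homology_table = hom_table)
}

#' Simulate a study and run the pipeline end to end
#'
#' The one-call entry point: generates the synthetic study for `seed`,
#' writes its input files, runs every stage, writes the shortlist, drop-out
#' log and a JSON run manifest (config snapshot, input hashes, per-stage
#' output paths, seed, package version), and returns the manifest. Identical
#' seeds give identical output files.
#'
#' @param config list as returned by [read_config()], or `NULL` for
#'   defaults.
#' @param seed integer seed for the synthetic study.
#' @param outdir output directory.
#' @return the manifest list, invisibly; side effect: files under `outdir`.
#' @export
run_all <- function(config = NULL, seed = 1, outdir = tempfile("cexrun")) {
  if (is.null(config)) config <- list(shortlist = shortlist_config(),
                                      sim = list())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  manifest <- list(tool = "cexscreen",
                   version = as.character(utils::packageVersion("cexscreen")),
                   seed = seed,
                   config = unclass(config$shortlist),
                   stages = list())
  result <- tryCatch({
    ds <- generate_dataset(do.call(sim_config, c(list(seed = seed),
                                                 config$sim)))
    input_dir <- file.path(outdir, "inputs")
    inputs <- write_dataset(ds, input_dir)
    manifest$stages$simulate <- as.list(inputs)
    manifest$input_hashes <- file_hashes(unlist(inputs))

    stage <- "pipeline"
    res <- run_pipeline(ds, config$shortlist)

    stage <- "write"
    paths <- c(shortlist = file.path(outdir, "shortlist.tsv"),
               dropout = file.path(outdir, "dropout_log.tsv"),
               hmm_hits = file.path(outdir, "hmm_hits.tsv"))
    write_shortlist(res$shortlist, paths[["shortlist"]])
    write.table(res$shortlist$dropout, paths[["dropout"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(res$hmm_hits, paths[["hmm_hits"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages$outputs <- as.list(paths)
    res
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest_path <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  out <- c(manifest, list(result = result))
  invisible(out)
}
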