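#' The five comparator species of the homology screen
#'
#' Citrate producers: *A. kawachii* and *Y. lipolytica*; non-producers:
#' *A. flavus*, *A. terreus* and *S. cerevisiae*. The asymmetry criteria ask
#' that a candidate's best homolog be strictly more identical in the producer
#' of each pair-set than in the corresponding non-producers.
#'
#' @param producers_only return only the two producer species.
#' @return character vector of species tokens.
#' @export
comparator_species <- function(producers_only = FALSE) {
  sp <- c("A_kawachii", "A_flavus", "A_terreus", "Y_lipolytica",
          "S_cerevisiae")
  if (producers_only) sp[c(1, 4)] else sp
}

align_global <- function(a, b, gap_open = 10, gap_extend = 0.5,
                         matrix = "BLOSUM62") {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  submat <- get_blosum(matrix)
  Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                Biostrings::AAString(b),
                                type = "global",
                                substitutionMatrix = submat,
                                gapOpening = gap_open,
                                gapExtension = gap_extend)
}

get_blosum <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    cache[[name]] <- e[[name]]
    cache[[name]]
  }
})

# identity over the full alignment length: every aligned column holds one
# residue of each gapless sequence, so length = |a| + |b| - (match+mismatch)
pid_of_alignment <- function(pa, len_a, len_b) {
  nm <- Biostrings::nmatch(pa)
  aln_len <- len_a + len_b - nm - Biostrings::nmismatch(pa)
  100 * nm / aln_len
}

#' Percent identity of the optimal global alignment
#'
#' Aligns two proteins end to end with affine gap costs (a gap of length L
#' costs `gap_open + L * gap_extend`) under a BLOSUM62 substitution matrix,
#' and reports `100 * identical positions / alignment length`, counting gap
#' columns in the length. The optimum is chosen by alignment score, not by
#' identity. Global alignment deliberately replaces a heuristic local search
#' tool here: the screen compares full-length transporters, and the global
#' optimum is reproducible without seeding heuristics.
#'
#' @param a,b protein sequences (non-empty strings).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param matrix substitution matrix name available in Biostrings
#'   (default `"BLOSUM62"`).
#' @return percent identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b, gap_open = 10, gap_extend = 0.5,
                             matrix = "BLOSUM62") {
  # canonical argument order: among score-tied optimal alignments the
  # aligner's pick can depend on orientation; fixing the order makes the
  # reported identity symmetric in (a, b)
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  pid_of_alignment(align_global(a, b, gap_open, gap_extend, matrix),
                   nchar(a), nchar(b))
}

#' Best database hit of a query protein
#'
#' Scores the query against every database sequence with the global
#' affine-gap alignment of [percent_identity()]; the hit with the maximal
#' alignment score wins (ties broken by ascending id) and its percent
#' identity is reported. An empty database yields `(NA, 0)`.
#'
#' @param query protein sequence.
#' @param db named character vector of database sequences.
#' @inheritParams percent_identity
#' @return list with fields `id` (character or `NA`) and `identity`.
#' @export
best_hit <- function(query, db, gap_open = 10, gap_extend = 0.5,
                     matrix = "BLOSUM62") {
  if (length(db) == 0) return(list(id = NA_character_, identity = 0))
  if (!nzchar(query) || any(!nzchar(db))) stop("sequences must be non-empty")
  scores <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(db), Biostrings::AAString(query),
    type = "global", substitutionMatrix = get_blosum(matrix),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  best <- order(-scores, names(db))[1]
  list(id = names(db)[best],
       identity = percent_identity(query, db[[best]], gap_open, gap_extend,
                                   matrix))
}

#' Best-hit identity profile of one query across the comparator species
#'
#' @param query_id query protein id.
#' @param query protein sequence.
#' @param dbs named list (one entry per species in [comparator_species()])
#'   of named character vectors of protein sequences.
#' @inheritParams percent_identity
#' @return a `homolog_profile` list with fields `query_id`, `identity`
#'   (named numeric, one entry per species, 0 when no hit) and `best_hit_id`
#'   (named character, `NA` when no hit).
#' @export
homolog_profile <- function(query_id, query, dbs, gap_open = 10,
                            gap_extend = 0.5, matrix = "BLOSUM62") {
  species <- comparator_species()
  missing <- setdiff(species, names(dbs))
  if (length(missing))
    stop("missing homolog database(s): ", paste(missing, collapse = ", "))
  hits <- lapply(dbs[species], function(db)
    best_hit(query, db, gap_open, gap_extend, matrix))
  structure(list(query_id = query_id,
                 identity = vapply(hits, function(h) h$identity, 0),
                 best_hit_id = vapply(hits, function(h) h$id, "")),
            class = "homolog_profile")
}

#' Producer/non-producer homology asymmetry predicates
#'
#' `aspergillus_ok`: the *A. kawachii* best-hit identity strictly exceeds
#' both the *A. flavus* and the *A. terreus* identities. `yeast_ok`: the
#' *Y. lipolytica* identity strictly exceeds the *S. cerevisiae* identity.
#' Ties fail ("more similar" is read strictly). Both must hold for a
#' candidate to pass the homology criteria of the stringent cascade.
#'
#' @param p a [homolog_profile()] or a named numeric vector of identities
#'   over the five comparator species.
#' @return list with logical fields `aspergillus_ok` and `yeast_ok`.
#' @export
producer_asymmetry <- function(p) {
  id <- if (inherits(p, "homolog_profile")) p$identity else p
  missing <- setdiff(comparator_species(), names(id))
  if (length(missing))
    stop("identity missing for species: ", paste(missing, collapse = ", "))
  list(aspergillus_ok = id[["A_kawachii"]] > id[["A_flavus"]] &&
         id[["A_kawachii"]] > id[["A_terreus"]],
       yeast_ok = id[["Y_lipolytica"]] > id[["S_cerevisiae"]])
}

#' Run the homology screen over a set of query proteins
#'
#' @param queries named character vector of query protein sequences
#'   (typically the predicted plasma-membrane subset of the proteome).
#' @param dbs named list of per-species databases (see [homolog_profile()]).
#' @inheritParams percent_identity
#' @return data.frame with one row per query: identity and best-hit columns
#'   per species plus the two asymmetry verdicts.
#' @export
homology_screen <- function(queries, dbs, gap_open = 10, gap_extend = 0.5,
                            matrix = "BLOSUM62") {
  species <- comparator_species()
  missing <- setdiff(species, names(dbs))
  if (length(missing))
    stop("missing homolog database(s): ", paste(missing, collapse = ", "))
  if (is.null(names(queries)) || any(!nzchar(names(queries))))
    stop("queries must be named")
  submat <- get_blosum(matrix)
  nq <- length(queries)
  qset <- Biostrings::AAStringSet(queries)
  # one vectorised score pass per species to find each query's best hit ...
  winners <- lapply(dbs[species], function(db) {
    if (length(db) == 0)
      return(data.frame(hit = NA_character_, seq = NA_character_,
                        stringsAsFactors = FALSE)[rep(1, nq), ])
    nd <- length(db)
    pat <- Biostrings::AAStringSet(db[rep(seq_len(nd), times = nq)])
    sub <- Biostrings::AAStringSet(queries[rep(seq_len(nq), each = nd)])
    sc <- matrix(Biostrings::pairwiseAlignment(
      pat, sub, type = "global", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE),
      nrow = nd)
    best <- apply(sc, 2, function(col) order(-col, names(db))[1])
    data.frame(hit = names(db)[best], seq = unname(db[best]),
               stringsAsFactors = FALSE)
  })
  # ... then one vectorised full alignment over all (query, winner) pairs
  pair_q <- rep(seq_len(nq), times = length(species))
  pair_seq <- unlist(lapply(winners, function(w) w$seq), use.names = FALSE)
  has_hit <- !is.na(pair_seq)
  ident <- numeric(length(pair_seq))
  if (any(has_hit)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pair_seq[has_hit]),
      qset[pair_q[has_hit]], type = "global",
      substitutionMatrix = submat, gapOpening = gap_open,
      gapExtension = gap_extend)
    ident[has_hit] <- pid_of_alignment(pa, nchar(pair_seq[has_hit]),
                                       nchar(queries)[pair_q[has_hit]])
  }
  ident_m <- matrix(ident, nrow = nq,
                    dimnames = list(names(queries), species))
  hit_m <- matrix(unlist(lapply(winners, function(w) w$hit),
                         use.names = FALSE),
                  nrow = nq, dimnames = list(names(queries), species))
  profiles <- lapply(names(queries), function(g)
    structure(list(query_id = g,
                   identity = ident_m[g, ],
                   best_hit_id = hit_m[g, ]),
              class = "homolog_profile"))
  rows <- lapply(profiles, function(p) {
    asym <- producer_asymmetry(p)
    cbind(data.frame(query_id = p$query_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(p$identity)),
          setNames(as.data.frame(as.list(p$best_hit_id)),
                   paste0("hit_", names(p$best_hit_id))),
          data.frame(aspergillus_ok = asym$aspergillus_ok,
                     yeast_ok = asym$yeast_ok))
  })
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- setNames(profiles, names(queries))
  out
}
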