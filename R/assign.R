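#' Rank-assignment thresholds for best-hit mismatch scores
#'
#' Calibrated divergence ceilings on the mismatch score: a best hit
#' under 0.3% indicates the same species, under 2.0% the same genus and
#' under 4% the same family. All three bounds are strict ("under"), so a
#' score exactly at a threshold falls in the coarser band.
#'
#' @param species_max,genus_max,family_max strict upper bounds of the
#'   species, genus and family bands (fractions).
#' @return list of class `assignment_thresholds`.
#' @export
assignment_thresholds <- function(species_max = 0.003, genus_max = 0.020,
                                  family_max = 0.040) {
  stopifnot(species_max > 0, species_max < genus_max,
            genus_max < family_max)
  structure(list(species_max = species_max, genus_max = genus_max,
                 family_max = family_max),
            class = "assignment_thresholds")
}

.RANKS <- c("species", "genus", "family", "unassigned")

.score_rank <- function(score, th) {
  if (is.na(score)) return("unassigned")
  if (score < th$species_max) "species"
  else if (score < th$genus_max) "genus"
  else if (score < th$family_max) "family"
  else "unassigned"
}

#' Convert ranked hits into a rank-resolved taxon call
#'
#' The best hit's mismatch score picks the finest band it falls in
#' (species / genus / family / unassigned). All hits whose score lies in
#' that same band vote: if they agree on the taxon at the band's rank,
#' that taxon is called; if they disagree, the call is demoted to their
#' lowest common rank (genus, then family), and to unassigned when even
#' the families conflict. This consensus demotion is why some fragments
#' are identifiable "only to a family" even with a sub-threshold best
#' hit.
#'
#' @param hits data frame from [search_reference()], sorted by ascending
#'   `mismatch_score` (zero rows allowed).
#' @param db the [reference_db] the hits refer to.
#' @param thresholds an [assignment_thresholds()] list.
#' @return one-row data frame: `query_id`, `assigned_rank`, `species`,
#'   `genus`, `family` (NA below the assigned rank), `assigned_taxon`,
#'   `best_score`, `n_support`, `supporting_refs`
#'   (comma-separated ids).
#' @export
assign_taxon <- function(hits, db, thresholds = assignment_thresholds()) {
  stopifnot(inherits(db, "reference_db"),
            inherits(thresholds, "assignment_thresholds"))
  empty <- function(qid) data.frame(
    query_id = qid, assigned_rank = "unassigned",
    species = NA_character_, genus = NA_character_,
    family = NA_character_, assigned_taxon = NA_character_,
    best_score = NA_real_, n_support = 0L,
    supporting_refs = "", stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty(NA_character_))
  if (is.unsorted(hits$mismatch_score)) {
    stop("hits must be sorted by ascending mismatch_score")
  }
  best <- hits$mismatch_score[1L]
  band <- .score_rank(best, thresholds)
  if (band == "unassigned") {
    out <- empty(hits$query_id[1L])
    out$best_score <- best
    return(out)
  }
  ceiling <- switch(band, species = thresholds$species_max,
                    genus = thresholds$genus_max,
                    family = thresholds$family_max)
  voters <- hits[hits$mismatch_score < ceiling, , drop = FALSE]
  tax <- db$taxonomy[match(voters$ref_id, db$taxonomy$seq_id), ,
                     drop = FALSE]
  # demote until the voters agree
  rank <- band
  repeat {
    taxa <- unique(tax[[rank]])
    if (length(taxa) == 1L) break
    rank <- switch(rank, species = "genus", genus = "family",
                   family = "unassigned")
    if (rank == "unassigned") break
  }
  if (rank == "unassigned") {
    out <- empty(hits$query_id[1L])
    out$best_score <- best
    out$n_support <- nrow(voters)
    out$supporting_refs <- paste(voters$ref_id, collapse = ",")
    return(out)
  }
  data.frame(
    query_id = hits$query_id[1L], assigned_rank = rank,
    species = if (rank == "species") taxa else NA_character_,
    genus = if (rank %in% c("species", "genus")) unique(tax$genus)[1L]
            else if (rank == "genus") taxa else NA_character_,
    family = unique(tax$family)[1L],
    assigned_taxon = taxa,
    best_score = best, n_support = nrow(voters),
    supporting_refs = paste(voters$ref_id, collapse = ","),
    stringsAsFactors = FALSE)
}

#' Assign every QC-passing query in one call
#'
#' Runs [search_reference()] and [assign_taxon()] over a table of query
#' fragments.
#'
#' @param fragments `query_fragments` data frame (only rows with
#'   `passed_qc` are assigned).
#' @param db a [reference_db].
#' @param thresholds an [assignment_thresholds()] list.
#' @inheritParams align_pair
#' @return data frame with one row per QC-passing query (see
#'   [assign_taxon()]).
#' @export
assign_all <- function(fragments, db,
                       thresholds = assignment_thresholds(),
                       min_coverage = 0.5, both_strands = TRUE) {
  frs <- fragments[fragments$passed_qc, , drop = FALSE]
  rows <- lapply(seq_len(nrow(frs)), function(i) {
    hits <- search_reference(frs[i, , drop = FALSE], db,
                             min_coverage = min_coverage,
                             both_strands = both_strands)
    out <- assign_taxon(hits, db, thresholds)
    out$query_id <- frs$seq_id[i]
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- assign_taxon(
      data.frame(query_id = character(0), ref_id = character(0),
                 mismatch_score = numeric(0)), db, thresholds)[0L, ]
  }
  rownames(out) <- NULL
  out
}

#' Tally assignments by rank and by distinct taxon
#'
#' Counts queries per assignment rank and the minimum number of distinct
#' taxa implied at each rank. A call at a fine rank propagates upward: a
#' species-level call contributes its species, genus and family; a
#' genus-level call its genus and family; each taxon is counted once
#' however many queries hit it.
#'
#' @param assignments data frame from [assign_all()] /
#'   [assign_taxon()].
#' @return list with `queries_per_rank` (named integer vector over
#'   species/genus/family/unassigned) and `distinct_taxa` (named integer
#'   vector over species/genus/family).
#' @export
tally_assignments <- function(assignments) {
  qr <- vapply(.RANKS, function(r)
    sum(assignments$assigned_rank == r, na.rm = TRUE), integer(1L))
  distinct <- c(
    species = length(unique(stats::na.omit(assignments$species))),
    genus = length(unique(stats::na.omit(assignments$genus))),
    family = length(unique(stats::na.omit(assignments$family))))
  list(queries_per_rank = qr, distinct_taxa = distinct)
}
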