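# Diet records are plain data frames with columns taxon_species,
# taxon_genus, taxon_family, source (W/B/D/G), item (fruit/browse),
# sample_id, month, seed_condition (intact/damaged/mixed/NA). Finer
# ranks may be NA when a record is identified only to genus or family.

.check_records <- function(records) {
  needed <- c("taxon_species", "taxon_genus", "taxon_family",
              "source", "item")
  stopifnot(is.data.frame(records), all(needed %in% names(records)))
  invisible(records)
}

#' Molecular pipeline success rates
#'
#' Given the number of dung-fibre particles processed, the number whose
#' DNA amplified and the number successfully sequenced, returns the
#' amplification rate, the overall sequencing rate (sequenced out of all
#' particles) and the sequencing success rate (sequenced out of
#' amplified). Full precision is retained; `rounded` carries the
#' nearest-integer percentages used in reporting.
#'
#' @param n_particles,n_amplified,n_sequenced pipeline counts; must
#'   satisfy `n_sequenced <= n_amplified <= n_particles`.
#' @return list with `amplification_pct`, `sequencing_overall_pct`,
#'   `sequencing_success_pct` (full precision, `NA` on a zero
#'   denominator) and `rounded` (named integer vector).
#' @export
success_rates <- function(n_particles, n_amplified, n_sequenced) {
  stopifnot(n_particles >= 0, n_amplified >= 0, n_sequenced >= 0,
            n_sequenced <= n_amplified, n_amplified <= n_particles)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- list(
    amplification_pct = pct(n_amplified, n_particles),
    sequencing_overall_pct = pct(n_sequenced, n_particles),
    sequencing_success_pct = pct(n_sequenced, n_amplified))
  out$rounded <- vapply(out, function(x)
    if (is.na(x)) NA_integer_ else as.integer(round(x)), integer(1L))
  out
}

# distinct taxa of one source at one rank (dropping NA, i.e. records not
# identified to that rank)
.taxa_at <- function(records, src, rank_col) {
  unique(stats::na.omit(records[[rank_col]][records$source == src]))
}

#' Overlap of diet evidence sources by rank
#'
#' For each taxonomic rank and item type, compares the taxon sets found
#' by each evidence source: per-source counts, the pairwise and
#' all-source intersections, and for each source the percentage of its
#' taxa also found by the union of the other sources.
#'
#' @param records diet-record data frame.
#' @param sources which sources to compare (default: those present).
#' @return list with one element per item type, each containing
#'   `per_rank`: a list over ranks with `counts` (named), `pairwise`
#'   (named count per source pair), `all_sources` (count), and
#'   `pct_found_by_others` (named).
#' @export
method_overlap <- function(records, sources = NULL) {
  .check_records(records)
  if (is.null(sources)) sources <- sort(unique(records$source))
  ranks <- c(family = "taxon_family", genus = "taxon_genus",
             species = "taxon_species")
  out <- list()
  for (it in sort(unique(records$item))) {
    rec <- records[records$item == it, , drop = FALSE]
    per_rank <- list()
    for (rk in names(ranks)) {
      sets <- lapply(sources, function(s) .taxa_at(rec, s, ranks[[rk]]))
      names(sets) <- sources
      counts <- lengths(sets)
      if (length(sources) >= 2L) {
        pairs <- utils::combn(sources, 2L, simplify = FALSE)
        pairwise <- vapply(pairs, function(p)
          length(intersect(sets[[p[1L]]], sets[[p[2L]]])), integer(1L))
        names(pairwise) <- vapply(pairs, paste, "", collapse = "&")
      } else {
        pairwise <- integer(0)
      }
      all_src <- length(Reduce(intersect, sets))
      pct_others <- vapply(sources, function(s) {
        others <- unique(unlist(sets[setdiff(sources, s)]))
        if (length(sets[[s]]) == 0L) return(0)
        100 * length(intersect(sets[[s]], others)) / length(sets[[s]])
      }, numeric(1L))
      per_rank[[rk]] <- list(counts = counts, pairwise = pairwise,
                             all_sources = all_src,
                             pct_found_by_others = pct_others)
    }
    out[[it]] <- per_rank
  }
  out
}

# finest available taxon label of each record, for counting distinct taxa
.finest_taxon <- function(records) {
  ifelse(!is.na(records$taxon_species), records$taxon_species,
         ifelse(!is.na(records$taxon_genus), records$taxon_genus,
                records$taxon_family))
}

#' Seasonal diversity of fruit residues in dung
#'
#' Mean and standard deviation, per collection month, of the number of
#' distinct fruit taxa found per dung pile (source D records). Months
#' with no sampled piles are absent from the output.
#'
#' @param records diet-record data frame.
#' @param sd_type `"sample"` (n-1 denominator, default) or
#'   `"population"` (n).
#' @return data frame with columns `month`, `n_piles`, `mean_taxa`,
#'   `sd_taxa` (0 for single-pile months).
#' @export
seasonal_fruit_diversity <- function(records,
                                     sd_type = c("sample", "population")) {
  .check_records(records)
  sd_type <- match.arg(sd_type)
  rec <- records[records$source == "D" & records$item == "fruit" &
                   !is.na(records$sample_id) & !is.na(records$month), ,
                 drop = FALSE]
  if (nrow(rec) == 0L) {
    return(data.frame(month = integer(0), n_piles = integer(0),
                      mean_taxa = numeric(0), sd_taxa = numeric(0)))
  }
  rec$taxon <- .finest_taxon(rec)
  per_pile <- stats::aggregate(
    taxon ~ month + sample_id, data = rec,
    FUN = function(x) length(unique(x)))
  sd_fun <- function(x) {
    if (length(x) < 2L) return(0)
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((length(x) - 1) / length(x))
    else s
  }
  out <- do.call(rbind, lapply(split(per_pile, per_pile$month),
                               function(d) data.frame(
    month = d$month[1L], n_piles = nrow(d),
    mean_taxa = mean(d$taxon), sd_taxa = sd_fun(d$taxon))))
  out <- out[order(out$month), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dung-pile frequency of fruit families and genera
#'
#' Counts, for every fruit family and genus found in dung (source D),
#' the number of distinct dung piles containing it, and filters the
#' report to recurrent taxa: families in more than `min_family_piles - 1`
#' piles and genera in more than `min_genus_piles - 1` piles (the
#' defaults keep families in at least 5 piles and genera in at least 4,
#' i.e. "more than four" and "more than three" read strictly).
#'
#' @param records diet-record data frame.
#' @param min_family_piles minimum pile count for a family to be
#'   reported.
#' @param min_genus_piles minimum pile count for a genus to be reported.
#' @return data frame with columns `rank`, `taxon`, `family`, `n_piles`,
#'   sorted by decreasing `n_piles` within rank.
#' @export
taxon_frequency <- function(records, min_family_piles = 5L,
                            min_genus_piles = 4L) {
  .check_records(records)
  rec <- records[records$source == "D" & records$item == "fruit" &
                   !is.na(records$sample_id), , drop = FALSE]
  count_piles <- function(col) {
    d <- rec[!is.na(rec[[col]]), c(col, "sample_id")]
    if (nrow(d) == 0L) return(stats::setNames(integer(0), character(0)))
    tapply(d$sample_id, d[[col]], function(x) length(unique(x)))
  }
  fam <- count_piles("taxon_family")
  gen <- count_piles("taxon_genus")
  gen_fam <- rec$taxon_family[match(names(gen), rec$taxon_genus)]
  rank_rows <- function(rank, taxa, fams, n) {
    data.frame(rank = rep(rank, length(taxa)), taxon = taxa,
               family = fams, n_piles = as.integer(n),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    rank_rows("family", names(fam), names(fam), fam),
    rank_rows("genus", names(gen), gen_fam, gen))
  keep <- (out$rank == "family" & out$n_piles >= min_family_piles) |
    (out$rank == "genus" & out$n_piles >= min_genus_piles)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$rank, -out$n_piles, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Seed intactness across fruit taxa in dung
#'
#' Among the distinct fruit taxa found in dung samples with a recorded
#' seed condition, the percentage whose seeds were at least once intact
#' ("sometimes intact": any record intact or mixed) and the percentage
#' whose seeds were intact in every record ("always intact"). The
#' always-intact set is a subset of the sometimes-intact set, so the
#' first percentage bounds the second from above.
#'
#' @param records diet-record data frame.
#' @return list with `n_taxa`, `pct_sometimes_intact`,
#'   `pct_always_intact` (full precision) and `rounded`.
#' @export
seed_intactness <- function(records) {
  .check_records(records)
  rec <- records[records$source == "D" & records$item == "fruit" &
                   !is.na(records$seed_condition), , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(list(n_taxa = 0L, pct_sometimes_intact = NA_real_,
                pct_always_intact = NA_real_,
                rounded = c(pct_sometimes_intact = NA_integer_,
                            pct_always_intact = NA_integer_)))
  }
  rec$taxon <- .finest_taxon(rec)
  by_taxon <- split(rec$seed_condition, rec$taxon)
  sometimes <- vapply(by_taxon, function(x)
    any(x %in% c("intact", "mixed")), logical(1L))
  always <- vapply(by_taxon, function(x) all(x == "intact"), logical(1L))
  n <- length(by_taxon)
  out <- list(n_taxa = n,
              pct_sometimes_intact = 100 * sum(sometimes) / n,
              pct_always_intact = 100 * sum(always) / n)
  out$rounded <- c(
    pct_sometimes_intact = as.integer(round(out$pct_sometimes_intact)),
    pct_always_intact = as.integer(round(out$pct_always_intact)))
  out
}

#' Read / write diet-record tables
#' @param path TSV path with the diet-record columns.
#' @return [read_diet_records()]: diet-record data frame.
#' @export
read_diet_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  .check_records(df)
  df
}

#' @rdname read_diet_records
#' @param records diet-record data frame to write.
#' @export
write_diet_records <- function(records, path) {
  .check_records(records)
  write_tsv(records, path)
}
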