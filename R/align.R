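# IUPAC alphabet used for scoring. Only the four unambiguous bases can
# score a match; every other comparison (including N vs N) is a mismatch,
# the conservative choice for degraded template.
.IUPAC <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
            "V", "H", "D", "B", "N")

.submat <- local({
  m <- matrix(-1, length(.IUPAC), length(.IUPAC),
              dimnames = list(.IUPAC, .IUPAC))
  for (b in c("A", "C", "G", "T")) m[b, b] <- 1
  m
})

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Mismatch statistic of a local alignment
#'
#' Aligns a query fragment against one reference sequence with
#' Smith-Waterman local alignment (match +1, mismatch -1, gap open -2,
#' gap extend -1) and computes the barcode mismatch score of the aligned
#' region:
#'
#' \deqn{score = (gap\ openings + mismatched\ columns) / alignment\ length}
#'
#' A gap opening is one maximal run of gap characters in either row of the
#' alignment; the alignment length counts all columns of the aligned
#' region, gap columns included. IUPAC ambiguity codes never count as
#' matches. Both orientations of the query are aligned and the one with
#' the lower mismatch score is reported (fragments of unknown strand).
#'
#' @param query DNA sequence of the query fragment (character scalar).
#' @param reference DNA sequence of the reference barcode.
#' @param min_coverage minimum fraction of the query that must be inside
#'   the aligned region for a hit to be reported; below it the result is
#'   the no-hit sentinel. Guards the denominator against trivial local
#'   matches.
#' @param both_strands align the reverse complement of the query as well
#'   and keep the better orientation.
#' @return A one-row data frame with columns `alignment_length`,
#'   `n_mismatches`, `n_gap_openings`, `coverage`, `mismatch_score` and
#'   `strand` ("+" or "-"), or `NULL` when no alignable region scores
#'   above zero at the required coverage.
#' @examples
#' s <- strrep("ACGT", 50)
#' align_pair(s, s)$mismatch_score  # 0
#' @export
align_pair <- function(query, reference, min_coverage = 0.5,
                       both_strands = TRUE) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query),
            is.character(reference), length(reference) == 1L,
            nzchar(reference))
  res <- .align_stats(toupper(query), toupper(reference))
  if (both_strands) {
    rc <- .align_stats(.revcomp(toupper(query)), toupper(reference))
    if (!is.null(rc) &&
        (is.null(res) || rc$mismatch_score < res$mismatch_score)) {
      rc$strand <- "-"
      res <- rc
    }
  }
  if (is.null(res) || res$coverage < min_coverage) return(NULL)
  res
}

# Single-orientation Smith-Waterman plus column walk.
.align_stats <- function(query, reference) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(reference),
    type = "local", substitutionMatrix = .submat,
    gapOpening = 2, gapExtension = 1)
  if (Biostrings::score(pa) <= 0) return(NULL)
  # pattern()/subject() expose the gapped rows of the aligned region
  .walk_columns(as.character(Biostrings::pattern(pa)),
                as.character(Biostrings::subject(pa)),
                query_len = nchar(query))
}

# Recompute the statistic from the two gapped rows of an alignment.
# Exported logic is kept separate from the aligner so the score can be
# audited on any alignment.
.walk_columns <- function(gapped_query, gapped_ref, query_len) {
  qc <- strsplit(gapped_query, "", fixed = TRUE)[[1L]]
  rc <- strsplit(gapped_ref, "", fixed = TRUE)[[1L]]
  stopifnot(length(qc) == length(rc), length(qc) >= 1L)
  qgap <- qc == "-"
  rgap <- rc == "-"
  both <- !qgap & !rgap
  canonical <- qc %in% c("A", "C", "G", "T")
  n_mism <- sum(both & !(qc == rc & canonical))
  runs <- function(g) sum(rle(g)$values)
  n_open <- runs(qgap) + runs(rgap)
  len <- length(qc)
  data.frame(
    alignment_length = len,
    n_mismatches = n_mism,
    n_gap_openings = n_open,
    coverage = sum(!qgap) / query_len,
    mismatch_score = (n_open + n_mism) / len,
    strand = "+",
    stringsAsFactors = FALSE)
}

#' Search a query against a reference database
#'
#' Aligns one query fragment against every reference barcode and returns
#' the hits ranked by ascending mismatch score, ties broken by reference
#' id so the ranking is deterministic.
#'
#' @param query a single-row query fragment (see [make_query_fragments()])
#'   or a plain character sequence.
#' @param db a [reference_db] object.
#' @param top_k maximum number of hits to return.
#' @inheritParams align_pair
#' @return Data frame with columns `query_id`, `ref_id`, `mismatch_score`,
#'   `n_mismatches`, `n_gap_openings`, `alignment_length`, `coverage`,
#'   `strand`, sorted by (`mismatch_score`, `ref_id`); zero rows when
#'   nothing aligns.
#' @export
search_reference <- function(query, db, top_k = Inf, min_coverage = 0.5,
                             both_strands = TRUE) {
  stopifnot(inherits(db, "reference_db"))
  if (length(db$sequences) == 0L) stop("reference database is empty")
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    qid <- query$seq_id
    qseq <- query$sequence
  } else {
    stopifnot(is.character(query), length(query) == 1L)
    qid <- "query"
    qseq <- query
  }
  hits <- .search_one(qseq, db$sequences, min_coverage, both_strands)
  if (nrow(hits) == 0L) {
    return(cbind(data.frame(query_id = character(0)), hits))
  }
  hits <- hits[order(hits$mismatch_score, hits$ref_id), , drop = FALSE]
  if (is.finite(top_k)) hits <- utils::head(hits, top_k)
  rownames(hits) <- NULL
  cbind(data.frame(query_id = qid, stringsAsFactors = FALSE), hits)
}

# Vectorised core: one pairwiseAlignment call per orientation for the
# whole reference set, column walks per hit.
.search_one <- function(qseq, refs, min_coverage, both_strands) {
  qseq <- toupper(qseq)
  orientations <- list(c(seq = qseq, strand = "+"))
  if (both_strands) {
    orientations <- c(orientations,
                      list(c(seq = .revcomp(qseq), strand = "-")))
  }
  ref_set <- Biostrings::DNAStringSet(toupper(unname(refs)))
  names(ref_set) <- names(refs)
  out <- list()
  for (ori in orientations) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = ref_set, subject = Biostrings::DNAString(ori[["seq"]]),
      type = "local", substitutionMatrix = .submat,
      gapOpening = 2, gapExtension = 1)
    scores <- Biostrings::score(pa)
    gq <- as.character(Biostrings::subject(pa))   # query row
    gr <- as.character(Biostrings::pattern(pa))   # reference row
    for (i in which(scores > 0)) {
      st <- .walk_columns(gq[i], gr[i], query_len = nchar(qseq))
      if (st$coverage < min_coverage) next
      st$strand <- ori[["strand"]]
      st <- cbind(data.frame(ref_id = names(refs)[i],
                             stringsAsFactors = FALSE), st)
      out[[length(out) + 1L]] <- st
    }
  }
  if (length(out) == 0L) {
    return(data.frame(ref_id = character(0), alignment_length = integer(0),
                      n_mismatches = integer(0), n_gap_openings = integer(0),
                      coverage = numeric(0), mismatch_score = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, out)
  # keep the better orientation per reference
  all <- all[order(all$ref_id, all$mismatch_score), , drop = FALSE]
  all[!duplicated(all$ref_id), , drop = FALSE]
}

#' Pairwise divergence between two sequences
#'
#' Convenience wrapper returning just the mismatch score of the best local
#' alignment, measured with the shorter sequence as the query so that
#' coverage is assessed against the shorter of the pair. `NA` when the
#' pair has no alignable region.
#'
#' @inheritParams align_pair
#' @param a,b DNA sequences.
#' @return list with `divergence` (fraction or NA) and `compared`
#'   (aligned fraction of the shorter sequence, or NA).
#' @export
pair_divergence <- function(a, b, both_strands = TRUE) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  res <- align_pair(a, b, min_coverage = 0, both_strands = both_strands)
  if (is.null(res)) return(list(divergence = NA_real_, compared = NA_real_))
  list(divergence = res$mismatch_score, compared = res$coverage)
}
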