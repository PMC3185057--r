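#' Construct a reference barcode database
#'
#' A reference database pairs one barcode sequence per taxon with a
#' three-rank taxonomy (species, genus, family). It is the target of
#' [search_reference()] and the source of rank information for
#' [assign_taxon()].
#'
#' @param sequences named character vector of DNA sequences; names are
#'   the sequence ids.
#' @param taxonomy data frame with columns `seq_id`, `species`, `genus`,
#'   `family`; every sequence id must appear exactly once and carry all
#'   three ranks.
#' @return An object of class `reference_db`: a list with elements
#'   `sequences` and `taxonomy`.
#' @export
reference_db <- function(sequences, taxonomy) {
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            all(nzchar(names(sequences))),
            is.data.frame(taxonomy),
            all(c("seq_id", "species", "genus", "family") %in%
                  names(taxonomy)))
  if (anyDuplicated(names(sequences))) {
    stop("duplicate sequence ids: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  }
  if (anyDuplicated(taxonomy$seq_id)) {
    stop("duplicate taxonomy rows for: ",
         paste(unique(taxonomy$seq_id[duplicated(taxonomy$seq_id)]),
               collapse = ", "))
  }
  orphans <- setdiff(names(sequences), taxonomy$seq_id)
  if (length(orphans)) {
    stop("sequences without taxonomy entry: ",
         paste(orphans, collapse = ", "))
  }
  taxonomy <- taxonomy[match(names(sequences), taxonomy$seq_id),
                       c("seq_id", "species", "genus", "family")]
  rownames(taxonomy) <- NULL
  incomplete <- !stats::complete.cases(taxonomy) |
    !apply(taxonomy != "", 1L, all)
  if (any(incomplete)) {
    stop("taxonomy rows missing a rank: ",
         paste(taxonomy$seq_id[incomplete], collapse = ", "))
  }
  structure(list(sequences = sequences, taxonomy = taxonomy),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf(
    "reference_db: %d sequences, %d species / %d genera / %d families\n",
    length(x$sequences), length(unique(x$taxonomy$species)),
    length(unique(x$taxonomy$genus)), length(unique(x$taxonomy$family))))
  invisible(x)
}

#' @export
length.reference_db <- function(x) length(x$sequences)

#' Read a reference database from FASTA + taxonomy TSV
#'
#' The taxonomy TSV has columns `seq_id`, `species`, `genus`, `family`.
#' Every FASTA id must appear in the taxonomy; orphans on either side are
#' reported by id.
#'
#' @param fasta_path path to the reference FASTA.
#' @param taxonomy_path path to the taxonomy TSV.
#' @return A [reference_db] object.
#' @export
read_reference <- function(fasta_path, taxonomy_path) {
  seqs <- read_fasta(fasta_path)
  tax <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  reference_db(seqs, tax)
}

#' Write a reference database to FASTA + taxonomy TSV
#'
#' @param db a [reference_db] object.
#' @param fasta_path,taxonomy_path output paths.
#' @return `db`, invisibly.
#' @export
write_reference <- function(db, fasta_path, taxonomy_path) {
  stopifnot(inherits(db, "reference_db"))
  write_fasta(db$sequences, fasta_path)
  write_tsv(db$taxonomy, taxonomy_path)
  invisible(db)
}

# Plain-text FASTA I/O. Case and IUPAC ambiguity codes are preserved
# verbatim; files are UTF-8 with LF endings.

#' Read a FASTA file into a named character vector
#' @param path file path.
#' @return named character vector (full header line after `>` as name).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- names(set)
  out
}

#' Write a named character vector of sequences as FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  stopifnot(!is.null(names(sequences)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    chunks <- substring(sequences[[i]],
                        seq(1L, nchar(sequences[[i]]), by = width),
                        pmin(seq(1L, nchar(sequences[[i]]), by = width) +
                               width - 1L, nchar(sequences[[i]])))
    writeLines(c(paste0(">", names(sequences)[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

# TSV writer with deterministic formatting (LF, no quoting, no rownames).
write_tsv <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", eol = "\n")
  invisible(path)
}

#' Build a query-fragment table
#'
#' Query fragments are sequences recovered from individual dung fibres.
#' Truth labels (for simulated data) travel in the FASTA header as a
#' `|taxon|` token so no side file is needed; [read_queries()] recovers
#' them.
#'
#' @param seq_ids character vector of ids.
#' @param sequences character vector of DNA sequences.
#' @param dung_pile_ids sampling-unit id per fragment.
#' @param truth_taxon optional true source species id (or `"novel"`).
#' @param min_length QC length threshold; a fragment passes QC when it is
#'   strictly longer than this (see [qc_filter()]).
#' @return data frame of class `query_fragments` with columns `seq_id`,
#'   `sequence`, `length`, `dung_pile_id`, `truth_taxon`, `passed_qc`.
#' @export
make_query_fragments <- function(seq_ids, sequences, dung_pile_ids = NA,
                                 truth_taxon = NA, min_length = 120L) {
  stopifnot(length(seq_ids) == length(sequences))
  n <- length(seq_ids)
  out <- data.frame(
    seq_id = as.character(seq_ids),
    sequence = as.character(sequences),
    length = nchar(as.character(sequences)),
    dung_pile_id = rep_len(as.character(dung_pile_ids), n),
    truth_taxon = rep_len(as.character(truth_taxon), n),
    stringsAsFactors = FALSE)
  out$passed_qc <- out$length > min_length
  class(out) <- c("query_fragments", class(out))
  out
}

#' Length-based quality filter for query fragments
#'
#' Sanger reads from degraded dung template shorter than the threshold
#' are unreliable for barcode matching and are discarded. "Longer than"
#' is read strictly by default: a fragment of exactly `min_length` bases
#' is discarded. Set `inclusive = TRUE` to keep the boundary length.
#'
#' @param fragments a `query_fragments` data frame.
#' @param min_length threshold in bases (default 120).
#' @param inclusive keep fragments of exactly `min_length` bases.
#' @return list with elements `kept` and `discarded`; together they
#'   partition the input.
#' @export
qc_filter <- function(fragments, min_length = 120L, inclusive = FALSE) {
  keep <- if (inclusive) fragments$length >= min_length
          else fragments$length > min_length
  kept <- fragments[keep, , drop = FALSE]
  discarded <- fragments[!keep, , drop = FALSE]
  kept$passed_qc <- rep(TRUE, nrow(kept))
  discarded$passed_qc <- rep(FALSE, nrow(discarded))
  rownames(kept) <- NULL
  rownames(discarded) <- NULL
  list(kept = kept, discarded = discarded)
}

#' Write query fragments as FASTA with embedded truth labels
#' @param fragments a `query_fragments` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_queries <- function(fragments, path) {
  headers <- ifelse(
    is.na(fragments$truth_taxon),
    paste0(fragments$seq_id, "|", fragments$dung_pile_id),
    paste0(fragments$seq_id, "|", fragments$dung_pile_id, "|",
           fragments$truth_taxon, "|"))
  seqs <- fragments$sequence
  names(seqs) <- headers
  write_fasta(seqs, path)
}

#' Read query fragments from FASTA, recovering embedded labels
#' @param path query FASTA path.
#' @param min_length QC threshold passed to [make_query_fragments()].
#' @return `query_fragments` data frame.
#' @export
read_queries <- function(path, min_length = 120L) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  make_query_fragments(
    seq_ids = vapply(parts, `[`, "", 1L),
    sequences = unname(seqs),
    dung_pile_ids = vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, ""),
    truth_taxon = vapply(parts, function(p)
      if (length(p) >= 3L) p[3L] else NA_character_, ""),
    min_length = min_length)
}
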