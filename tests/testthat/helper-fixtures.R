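# Shared fixture builders and independent oracles used across test files.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly k bases at given (or random interior) positions
mutate_seq <- function(seq, k, positions = NULL, margin = 5L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (is.null(positions)) {
    positions <- sample(seq.int(margin + 1L, length(ch) - margin), k)
  }
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# a small hand-built reference database: 2 families x 2 genera x 2 species
toy_db <- function(seq_length = 200L) {
  ids <- c("SpA1a", "SpA1b", "SpA2a", "SpA2b",
           "SpB1a", "SpB1b", "SpB2a", "SpB2b")
  seqs <- vapply(ids, function(i) random_dna(seq_length), "")
  tax <- data.frame(
    seq_id = ids,
    species = ids,
    genus = rep(c("GenA1", "GenA2", "GenB1", "GenB2"), each = 2L),
    family = rep(c("FamA", "FamB"), each = 4L),
    stringsAsFactors = FALSE)
  reference_db(seqs, tax)
}

# brute-force connected components on a precomputed link matrix,
# independent of igraph: breadth-first flood fill in base R
bf_components <- function(link) {
  n <- nrow(link)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    frontier <- i
    comp[i] <- k
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(link[v, ] & is.na(comp))
        comp[nb] <- k
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  comp
}

# partition of ids -> canonical representation for set comparison
canon_partition <- function(groups) {
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[`, "", 1L))])
}

# hits table shaped like search_reference() output, for assignment tests
fake_hits <- function(ref_ids, scores, query_id = "q1") {
  if (length(ref_ids) == 0L) {
    return(data.frame(query_id = character(0), ref_id = character(0),
                      mismatch_score = numeric(0)))
  }
  data.frame(query_id = query_id, ref_id = ref_ids,
             mismatch_score = scores,
             n_mismatches = NA_integer_, n_gap_openings = NA_integer_,
             alignment_length = NA_integer_, coverage = 1,
             strand = "+", stringsAsFactors = FALSE)[order(scores), ]
}

# incidence matrix realizing prescribed per-taxon sample frequencies
incidence_from_freqs <- function(freqs, m) {
  stopifnot(all(freqs <= m))
  x <- matrix(0L, nrow = m, ncol = length(freqs),
              dimnames = list(sprintf("s%02d", seq_len(m)),
                              sprintf("t%02d", seq_along(freqs))))
  for (j in seq_along(freqs)) {
    if (freqs[j] > 0L) x[sample(m, freqs[j]), j] <- 1L
  }
  x
}

# minimal diet-record row constructor
diet_rec <- function(species = NA, genus = NA, family, source = "D",
                     item = "fruit", sample_id = NA, month = NA,
                     seed_condition = NA) {
  data.frame(taxon_species = species, taxon_genus = genus,
             taxon_family = family, source = source, item = item,
             sample_id = sample_id, month = month,
             seed_condition = seed_condition, stringsAsFactors = FALSE)
}
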