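#' Single-linkage clustering of sequences into minimum taxa
#'
#' Two sequences are linked when their best-alignment divergence
#' (mismatch score) is at most `max_divergence` and the aligned region
#' covers at least `min_length_compared` of the shorter sequence of the
#' pair. Clusters are the connected components of the link graph (single
#' linkage), so sequences differing by more than the cutoff can still
#' share a cluster through a chain of close neighbours. Pairs failing
#' the compared-length requirement contribute no edge: they are neither
#' linked nor forced apart. The number of clusters is a floor on the
#' number of species present ("minimum richness").
#'
#' @param sequences named character vector of DNA sequences, or a
#'   `query_fragments` data frame (its QC status is not re-checked).
#' @param max_divergence divergence cutoff; "differing by more than 5%"
#'   is read strictly, so a pair at exactly 5% is still linked.
#' @param min_length_compared minimum aligned fraction of the shorter
#'   sequence for a pair to be comparable.
#' @param both_strands compare both orientations of each pair.
#' @return list of class `cluster_set`: `clusters` (list of character
#'   vectors of sequence ids, ordered by first id), `params`.
#' @export
cluster_sequences <- function(sequences, max_divergence = 0.05,
                              min_length_compared = 0.95,
                              both_strands = TRUE) {
  stopifnot(max_divergence > 0, max_divergence <= 1,
            min_length_compared > 0, min_length_compared <= 1)
  if (is.data.frame(sequences)) {
    seqs <- sequences$sequence
    names(seqs) <- sequences$seq_id
  } else {
    seqs <- sequences
  }
  params <- list(max_divergence = max_divergence,
                 min_length_compared = min_length_compared)
  if (length(seqs) == 0L) {
    return(structure(list(clusters = list(), params = params),
                     class = "cluster_set"))
  }
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  ids <- names(seqs)
  n <- length(seqs)
  edges <- matrix(character(0), ncol = 2L)
  if (n > 1L) {
    el <- list()
    for (a in seq_len(n - 1L)) {
      for (b in seq.int(a + 1L, n)) {
        pd <- pair_divergence(seqs[[a]], seqs[[b]],
                              both_strands = both_strands)
        if (!is.na(pd$divergence) &&
            pd$divergence <= max_divergence &&
            pd$compared >= min_length_compared) {
          el[[length(el) + 1L]] <- c(ids[a], ids[b])
        }
      }
    }
    if (length(el)) edges <- do.call(rbind, el)
  }
  edge_df <- data.frame(from = edges[, 1L], to = edges[, 2L],
                        stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edge_df, directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  clusters <- split(names(comp), comp)
  clusters <- lapply(clusters, function(x) sort(x))
  clusters <- unname(clusters[order(vapply(clusters, `[`, "", 1L))])
  structure(list(clusters = clusters, params = params),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d sequences (<=%.1f%% divergence, >=%.0f%% length compared)\n",
              length(x$clusters), sum(lengths(x$clusters)),
              100 * x$params$max_divergence,
              100 * x$params$min_length_compared))
  invisible(x)
}

#' Minimum cumulated richness implied by a clustering
#'
#' @param clusters a `cluster_set` from [cluster_sequences()].
#' @return number of clusters (a lower bound on species present).
#' @export
min_richness <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  length(clusters$clusters)
}

#' Cluster membership as a table
#' @param clusters a `cluster_set`.
#' @return data frame with columns `cluster_id`, `seq_id`.
#' @export
cluster_table <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (!length(clusters$clusters)) {
    return(data.frame(cluster_id = integer(0), seq_id = character(0)))
  }
  data.frame(
    cluster_id = rep(seq_along(clusters$clusters),
                     lengths(clusters$clusters)),
    seq_id = unlist(clusters$clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
}
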