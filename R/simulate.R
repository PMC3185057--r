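#' Simulation configuration for synthetic barcode data
#'
#' Bundles the parameters of the synthetic reference/query generator.
#' The three band parameters are target pairwise divergences, chosen so
#' that realized divergences discriminate the three identification
#' ranks: fragments of the same species differ by less than the species
#' threshold (0.3%), congeneric species fall between the species and
#' genus thresholds (0.3--2%), confamilial genera between the genus and
#' family thresholds (2--4%), and species of different families beyond
#' the family threshold.
#'
#' @param n_families,genera_per_family,species_per_genus tree shape.
#' @param seq_length reference barcode length in bases (the trnH-psbA
#'   spacer is roughly 500 bp).
#' @param species_band target within-species divergence budget
#'   (degradation level at which fragments stay species-assignable).
#' @param genus_band target divergence between congeneric species.
#' @param family_band target divergence between confamilial genera.
#' @param interfamily_divergence target divergence between families,
#'   beyond the family threshold.
#' @param substitution_rate,indel_rate per-base degradation rates applied
#'   to query fragments.
#' @param truncation_range length range (bases) from which query
#'   fragment lengths are drawn uniformly.
#' @param frac_short fraction of queries drawn instead from
#'   `short_range`, to exercise the length QC filter.
#' @param short_range length range for the deliberately short fraction.
#' @param frac_novel fraction of queries drawn from species absent from
#'   the reference (each novel species sits at genus-band divergence
#'   from its congeners).
#' @param seed integer seed; a fixed seed makes every generator output
#'   bit-identical across runs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_families = 5L, genera_per_family = 2L,
                       species_per_genus = 2L, seq_length = 500L,
                       species_band = 0.002, genus_band = 0.015,
                       family_band = 0.035,
                       interfamily_divergence = 0.06,
                       substitution_rate = 0, indel_rate = 0,
                       truncation_range = c(200L, 450L),
                       frac_short = 0, short_range = c(60L, 120L),
                       frac_novel = 0, seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              genera_per_family = as.integer(genera_per_family),
              species_per_genus = as.integer(species_per_genus),
              seq_length = as.integer(seq_length),
              species_band = species_band, genus_band = genus_band,
              family_band = family_band,
              interfamily_divergence = interfamily_divergence,
              substitution_rate = substitution_rate,
              indel_rate = indel_rate,
              truncation_range = as.integer(truncation_range),
              frac_short = frac_short,
              short_range = as.integer(short_range),
              frac_novel = frac_novel, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_families < 1L || genera_per_family < 1L || species_per_genus < 1L)
      stop("tree shape counts must be positive")
    if (!(species_band < genus_band && genus_band < family_band &&
          family_band < interfamily_divergence))
      stop("divergence bands must be strictly ordered: ",
           "species < genus < family < interfamily")
    if (any(c(species_band, genus_band, family_band) <= 0))
      stop("divergence bands must be positive")
    rates <- c(substitution_rate, indel_rate, frac_short, frac_novel)
    if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
    if (length(truncation_range) != 2L ||
        truncation_range[1] > truncation_range[2] ||
        truncation_range[1] < 1L)
      stop("truncation_range must be an increasing pair of lengths")
  })
  invisible(cfg)
}

.other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
}

.mutate_at <- function(chars, positions) {
  if (length(positions)) chars[positions] <- .other_base(chars[positions])
  chars
}

#' Generate a band-calibrated synthetic reference database
#'
#' Builds a balanced family/genus/species taxonomy and one barcode
#' sequence per species by planting point substitutions along the tree at
#' globally disjoint positions: two species then differ exactly by the
#' substitutions on the branches between them, so pairwise divergences
#' land at the configured band targets by construction. Sequence ends are
#' left untouched so local alignment recovers full-length overlaps. Each
#' candidate database is audited with [divergence_audit()]; the rare
#' draw whose realized divergences stray outside the rank bands is
#' rejected and resampled.
#'
#' @param config a [sim_config()].
#' @param audit verify realized pairwise divergences by alignment and
#'   resample on violation (on by default; disable for large trees).
#' @param thresholds rank thresholds the audit checks against.
#' @return A [reference_db] with attribute `sim_info` used by
#'   [generate_queries()] to create novel-species queries.
#' @export
generate_reference <- function(config, audit = TRUE,
                               thresholds = assignment_thresholds()) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$seq_length
  n_gen <- config$n_families * config$genera_per_family
  n_sp <- n_gen * config$species_per_genus
  # per-branch substitution counts so path lengths hit the band targets;
  # ranks with a single child need no separating branch
  s <- max(1L, round(config$genus_band * L / 2))
  g <- if (config$genera_per_family == 1L) 0L
       else max(1L, round((config$family_band * L - 2 * s) / 2))
  f <- if (config$n_families == 1L) 0L
       else max(1L, round((config$interfamily_divergence * L -
                             2 * s - 2 * g) / 2))
  # reserve one species branch per genus for novel-species queries
  needed <- (n_sp + n_gen) * s + n_gen * g + config$n_families * f
  margin <- 10L  # untouched bases at each end
  if (needed > L - 2L * margin)
    stop("configuration error: sequence too short for the requested ",
         "tree and divergence bands (need ", needed, " mutable sites, ",
         L - 2L * margin, " available)")
  for (try in seq_len(5L)) {
    set.seed(config$seed + (try - 1L) * 1000003L)
    db <- .build_reference(config, L, s, g, f, margin)
    if (!audit) return(db)
    aud <- divergence_audit(db, thresholds)
    if (all(aud$ok)) return(db)
  }
  stop("could not realize the configured divergence bands after 5 draws; ",
       "widen the bands or lengthen the sequence")
}

.build_reference <- function(config, L, s, g, f, margin) {
  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  pool <- sample(seq.int(margin + 1L, L - margin))
  take <- function(n) {
    if (n == 0L) return(integer(0))
    if (n > length(pool)) stop("mutation position pool exhausted")
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  seqs <- character(0)
  tax <- list()
  genus_anc <- list()
  for (i in seq_len(config$n_families)) {
    fam_name <- sprintf("Fam%02d", i)
    fam_seq <- .mutate_at(root, take(f))
    for (j in seq_len(config$genera_per_family)) {
      gen_name <- sprintf("Gen%02d.%02d", i, j)
      gen_seq <- .mutate_at(fam_seq, take(g))
      genus_anc[[gen_name]] <- gen_seq
      for (k in seq_len(config$species_per_genus)) {
        sp_name <- sprintf("Spec%02d.%02d.%02d", i, j, k)
        sp_seq <- .mutate_at(gen_seq, take(s))
        seqs[[sp_name]] <- paste(sp_seq, collapse = "")
        tax[[length(tax) + 1L]] <- data.frame(
          seq_id = sp_name, species = sp_name, genus = gen_name,
          family = fam_name, stringsAsFactors = FALSE)
      }
    }
  }
  db <- reference_db(seqs, do.call(rbind, tax))
  attr(db, "sim_info") <- list(genus_ancestors = genus_anc,
                               free_positions = pool,
                               species_branch_subs = s,
                               config = config)
  db
}

#' Audit realized pairwise divergences against the rank bands
#'
#' Computes the alignment divergence ([pair_divergence()]) for every pair
#' of reference sequences and checks that it falls in the interval its
#' shared rank demands: congeneric pairs between the species and genus
#' thresholds, confamilial pairs between the genus and family thresholds,
#' and pairs from different families above the family threshold.
#'
#' @param db a [reference_db].
#' @param thresholds an [assignment_thresholds()] list.
#' @return data frame with one row per pair: `id_a`, `id_b`,
#'   `shared_rank`, `divergence`, `ok`.
#' @export
divergence_audit <- function(db, thresholds = assignment_thresholds()) {
  tax <- db$taxonomy
  ids <- names(db$sequences)
  n <- length(ids)
  rows <- list()
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      shared <- if (tax$genus[a] == tax$genus[b]) "genus"
                else if (tax$family[a] == tax$family[b]) "family"
                else "none"
      d <- pair_divergence(db$sequences[[a]], db$sequences[[b]])$divergence
      lo <- switch(shared, genus = thresholds$species_max,
                   family = thresholds$genus_max,
                   none = thresholds$family_max)
      hi <- switch(shared, genus = thresholds$genus_max,
                   family = thresholds$family_max, none = Inf)
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = ids[a], id_b = ids[b], shared_rank = shared,
        divergence = d, ok = !is.na(d) && d > lo && d <= hi,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      shared_rank = character(0), divergence = numeric(0),
                      ok = logical(0)))
  }
  do.call(rbind, rows)
}

#' Generate degraded query fragments with truth labels
#'
#' Each query is a fragment of a source barcode: a contiguous substring
#' whose length is drawn from the truncation range (or, for a configured
#' fraction, from the short range that fails length QC), degraded by
#' per-base substitutions and by single-base indels whose lengths extend
#' geometrically (p = 0.5). A configured fraction of queries comes from
#' novel species absent from the reference, placed at genus-band
#' divergence inside an existing genus; their truth label is `"novel"`.
#' With all degradation rates zero and no novel fraction, every query is
#' an exact substring of its source sequence.
#'
#' @param db a [reference_db] from [generate_reference()].
#' @param config the [sim_config()] used to build `db`.
#' @param n_queries number of fragments to draw.
#' @param n_piles number of dung piles the fragments are spread over.
#' @return A `query_fragments` data frame (see [make_query_fragments()])
#'   with `truth_taxon` set to the source species or `"novel"`.
#' @export
generate_queries <- function(db, config, n_queries, n_piles = 19L) {
  stopifnot(inherits(db, "reference_db"), inherits(config, "sim_config"))
  if (length(db$sequences) == 0L) stop("reference database is empty")
  if (n_queries <= 0L) stop("n_queries must be positive")
  set.seed(config$seed + 1L)
  info <- attr(db, "sim_info")
  n_novel <- round(config$frac_novel * n_queries)
  is_novel <- rep(FALSE, n_queries)
  if (n_novel > 0L) is_novel[sample(n_queries, n_novel)] <- TRUE

  novel_pool <- character(0)
  if (n_novel > 0L) novel_pool <- .novel_species(db, config, info)

  ids <- sprintf("q%04d", seq_len(n_queries))
  seqs <- character(n_queries)
  truth <- character(n_queries)
  for (i in seq_len(n_queries)) {
    if (is_novel[i]) {
      src <- sample(length(novel_pool), 1L)
      full <- novel_pool[[src]]
      truth[i] <- "novel"
    } else {
      src <- sample(length(db$sequences), 1L)
      full <- db$sequences[[src]]
      truth[i] <- db$taxonomy$species[src]
    }
    seqs[i] <- .degrade(full, config)
  }
  piles <- sprintf("pile%02d", sample(n_piles, n_queries, replace = TRUE))
  make_query_fragments(ids, seqs, dung_pile_ids = piles,
                       truth_taxon = truth)
}

# Novel species: a fresh species branch inside each genus. With the
# generator's position bookkeeping the branch uses untouched sites, so
# divergence to congeners is exactly two species branches (genus band).
.novel_species <- function(db, config, info) {
  if (!is.null(info)) {
    pool <- info$free_positions
    s <- info$species_branch_subs
    out <- vapply(info$genus_ancestors, function(anc) {
      pos <- pool[seq_len(min(s, length(pool)))]
      pool <<- pool[-seq_len(min(s, length(pool)))]
      paste(.mutate_at(anc, pos), collapse = "")
    }, "")
    return(out)
  }
  # db not built by generate_reference: mutate references at random sites
  s <- max(1L, round(config$genus_band * config$seq_length / 2))
  vapply(db$sequences, function(sq) {
    ch <- strsplit(sq, "", fixed = TRUE)[[1L]]
    paste(.mutate_at(ch, sample(length(ch), s)), collapse = "")
  }, "")
}

.degrade <- function(full, config) {
  L <- nchar(full)
  rng <- if (stats::runif(1) < config$frac_short) config$short_range
         else config$truncation_range
  len <- if (rng[1] == rng[2]) rng[1]
         else sample(seq.int(rng[1], rng[2]), 1L)
  len <- min(L, len)
  start <- if (len == L) 1L else sample(seq_len(L - len + 1L), 1L)
  ch <- strsplit(substr(full, start, start + len - 1L), "", fixed = TRUE)[[1L]]
  # substitutions
  k <- stats::rbinom(1L, length(ch), config$substitution_rate)
  if (k > 0L) ch <- .mutate_at(ch, sample(length(ch), min(k, length(ch))))
  # indels: single-base events extended geometrically
  k <- stats::rbinom(1L, length(ch), config$indel_rate)
  for (dummy in seq_len(k)) {
    ilen <- 1L + stats::rgeom(1L, 0.5)
    at <- sample(length(ch), 1L)
    if (stats::runif(1) < 0.5) {
      ch <- append(ch, sample(c("A", "C", "G", "T"), ilen, replace = TRUE),
                   after = at)
    } else {
      drop <- seq.int(at, min(length(ch), at + ilen - 1L))
      if (length(drop) < length(ch)) ch <- ch[-drop]
    }
  }
  paste(ch, collapse = "")
}

#' Generate a random presence/absence incidence matrix
#'
#' Cells are independent Bernoulli draws: taxon `j` is detected in each
#' sample with probability `detection_prob[j]`. This mimics sparse
#' dung-pile (or feeding-site) by taxon incidence data with a controlled
#' expected number of uniques and duplicates.
#'
#' @param n_samples number of sampling units (rows).
#' @param richness true number of taxa (columns).
#' @param detection_prob scalar or per-taxon vector of detection
#'   probabilities.
#' @param seed integer seed.
#' @return binary matrix with sample rownames and taxon colnames.
#' @export
generate_incidence <- function(n_samples, richness, detection_prob,
                               seed = 1L) {
  stopifnot(n_samples >= 1L, richness >= 1L)
  if (length(detection_prob) == 1L)
    detection_prob <- rep(detection_prob, richness)
  stopifnot(length(detection_prob) == richness,
            all(detection_prob >= 0 & detection_prob <= 1))
  set.seed(seed)
  m <- vapply(seq_len(richness), function(j)
    stats::rbinom(n_samples, 1L, detection_prob[j]), integer(n_samples))
  m <- matrix(m, nrow = n_samples, ncol = richness,
              dimnames = list(sprintf("samp%03d", seq_len(n_samples)),
                              sprintf("taxon%03d", seq_len(richness))))
  m
}

#' Simulate multi-source diet records
#'
#' Draws a synthetic set of diet observations in the shape the summary
#' statistics expect: fruit residues identified in dung piles (source
#' `"D"`, with month and per-record seed condition), browse taxa at
#' feeding sites (`"B"`), ethnobotanical reports (`"W"`) and genetic
#' identifications (`"G"`). Each fruit taxon carries a latent seed
#' survival probability so some taxa are always intact, some never, and
#' the rest mixed; monthly detection follows a unimodal seasonal profile
#' peaking in April.
#'
#' @param n_fruit_taxa,n_browse_taxa taxon pool sizes.
#' @param n_piles number of dung piles (source D sampling units).
#' @param n_sites number of feeding sites (source B sampling units).
#' @param p_detect mean per-pile detection probability of a fruit taxon.
#' @param seed integer seed.
#' @return data frame with columns `taxon_species`, `taxon_genus`,
#'   `taxon_family`, `source`, `item`, `sample_id`, `month`,
#'   `seed_condition`.
#' @export
simulate_diet_records <- function(n_fruit_taxa = 40L, n_browse_taxa = 70L,
                                  n_piles = 53L, n_sites = 73L,
                                  p_detect = 0.06, seed = 1L) {
  set.seed(seed)
  mk_taxa <- function(n, tag) {
    fam <- sprintf("%sFam%02d", tag, 1L + (seq_len(n) - 1L) %/% 4L)
    gen <- sprintf("%sGen%02d", tag, 1L + (seq_len(n) - 1L) %/% 2L)
    sp <- sprintf("%sSp%02d", tag, seq_len(n))
    data.frame(taxon_species = sp, taxon_genus = gen, taxon_family = fam,
               stringsAsFactors = FALSE)
  }
  fruit <- mk_taxa(n_fruit_taxa, "Fr")
  browse <- mk_taxa(n_browse_taxa, "Br")
  # seasonal profile: peak in April, trough in August-September
  season <- 0.3 + 0.7 * exp(-((1:12 - 4)^2) / 8)
  intact_p <- stats::runif(n_fruit_taxa)

  rec <- list()
  add <- function(df) rec[[length(rec) + 1L]] <<- df
  pile_month <- sample(1:12, n_piles, replace = TRUE,
                       prob = season / sum(season))
  for (p in seq_len(n_piles)) {
    mo <- pile_month[p]
    present <- which(stats::runif(n_fruit_taxa) <
                       p_detect * season[mo] / mean(season) * 2)
    for (t in present) {
      cond <- if (stats::runif(1) < intact_p[t]) "intact" else "damaged"
      add(data.frame(fruit[t, ], source = "D", item = "fruit",
                     sample_id = sprintf("pile%02d", p), month = mo,
                     seed_condition = cond, stringsAsFactors = FALSE))
    }
  }
  for (s in seq_len(n_sites)) {
    present <- sample(n_browse_taxa, size = 1L + stats::rpois(1L, 1.5))
    for (t in present) {
      add(data.frame(browse[t, ], source = "B", item = "browse",
                     sample_id = sprintf("site%02d", s),
                     month = sample(1:12, 1L), seed_condition = NA,
                     stringsAsFactors = FALSE))
    }
  }
  w_fruit <- sample(n_fruit_taxa, min(19L, n_fruit_taxa))
  w_browse <- sample(n_browse_taxa, min(26L, n_browse_taxa))
  add(cbind(fruit[w_fruit, ], source = "W", item = "fruit",
            sample_id = NA, month = NA, seed_condition = NA))
  add(cbind(browse[w_browse, ], source = "W", item = "browse",
            sample_id = NA, month = NA, seed_condition = NA))
  g_browse <- sample(n_browse_taxa, min(15L, n_browse_taxa))
  add(cbind(browse[g_browse, ], source = "G", item = "browse",
            sample_id = NA, month = NA, seed_condition = NA))
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}
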