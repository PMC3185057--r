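test_that("a degenerate one-species tree yields a single fully ranked record", {
  cfg <- sim_config(n_families = 1L, genera_per_family = 1L,
                    species_per_genus = 1L, seed = 2L)
  db <- generate_reference(cfg)
  expect_length(db$sequences, 1L)
  expect_equal(nrow(db$taxonomy), 1L)
  expect_false(any(is.na(db$taxonomy[, c("species", "genus", "family")])))
  expect_equal(nchar(db$sequences[[1L]]), cfg$seq_length)
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(n_families = 2L, genera_per_family = 2L,
                    species_per_genus = 2L, substitution_rate = 0.002,
                    indel_rate = 0.001, frac_novel = 0.2, seed = 7L)
  db1 <- generate_reference(cfg)
  db2 <- generate_reference(cfg)
  expect_identical(db1$sequences, db2$sequences)
  expect_identical(db1$taxonomy, db2$taxonomy)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_reference(db1, f1, paste0(f1, ".tsv"))
  write_reference(db2, f2, paste0(f2, ".tsv"))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  q1 <- generate_queries(db1, cfg, 30L)
  q2 <- generate_queries(db2, cfg, 30L)
  expect_identical(q1, q2)
  expect_identical(generate_incidence(10L, 8L, 0.3, seed = 9L),
                   generate_incidence(10L, 8L, 0.3, seed = 9L))
})

test_that("realized pairwise divergences land in their rank bands", {
  cfg <- sim_config(n_families = 2L, genera_per_family = 2L,
                    species_per_genus = 2L, species_band = 0.002,
                    genus_band = 0.015, family_band = 0.035, seed = 13L)
  db <- generate_reference(cfg)
  # brute force: all 28 pairs through the alignment module, with the
  # band intervals restated independently of divergence_audit()
  ids <- names(db$sequences)
  tax <- db$taxonomy
  n_pairs <- 0L
  for (a in seq_len(length(ids) - 1L)) {
    for (b in seq.int(a + 1L, length(ids))) {
      d <- pair_divergence(db$sequences[[a]], db$sequences[[b]])$divergence
      n_pairs <- n_pairs + 1L
      if (tax$genus[a] == tax$genus[b]) {
        expect_gt(d, 0.003); expect_lte(d, 0.020)
      } else if (tax$family[a] == tax$family[b]) {
        expect_gt(d, 0.020); expect_lte(d, 0.040)
      } else {
        expect_gt(d, 0.040)
      }
    }
  }
  expect_equal(n_pairs, choose(8L, 2L))
  expect_true(all(divergence_audit(db)$ok))
})

test_that("band infeasibility is a configuration error", {
  expect_error(sim_config(species_band = 0.02, genus_band = 0.015),
               "ordered")
  expect_error(generate_reference(sim_config(seq_length = 60L)),
               "too short")
  expect_error(
    generate_reference(sim_config(n_families = 10L,
                                  genera_per_family = 5L,
                                  species_per_genus = 5L,
                                  seq_length = 300L)),
    "too short")
})

test_that("undegraded queries are exact substrings of their source", {
  cfg <- sim_config(n_families = 2L, genera_per_family = 2L,
                    species_per_genus = 2L, seed = 3L)
  db <- generate_reference(cfg)
  q <- generate_queries(db, cfg, 40L)
  expect_true(all(q$truth_taxon %in% db$taxonomy$species))
  for (i in seq_len(nrow(q))) {
    src <- db$sequences[[q$truth_taxon[i]]]
    expect_true(grepl(q$sequence[i], src, fixed = TRUE))
  }
})

test_that("fully novel query sets contain no reference taxon", {
  cfg <- sim_config(n_families = 2L, genera_per_family = 2L,
                    species_per_genus = 2L, frac_novel = 1, seed = 4L)
  db <- generate_reference(cfg)
  q <- generate_queries(db, cfg, 25L)
  expect_true(all(q$truth_taxon == "novel"))
  expect_error(generate_queries(db, cfg, 0L), "positive")
})

test_that("empirical substitution counts match the binomial expectation", {
  L <- 500L
  rate <- 0.001
  cfg <- sim_config(n_families = 2L, genera_per_family = 2L,
                    species_per_genus = 2L, seq_length = L,
                    substitution_rate = rate,
                    truncation_range = c(L, L), seed = 11L)
  db <- generate_reference(cfg)
  q <- generate_queries(db, cfg, 200L)
  total <- 0L
  for (i in seq_len(nrow(q))) {
    src <- strsplit(db$sequences[[q$truth_taxon[i]]], "")[[1L]]
    frag <- strsplit(q$sequence[i], "")[[1L]]
    expect_length(frag, L)   # full-length truncation range
    total <- total + sum(src != frag)
  }
  n_bases <- 200L * L
  expect_lt(abs(total - n_bases * rate),
            3 * sqrt(n_bases * rate * (1 - rate)))
})

test_that("incidence generator honours degenerate detection probabilities", {
  all_on <- generate_incidence(6L, 5L, 1, seed = 1L)
  expect_true(all(all_on == 1L))
  freq <- colSums(all_on)
  expect_equal(sum(freq == 1L), 0L)  # no uniques
  expect_equal(sum(freq == 2L), 0L)  # no duplicates
  all_off <- generate_incidence(6L, 5L, 0, seed = 1L)
  expect_true(all(all_off == 0L))
  expect_equal(sum(colSums(all_off) > 0L), 0L)
})

test_that("observed richness equals the brute-force nonzero-column count", {
  x <- generate_incidence(50L, 40L, 0.05, seed = 3L)
  s_obs <- sum(colSums(x) > 0L)
  expect_lte(s_obs, 40L)
  expect_equal(chao2(x)$S_obs, s_obs)
})

test_that("incidence marginals track their binomial expectation", {
  n <- 200L; rich <- 30L; p <- 0.2
  x <- generate_incidence(n, rich, p, seed = 21L)
  expect_lt(abs(sum(x) - n * rich * p),
            3 * sqrt(n * rich * p * (1 - p)))
})
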