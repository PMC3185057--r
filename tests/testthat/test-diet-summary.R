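test_that("success rates reproduce the printed pipeline arithmetic", {
  sr <- success_rates(410L, 95L, 57L)
  expect_equal(unname(sr$rounded), c(23L, 14L, 60L))
  expect_equal(sr$amplification_pct, 100 * 95 / 410)
  sr2 <- success_rates(100L, 100L, 100L)
  expect_equal(unname(sr2$rounded), c(100L, 100L, 100L))
  sr3 <- success_rates(1000L, 250L, 100L)
  expect_equal(unname(sr3$rounded), c(25L, 10L, 40L))
})

test_that("success rates validate counts and flag zero denominators", {
  expect_error(success_rates(10L, 12L, 5L))
  expect_error(success_rates(10L, 5L, 7L))
  sr <- success_rates(0L, 0L, 0L)
  expect_true(is.na(sr$amplification_pct))
  expect_true(is.na(sr$sequencing_success_pct))
})

test_that("method overlap matches brute-force set algebra", {
  recs <- rbind(
    diet_rec(species = c("s1", "s2", "s3"), genus = c("g1", "g1", "g2"),
             family = c("f1", "f1", "f2"), source = "W"),
    diet_rec(species = c("s2", "s3", "s4"), genus = c("g1", "g2", "g3"),
             family = c("f1", "f2", "f2"), source = "B"),
    diet_rec(species = c("s3", "s5"), genus = c("g2", "g4"),
             family = c("f2", "f3"), source = "D"))
  ov <- method_overlap(recs)$fruit
  # species sets: W {s1,s2,s3}, B {s2,s3,s4}, D {s3,s5}
  expect_equal(unname(ov$species$counts), c(3L, 2L, 3L))  # B, D, W order
  expect_equal(unname(ov$species$pairwise[["B&D"]]), 1L)  # {s3}
  expect_equal(unname(ov$species$pairwise[["B&W"]]), 2L)  # {s2,s3}
  expect_equal(ov$species$all_sources, 1L)                # {s3}
  # W species found by B or D: s2, s3 of 3 -> 66.7%
  expect_equal(ov$species$pct_found_by_others[["W"]], 100 * 2 / 3)
  # family sets: W {f1,f2}, B {f1,f2}, D {f2,f3}
  expect_equal(ov$family$all_sources, 1L)
  expect_equal(ov$family$pct_found_by_others[["W"]], 100)
})

test_that("a single source has no overlap; identical lists overlap fully", {
  solo <- diet_rec(species = c("s1", "s2"), genus = c("g1", "g2"),
                   family = c("f1", "f2"), source = "W")
  ov <- method_overlap(solo)$fruit
  expect_equal(ov$species$pct_found_by_others[["W"]], 0)
  dup <- rbind(solo, transform(solo, source = "D"))
  ov2 <- method_overlap(dup)$fruit
  for (rk in c("species", "genus", "family")) {
    expect_true(all(ov2[[rk]]$pct_found_by_others == 100))
  }
})

test_that("seasonal fruit diversity reproduces hand-computed statistics", {
  one <- diet_rec(species = paste0("s", 1:4), genus = paste0("g", 1:4),
                  family = paste0("f", 1:4), sample_id = "p1", month = 4L,
                  seed_condition = "intact")
  out <- seasonal_fruit_diversity(one)
  expect_equal(out$month, 4L)
  expect_equal(out$mean_taxa, 4)
  expect_equal(out$sd_taxa, 0)
  # two piles with 2 and 6 taxa: mean 4, sample SD = sqrt(8) ~ 2.828
  two <- rbind(
    diet_rec(species = paste0("a", 1:2), genus = paste0("ga", 1:2),
             family = paste0("fa", 1:2), sample_id = "p1", month = 5L),
    diet_rec(species = paste0("b", 1:6), genus = paste0("gb", 1:6),
             family = paste0("fb", 1:6), sample_id = "p2", month = 5L))
  out2 <- seasonal_fruit_diversity(two)
  expect_equal(out2$mean_taxa, 4)
  expect_equal(out2$sd_taxa, sqrt(8), tolerance = 1e-12)
  expect_equal(seasonal_fruit_diversity(two, sd_type = "population")$sd_taxa,
               2)
})

test_that("per-month statistics equal a brute-force group-by", {
  recs <- simulate_diet_records(n_fruit_taxa = 20L, n_piles = 30L,
                                seed = 5L)
  out <- seasonal_fruit_diversity(recs)
  d <- recs[recs$source == "D" & recs$item == "fruit", ]
  for (i in seq_len(nrow(out))) {
    mo <- out$month[i]
    piles <- unique(d$sample_id[d$month == mo])
    counts <- vapply(piles, function(p)
      length(unique(d$taxon_species[d$sample_id == p & d$month == mo])),
      integer(1L))
    expect_equal(out$n_piles[i], length(piles))
    expect_equal(out$mean_taxa[i], mean(counts))
  }
  # months with no piles are absent
  expect_true(all(out$n_piles > 0L))
})

test_that("taxon frequency filters are strict and counts match a recount", {
  mk <- function(genus, family, piles) {
    do.call(rbind, lapply(piles, function(p)
      diet_rec(species = paste0(genus, "_sp"), genus = genus,
               family = family, sample_id = p, month = 1L)))
  }
  recs <- rbind(
    mk("g3", "f3", paste0("p", 1:3)),   # genus in 3 piles: excluded
    mk("g4", "f4", paste0("p", 1:4)),   # genus in 4 piles: included
    mk("fam4a", "F4", paste0("p", 1:2)),
    mk("fam4b", "F4", paste0("p", 3:4)),  # family F4 in 4 piles: excluded
    mk("fam5a", "F5", paste0("p", 1:3)),
    mk("fam5b", "F5", paste0("p", 3:5)))  # family F5 in 5 piles: included
  tf <- taxon_frequency(recs)
  gen <- tf[tf$rank == "genus", ]
  expect_false("g3" %in% gen$taxon)
  expect_true("g4" %in% gen$taxon)
  fam <- tf[tf$rank == "family", ]
  expect_false("F4" %in% fam$taxon)
  expect_true("F5" %in% fam$taxon)
  expect_equal(fam$n_piles[fam$taxon == "F5"], 5L)
  # empty input gives an empty table
  expect_equal(nrow(taxon_frequency(recs[0L, ])), 0L)
  # lowering a threshold never removes a row
  loose <- taxon_frequency(recs, min_family_piles = 1L,
                           min_genus_piles = 1L)
  expect_true(all(paste(tf$rank, tf$taxon) %in%
                    paste(loose$rank, loose$taxon)))
})

test_that("pile counts equal a brute-force distinct count on random fixtures", {
  recs <- simulate_diet_records(n_fruit_taxa = 15L, n_piles = 40L,
                                p_detect = 0.15, seed = 9L)
  tf <- taxon_frequency(recs, min_family_piles = 1L, min_genus_piles = 1L)
  d <- recs[recs$source == "D" & recs$item == "fruit", ]
  for (i in which(tf$rank == "genus")) {
    expect_equal(tf$n_piles[i],
                 length(unique(d$sample_id[d$taxon_genus == tf$taxon[i]])))
  }
})

test_that("seed intactness reproduces the hand tally and subset property", {
  all_int <- diet_rec(species = c("a", "b"), genus = c("ga", "gb"),
                      family = c("fa", "fb"), sample_id = "p1",
                      month = 1L, seed_condition = "intact")
  si <- seed_intactness(all_int)
  expect_equal(si$pct_sometimes_intact, 100)
  expect_equal(si$pct_always_intact, 100)
  # A: intact,intact; B: intact,damaged; C: damaged
  mixed <- rbind(
    diet_rec("A", "gA", "fA", sample_id = c("p1", "p2"), month = 1L,
             seed_condition = "intact"),
    diet_rec("B", "gB", "fB", sample_id = c("p1", "p2"), month = 1L,
             seed_condition = c("intact", "damaged")),
    diet_rec("C", "gC", "fC", sample_id = "p1", month = 1L,
             seed_condition = "damaged"))
  si2 <- seed_intactness(mixed)
  expect_equal(si2$pct_sometimes_intact, 100 * 2 / 3)
  expect_equal(si2$pct_always_intact, 100 * 1 / 3)
  # always-intact is a subset of sometimes-intact on random fixtures
  for (s in 1:5) {
    recs <- simulate_diet_records(n_fruit_taxa = 12L, n_piles = 25L,
                                  seed = s)
    si3 <- seed_intactness(recs)
    expect_lte(si3$pct_always_intact, si3$pct_sometimes_intact)
    expect_gte(si3$pct_sometimes_intact, 0)
    expect_lte(si3$pct_sometimes_intact, 100)
  }
})

test_that("diet records round-trip through TSV", {
  recs <- simulate_diet_records(n_fruit_taxa = 8L, n_piles = 10L,
                                n_browse_taxa = 10L, n_sites = 5L,
                                seed = 3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_diet_records(recs, f)
  back <- read_diet_records(f)
  expect_equal(back$taxon_species, recs$taxon_species)
  expect_equal(back$seed_condition, recs$seed_condition)
  expect_equal(back$month, recs$month)
})
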