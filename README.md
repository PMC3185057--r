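# dietbarcode

Diet metabarcoding for elusive herbivores: taxonomic assignment of
degraded plant DNA barcode fragments, minimum-taxa clustering, and
incidence-based diet diversity.

## What it does, and for whom

Field studies of large tropical herbivores (the motivating case is the
lowland tapir, *Tapirus terrestris*) recover short, degraded fragments
of a chloroplast barcode — typically the trnH-psbA spacer, ~500 bp —
from plant fibres in dung. Identifying those fragments against a
regional reference database, and turning the identifications into diet
diversity statistics, is the job of this package. It is aimed at
molecular ecologists running desk-scale analyses of Sanger-sequenced
dung amplicons against curated reference sets.

The analysis chain:

1. **QC** — keep fragments strictly longer than 120 bp.
2. **Match** — Smith–Waterman local alignment of each query against
   every reference (both strands), scored by the mismatch statistic

   *d* = (gap openings + mismatched columns) / alignment length,

   where each maximal gap run in either row counts once.
3. **Assign** — the best hit's score picks a rank with calibrated
   ceilings: *d* < 0.3% same species, < 2.0% same genus, < 4% same
   family, otherwise unassigned. Hits tied inside the best hit's band
   vote, and disagreement demotes the call to their lowest common rank.
4. **Cluster** — unassigned fragments are grouped into minimum putative
   taxa: single-linkage components under divergence ≤ 5% with ≥ 95% of
   the shorter sequence aligned. The cluster count is a floor on
   species richness.
5. **Richness** — sample-based rarefaction (500 randomized sample
   orders) with the Mao Tau closed form as analytic reference, and the
   Chao2 estimator S_obs + ((m−1)/m)·Q1²/(2Q2) (bias-corrected form
   when Q2 = 0) with a log-normal 95% interval.
6. **Diet summaries** — amplification/sequencing success rates, overlap
   between evidence sources (ethnobotanical, botanical, dung residue,
   genetic), monthly fruit diversity in dung, recurrent-taxon
   frequencies, and seed-intactness proportions.

A synthetic-data module generates reference databases whose pairwise
divergences are calibrated to the assignment bands, degraded query
fragments with truth labels, incidence matrices, and multi-source diet
records — so the whole pipeline is testable without any field data.

## Worked example

```r
library(dietbarcode)

cfg <- sim_config(n_families = 3, genera_per_family = 2, species_per_genus = 2,
                  substitution_rate = 5e-4, truncation_range = c(350, 480),
                  frac_novel = 0.1, seed = 7)
db <- generate_reference(cfg)
db
#> reference_db: 12 sequences, 12 species / 6 genera / 3 families

queries <- generate_queries(db, cfg, 40)
kept <- qc_filter(queries)$kept
head(search_reference(kept[1, ], db)[, c("ref_id", "mismatch_score", "strand")], 3)
#>         ref_id mismatch_score strand
#> 1 Spec03.01.02     0.00000000      +
#> 2 Spec03.01.01     0.01773836      +
#> 3 Spec03.02.01     0.03991131      +

calls <- assign_all(kept, db)
tally_assignments(calls)
#> $queries_per_rank
#>    species      genus     family unassigned
#>         36          1          3          0
#> $distinct_taxa
#> species   genus  family
#>      12       6       3
```

The first query's top hit is its true source at zero mismatches; the
next hits are its congener (1.8%, genus band) and a confamilial genus
(4.0%, just outside the family band). Of 40 fragments, 36 are called to
species; the four fragments simulated from *novel* species (absent from
the reference) are correctly held at genus rank or coarser — never
species. The distinct-taxon tally recovers the full 12/6/3 taxonomy.

```r
inc <- generate_incidence(n_samples = 20, richness = 30, detection_prob = 0.15, seed = 7)
chao2(inc)
#> Chao2 (classic): S_obs = 29, S_est = 30.3 [29.2, 38.7]  (m = 20, Q1 = 4, Q2 = 6)

tail(rarefy_incidence(inc, R = 500, seed = 7), 3)
#>     t   mean        sd
#> 18 18 28.524 0.7606452
#> 19 19 28.782 0.5244293
#> 20 20 29.000 0.0000000
```

29 of 30 taxa were detected; with 4 uniques and 6 duplicates Chao2
estimates 30.3 total, and the accumulation curve ends exactly at
S_obs = 29 with zero spread.

A full reproducible run — simulation, thinning by amplification and
sequencing success, QC, assignment, clustering, richness, summaries,
and a JSON manifest — is one call:

```r
run_pipeline(pipeline_config("out_dir", seed = 1))
```

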