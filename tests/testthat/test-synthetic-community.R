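test_that("reference generation is seed-deterministic and respects divergence", {
  a <- generate_reference_db(n_species = 10, seed = 42)
  b <- generate_reference_db(n_species = 10, seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a$refs$sequence,
    generate_reference_db(n_species = 10, seed = 43)$refs$sequence))

  # ranks descend root -> leaf and every species reaches the root
  tax <- a$taxonomy
  rank_idx <- setNames(seq_along(ambin:::TAX_RANKS), ambin:::TAX_RANKS)
  non_root <- tax[!is.na(tax$parent_id), ]
  parent_rank <- tax$rank[match(non_root$parent_id, tax$taxon_id)]
  expect_true(all(rank_idx[non_root$rank] == rank_idx[parent_rank] + 1))
  species <- tax$taxon_id[tax$rank == "species"]
  expect_true(all(vapply(species, depth_of, numeric(1),
                         taxonomy = tax) == 6))

  expect_error(generate_reference_db(n_species = 1), "n_species")
  expect_error(generate_reference_db(n_species = 4, fragment_length = 10),
               "fragment_length")
})

test_that("within-genus divergence matches the requested rate", {
  db0 <- generate_reference_db(n_species = 4, species_per_genus = 2,
                               divergence = 0, identical_fraction = 0,
                               seed = 5)
  genus <- db0$taxonomy$parent_id[match(db0$refs$taxon_id,
                                        db0$taxonomy$taxon_id)]
  sib <- split(db0$refs$sequence, genus)
  for (s in sib) expect_identical(s[1], s[2])

  db <- generate_reference_db(n_species = 10, species_per_genus = 2,
                              fragment_length = 400, divergence = 0.05,
                              identical_fraction = 0, seed = 11)
  genus <- db$taxonomy$parent_id[match(db$refs$taxon_id,
                                       db$taxonomy$taxon_id)]
  dists <- vapply(split(db$refs$sequence, genus),
                  function(s) hamming(s[1], s[2]), numeric(1))
  # each pair ~ 2 x Binomial(400, 0.025) minus rare collisions: mean ~20
  expect_gt(mean(dists), 13)
  expect_lt(mean(dists), 27)
})

test_that("amplicon simulation records provenance and applies the error model", {
  db <- generate_reference_db(n_species = 6, fragment_length = 400,
                              identical_fraction = 0, seed = 2)
  design <- sample_design()[1:4, ]

  sim0 <- simulate_amplicons(db$refs, design, reads_per_sample = 50,
                             error_rate = 0, seed = 3)
  expect_identical(sim0,
                   simulate_amplicons(db$refs, design, reads_per_sample = 50,
                                      error_rate = 0, seed = 3))
  expect_equal(nrow(sim0$reads), 50 * nrow(design))
  expect_setequal(sim0$truth$read_id, sim0$reads$read_id)
  src <- setNames(db$refs$sequence, db$refs$accession)
  expect_identical(sim0$reads$sequence,
                   unname(src[sim0$truth$accession]))

  one <- tibble::tibble(treatment = unique(design$treatment),
                        accession = db$refs$accession[1], weight = 1)
  simw <- simulate_amplicons(db$refs, design[1, ], reads_per_sample = 200,
                             abundance = one, error_rate = 0, seed = 4)
  expect_true(all(simw$truth$accession == db$refs$accession[1]))

  sim <- simulate_amplicons(db$refs, design[1:2, ], reads_per_sample = 500,
                            error_rate = 0.01, seed = 5)
  mm <- mapply(hamming, sim$reads$sequence,
               unname(src[sim$truth$accession]))
  expect_gt(mean(mm), 3.6)   # expectation 4 = 400 * 0.01
  expect_lt(mean(mm), 4.4)

  expect_error(simulate_amplicons(db$refs[0, ], design, 10), "nonempty")
})

test_that("hit tables score identity, ties and boundaries as documented", {
  db <- generate_reference_db(n_species = 6, fragment_length = 400,
                              identical_fraction = 0, seed = 2)
  design <- sample_design()[1, ]
  sim <- simulate_amplicons(db$refs, design, reads_per_sample = 30,
                            error_rate = 0, seed = 9)
  hits <- simulate_hit_table(sim$reads, db$refs)
  expect_true(all(hits$qcovs == 100))

  # zero-error reads: the source accession has identity 100 and max bitscore
  src_hits <- dplyr::inner_join(
    hits, sim$truth, by = c(qseqid = "read_id", sseqid = "accession"))
  expect_equal(nrow(src_hits), nrow(sim$reads))
  expect_true(all(src_hits$pident == 100))
  best <- dplyr::summarise(dplyr::group_by(hits, .data$qseqid),
                           mx = max(bitscore))
  expect_equal(setNames(src_hits$bitscore, src_hits$qseqid)[best$qseqid],
               setNames(best$mx, best$qseqid))

  # forced tie: two identical congeneric fragments share every score
  db_id <- generate_reference_db(n_species = 2, species_per_genus = 2,
                                 fragment_length = 400,
                                 identical_fraction = 1, seed = 6)
  expect_identical(db_id$refs$sequence[1], db_id$refs$sequence[2])
  sim_id <- simulate_amplicons(db_id$refs, design, reads_per_sample = 5,
                               error_rate = 0, seed = 7)
  h <- simulate_hit_table(sim_id$reads, db_id$refs)
  per <- split(h, h$qseqid)
  for (d in per) {
    expect_equal(nrow(d), 2)
    expect_equal(d$bitscore[1], d$bitscore[2])
    expect_equal(d$pident[1], d$pident[2])
  }

  # hand value: 2 substitutions on 400 bp -> identity 99.5 for the source
  reads2 <- sim$reads[1, ]
  s <- strsplit(reads2$sequence, "")[[1]]
  s[c(10, 20)] <- ifelse(s[c(10, 20)] == "A", "C", "A")
  reads2$sequence <- paste(s, collapse = "")
  h2 <- simulate_hit_table(reads2, db$refs)
  src_acc <- sim$truth$accession[sim$truth$read_id == reads2$read_id]
  expect_equal(h2$pident[h2$sseqid == src_acc], 99.5)
})

test_that("count simulation has the promised NB moments and errors", {
  design <- sample_design()
  # Poisson null: per-group sample means within 4 sigma of 1000
  cs <- simulate_count_experiment(5, design, dispersion = 0,
                                  baseline = 1000, seed = 21)
  m <- ambin:::as_count_matrix(cs$counts)
  for (tr in unique(design$treatment)) {
    gm <- rowMeans(m[, design$sample_id[design$treatment == tr]])
    expect_true(all(abs(gm - 1000) < 4 * sqrt(1000 / 4)))
  }

  # lfc = 2 for three_metal: mean ratio over replicate simulations ~ 4
  lfc <- tibble::tibble(otu_id = "OTU0001", treatment = "three_metal",
                        lfc = 2)
  ratios <- vapply(1:200, function(k) {
    cs <- simulate_count_experiment(1, design, lfc = lfc, dispersion = 0.1,
                                    baseline = 500, seed = 1000 + k)
    m <- ambin:::as_count_matrix(cs$counts)
    mean(m[, design$treatment == "three_metal"]) /
      mean(m[, design$treatment == "control"])
  }, numeric(1))
  expect_gt(mean(ratios), 3.5)
  expect_lt(mean(ratios), 4.6)

  # variance ~ mu + alpha mu^2 across many replicates
  big <- sample_design(treatments = "control", n_blocks = 500)
  cs2 <- simulate_count_experiment(3, big, dispersion = 0.2,
                                   baseline = 500, seed = 22)
  v <- apply(ambin:::as_count_matrix(cs2$counts), 1, var)
  expect_true(all(v > 0.6 * (500 + 0.2 * 500^2)))
  expect_true(all(v < 1.5 * (500 + 0.2 * 500^2)))

  expect_error(simulate_count_experiment(2, design, baseline = 0),
               "positive")
  expect_error(simulate_count_experiment(2, design, dispersion = -1),
               "nonnegative")
})

test_that("writers produce the documented plain-text formats", {
  db <- generate_reference_db(n_species = 4, seed = 2)
  design <- sample_design()[1:2, ]
  sim <- simulate_amplicons(db$refs, design, reads_per_sample = 5,
                            error_rate = 0, seed = 3)
  dir <- withr::local_tempdir()
  fasta <- write_sample_fasta(sim$reads, dir)
  expect_length(fasta, 2)
  lines <- readLines(fasta[1])
  expect_equal(sum(startsWith(lines, ">")), 5)

  hits <- simulate_hit_table(sim$reads, db$refs)
  hp <- file.path(dir, "hits.tsv")
  write_hit_table(hits, hp)
  expect_equal(length(strsplit(readLines(hp, n = 1), "\t")[[1]]), 13)

  tp <- file.path(dir, "tax.tsv")
  write_taxonomy_table(db$refs, db$taxonomy, tp)
  tax <- readr::read_tsv(tp, show_col_types = FALSE)
  expect_equal(names(tax),
               c("accession", ambin:::TAX_RANKS, "label"))
  expect_equal(nrow(tax), 4)
})
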