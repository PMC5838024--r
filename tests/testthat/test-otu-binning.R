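test_that("rarefaction subsamples exactly and reproducibly", {
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", 1:70),
    sample_id = rep(c("A", "B"), c(30, 40)))
  r1 <- rarefy_samples(reads, depth = 30, seed = 5)
  expect_equal(as.vector(table(r1$sample_id)[c("A", "B")]), c(30L, 30L))
  expect_identical(r1, rarefy_samples(reads, depth = 30, seed = 5))
  expect_false(identical(r1$read_id,
                         rarefy_samples(reads, depth = 30, seed = 6)$read_id))
  expect_error(rarefy_samples(reads, depth = 31), "`A`")
})

test_that("round-1 binning groups reads by annotation identity", {
  tax <- tiny_taxonomy()
  reads <- tibble::tibble(read_id = sprintf("r%d", 1:6),
                          sample_id = rep(c("A", "B"), 3))
  ann <- tibble::tibble(
    query_id = sprintf("r%d", 1:5),
    taxon_id = c("s1", "s1", "s1", "g1", "g1"),
    rank = c("species", "species", "species", "genus", "genus"),
    label = c(rep("GenusOne alpha", 3), rep("GenusOne alpha", 2)),
    accessions = c(rep(list("ACC1"), 3), rep(list(c("ACC1", "ACC2")), 2)),
    best_bitscore = 500)
  b <- bin_round1(ann, reads)
  expect_equal(nrow(b$otus), 2)
  expect_equal(sort(as.vector(table(b$assignments$otu_id))), c(2L, 3L))
  expect_equal(b$unassigned$read_id, "r6")

  empty <- bin_round1(ann[0, ], reads)
  expect_equal(nrow(empty$otus), 0)
  expect_equal(nrow(empty$unassigned), 6)

  expect_error(bin_round1(ann[c(1, 1), ], reads), "more than once")
})

test_that("error-free synthetic reads bin exactly to their provenance", {
  db <- generate_reference_db(n_species = 4, species_per_genus = 1,
                              divergence = 0.05, identical_fraction = 0,
                              seed = 14)
  design <- sample_design()[1:2, ]
  sim <- simulate_amplicons(db$refs, design, reads_per_sample = 50,
                            error_rate = 0, seed = 15)
  raw <- simulate_hit_table(sim$reads, db$refs)
  hits <- tibble::tibble(query_id = raw$qseqid, accession = raw$sseqid,
                         identity = raw$pident, coverage = raw$qcovs,
                         evalue = raw$evalue, bitscore = raw$bitscore)
  ann <- annotate_queries(hits, db$refs, db$taxonomy)
  b <- bin_round1(ann, sim$reads)
  expect_equal(nrow(b$unassigned), 0)
  expect_equal(nrow(b$otus), 4)

  got <- dplyr::count(b$assignments, .data$otu_id)
  species_of_otu <- b$otus$taxon_id[match(got$otu_id, b$otus$otu_id)]
  acc_of_species <- setNames(db$refs$accession, db$refs$taxon_id)
  want <- dplyr::count(sim$truth, .data$accession)
  expect_equal(setNames(got$n, acc_of_species[species_of_otu])[want$accession],
               setNames(want$n, want$accession))
})

test_that("round-2 rescues into established OTUs only, by best bit score", {
  tax <- tiny_taxonomy()
  refs <- tiny_refs()
  reads <- tibble::tibble(read_id = c("r1", "r2", "u1", "u2", "u3"),
                          sample_id = "A")
  ann <- tibble::tibble(
    query_id = c("r1", "r2"),
    taxon_id = c("s1", "s3"), rank = "species",
    label = c("GenusOne alpha", "GenusTwo gamma"),
    accessions = list("ACC1", "ACC3"), best_bitscore = 500)
  b <- bin_round1(ann, reads)
  otu_s1 <- b$otus$otu_id[b$otus$taxon_id == "s1"]
  otu_s3 <- b$otus$otu_id[b$otus$taxon_id == "s3"]

  hits <- dplyr::bind_rows(
    make_hit("u1", "ACC1", identity = 98.5, coverage = 99, bitscore = 700),
    make_hit("u2", "ACC2", identity = 98.5, coverage = 99, bitscore = 700),
    make_hit("u3", "ACC1", identity = 98.2, coverage = 98, bitscore = 650),
    make_hit("u3", "ACC3", identity = 98.9, coverage = 99, bitscore = 680))
  b2 <- bin_round2(b, hits)

  # u1: qualifying hit into the OTU registering ACC1
  got_u1 <- b2$assignments$otu_id[b2$assignments$read_id == "u1"]
  expect_equal(got_u1, otu_s1)
  # u2: its only hit accession is registered nowhere -> stays unassigned
  expect_true("u2" %in% b2$unassigned$read_id)
  # u3: qualifying hits into two OTUs; exhaustive max says ACC3's OTU
  qual <- hits[hits$query_id == "u3" & hits$identity >= 98 &
                 hits$coverage >= 98, ]
  best_acc <- qual$accession[which.max(qual$bitscore)]
  expect_equal(b2$assignments$otu_id[b2$assignments$read_id == "u3"],
               if (best_acc == "ACC1") otu_s1 else otu_s3)
  # no new OTU construction
  expect_setequal(unique(b2$assignments$otu_id), b$otus$otu_id)
  expect_identical(b2$otus, b$otus)
})

test_that("binning rounds partition the rarefied reads", {
  db <- generate_reference_db(n_species = 8, divergence = 0.05,
                              identical_fraction = 0.25, seed = 41)
  design <- sample_design()[1:4, ]
  sim <- simulate_amplicons(db$refs, design, reads_per_sample = 150,
                            error_rate = 0.008, seed = 42)
  rar <- rarefy_samples(sim$reads, 120, seed = 43)
  raw <- simulate_hit_table(rar, db$refs)
  hits <- tibble::tibble(query_id = raw$qseqid, accession = raw$sseqid,
                         identity = raw$pident, coverage = raw$qcovs,
                         evalue = raw$evalue, bitscore = raw$bitscore)
  ann <- annotate_queries(hits, db$refs, db$taxonomy)
  b1 <- bin_round1(ann, rar)
  b2 <- bin_round2(b1, hits)

  expect_equal(anyDuplicated(b2$assignments$read_id), 0)
  expect_setequal(c(b2$assignments$read_id, b2$unassigned$read_id),
                  rar$read_id)
  expect_gte(nrow(b2$assignments), nrow(b1$assignments))
})

test_that("count matrices conserve assigned reads and zero-fill", {
  reads <- tibble::tibble(read_id = c("r1", "r2"), sample_id = "A")
  ann <- tibble::tibble(query_id = c("r1", "r2"), taxon_id = "s1",
                        rank = "species", label = "X",
                        accessions = list("ACC1", "ACC1"),
                        best_bitscore = 500)
  b <- bin_round1(ann, reads)
  design <- tibble::tibble(sample_id = c("A", "B", "C"),
                           treatment = "control", block = 1:3)
  m <- build_count_matrix(b, design)
  expect_equal(names(m), c("otu_id", "A", "B", "C"))
  expect_equal(unlist(m[1, c("A", "B", "C")], use.names = FALSE),
               c(2, 0, 0))

  b_empty <- bin_round1(ann[0, ], reads)
  b_empty$unassigned <- reads
  m0 <- build_count_matrix(b_empty, design)
  expect_equal(nrow(m0), 0)
  expect_equal(names(m0), c("otu_id", "A", "B", "C"))
})

test_that("sparsity filter applies the replicate and concentration rules", {
  m <- matrix(c(10, 10, 10, 10, 0,    # retained: 4 replicates, conc 0.25
                5, 5, 5, 0, 0,        # flagged: 3 replicates
                30, 5, 4, 1, 0,       # flagged: 30/40 = 0.75 boundary
                29, 5, 5, 1, 0,       # retained: 29/40 < 0.75, 4 reps
                0, 0, 0, 0, 0),       # flagged: absent
              nrow = 5, byrow = TRUE,
              dimnames = list(paste0("o", 1:5), paste0("S", 1:5)))
  out <- sparsity_filter(m)
  expect_setequal(out$retained$otu_id, c("o1", "o4"))
  expect_equal(out$flags$reason[match(c("o2", "o3", "o5"),
                                      out$flags$otu_id)],
               c("replicates", "concentration", "absent"))

  # idempotent
  again <- sparsity_filter(out$retained)
  expect_equal(again$retained, out$retained)
  expect_equal(nrow(again$flags), 0)
})

test_that("abundance retention applies the strict normalized-total rule", {
  m <- matrix(c(3, 3, 3, 2,      # total 11 -> retained at sf = 1
                3, 3, 2, 2,      # total 10 -> removed (strict > 10)
                10, 10, 10, 10), # total 40
              nrow = 3, byrow = TRUE,
              dimnames = list(paste0("o", 1:3), paste0("S", 1:4)))
  sf1 <- setNames(rep(1, 4), paste0("S", 1:4))
  expect_setequal(abundance_retention(m, sf1)$otu_id, c("o1", "o3"))
  # total 40 with all size factors 4 -> normalized 10 -> removed
  sf4 <- setNames(rep(4, 4), paste0("S", 1:4))
  expect_equal(nrow(abundance_retention(m[3, , drop = FALSE], sf4)), 0)
  expect_equal(nrow(abundance_retention(m[0, , drop = FALSE], sf1)), 0)
  expect_error(abundance_retention(m, sf1 * 0), "positive")
})

test_that("binning bookkeeping reports rates at reporting precision", {
  r <- binning_rates(4, 1, 10)
  expect_equal(r$n_binned, 5)
  expect_equal(r$pct_round1, 40)
  expect_equal(r$pct_binned, 50)
})
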