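#' Treatment-by-block sample design
#'
#' Builds the default field design used throughout the package: five
#' treatments (untreated control and soil spiked with lead, zinc, copper, or
#' all three metals) laid out in four replicate blocks, i.e. 20 samples with
#' n = 4 biological replicates per treatment.
#'
#' @param treatments Character vector of treatment names.
#' @param n_blocks Number of replicate blocks per treatment.
#' @return A tibble with columns `sample_id`, `treatment`, `block`.
#' @examples
#' sample_design()
#' @export
sample_design <- function(treatments = c("control", "Pb", "Zn", "Cu", "three_metal"),
                          n_blocks = 4) {
  assert_that(length(treatments) >= 1 && n_blocks >= 1,
              "need at least one treatment and one block")
  assert_that(!anyDuplicated(treatments), "treatments must be unique")
  tidyr::expand_grid(treatment = treatments, block = seq_len(n_blocks)) |>
    dplyr::mutate(sample_id = sprintf("%s_b%d", .data$treatment, .data$block),
                  .before = 1)
}

rank_children <- c(superkingdom = 1L, phylum = 2L, class = 2L, order = 2L,
                   family = 2L)

#' Generate a ranked reference taxonomy and 16S fragment database
#'
#' Creates a seven-rank taxonomy (superkingdom down to species) and one
#' reference sequence record per species, emulating the nucleotide database an
#' amplicon would be searched against. Species within a genus descend from a
#' shared ancestral fragment and differ, on average, at
#' `divergence * fragment_length` positions. A configurable fraction of
#' genera carry species with byte-identical fragments, so that best-hit
#' annotation is forced into bit-score ties that must be resolved by the
#' lowest common taxon. A fraction of records receive "uncharacterized" or
#' "uncultured" display labels to exercise label cleaning.
#'
#' @param n_species Number of species (>= 2).
#' @param species_per_genus Species per genus.
#' @param fragment_length Length of the amplified fragment in bp (>= 50).
#' @param divergence Expected within-genus pairwise difference per site.
#' @param identical_fraction Fraction of genera whose species share one
#'   identical fragment.
#' @param label_noise Fraction of species given a decorated
#'   ("uncharacterized ..."/"uncultured ...") display label.
#' @param seed Integer seed; output is byte-identical for equal inputs.
#' @return A list with elements `taxonomy` (tibble: `taxon_id`, `name`,
#'   `rank`, `parent_id`) and `refs` (tibble: `accession`, `taxon_id`,
#'   `label`, `sequence`).
#' @examples
#' db <- generate_reference_db(n_species = 6, seed = 1)
#' db$refs
#' @export
generate_reference_db <- function(n_species,
                                  species_per_genus = 2,
                                  fragment_length = 400,
                                  divergence = 0.02,
                                  identical_fraction = 0.1,
                                  label_noise = 0.15,
                                  seed = 1L) {
  assert_that(n_species >= 2, "n_species must be >= 2")
  assert_that(species_per_genus >= 1, "species_per_genus must be positive")
  assert_that(fragment_length >= 50, "fragment_length must be >= 50")
  assert_that(divergence >= 0 && divergence <= 1,
              "divergence must be in [0, 1]")
  withr::local_seed(seed)

  n_genus  <- ceiling(n_species / species_per_genus)
  n_family <- ceiling(n_genus / 2)
  n_order  <- ceiling(n_family / 2)
  n_class  <- ceiling(n_order / 2)
  n_phylum <- ceiling(n_class / 2)

  # ids are strings; parent index maps each level to the one above
  lvl <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  ids <- list(superkingdom = "k01", phylum = lvl("p", n_phylum),
              class = lvl("c", n_class), order = lvl("o", n_order),
              family = lvl("f", n_family), genus = lvl("g", n_genus),
              species = sprintf("s%03d", seq_len(n_species)))
  parent_of <- function(child_n, parent_ids) {
    parent_ids[((seq_len(child_n) - 1) %% length(parent_ids)) + 1]
  }
  nodes <- list(
    tibble::tibble(taxon_id = ids$superkingdom, name = "Bacteria",
                   rank = "superkingdom", parent_id = NA_character_)
  )
  parent_ids <- ids$superkingdom
  for (rk in TAX_RANKS[-1]) {
    this <- ids[[rk]]
    nodes[[rk]] <- tibble::tibble(
      taxon_id = this,
      name = paste0(toupper(substr(rk, 1, 1)), sub("^.", "", this)),
      rank = rk,
      parent_id = sort(parent_of(length(this), parent_ids))
    )
    parent_ids <- this
  }
  taxonomy <- dplyr::bind_rows(nodes)

  # nicer binomials for display labels
  genus_name <- setNames(paste0("Genus", sub("^g", "", ids$genus)), ids$genus)
  sp_parent <- taxonomy$parent_id[match(ids$species, taxonomy$taxon_id)]
  sp_name <- paste0(genus_name[sp_parent], " sp",
                    sub("^s0*", "", ids$species))
  taxonomy$name[match(ids$species, taxonomy$taxon_id)] <- sp_name

  bases <- c("A", "C", "G", "T")
  identical_genera <- character(0)
  n_ident <- floor(identical_fraction * n_genus)
  if (n_ident > 0)
    identical_genera <- sample(ids$genus, n_ident)

  ancestor <- lapply(ids$genus, function(g)
    sample(bases, fragment_length, replace = TRUE))
  names(ancestor) <- ids$genus

  seqs <- character(n_species)
  for (i in seq_len(n_species)) {
    g <- sp_parent[i]
    s <- ancestor[[g]]
    if (!(g %in% identical_genera) && divergence > 0) {
      n_mut <- rbinom(1, fragment_length, divergence / 2)
      if (n_mut > 0) {
        pos <- sample.int(fragment_length, n_mut)
        s[pos] <- vapply(s[pos], function(b)
          sample(setdiff(bases, b), 1), character(1))
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }

  labels <- sp_name
  n_noise <- floor(label_noise * n_species)
  if (n_noise > 0) {
    idx <- sample.int(n_species, n_noise)
    fam <- taxonomy$parent_id[match(sp_parent[idx], taxonomy$taxon_id)]
    fam_name <- taxonomy$name[match(fam, taxonomy$taxon_id)]
    deco <- ifelse(seq_along(idx) %% 2 == 0,
                   paste("uncharacterized", fam_name),
                   paste("uncultured", genus_name[sp_parent[idx]], "bacterium"))
    labels[idx] <- deco
  }

  refs <- tibble::tibble(
    accession = sprintf("SYN%05d", seq_len(n_species)),
    taxon_id = ids$species,
    label = unname(labels),
    sequence = seqs
  )
  list(taxonomy = taxonomy, refs = refs)
}

seq_to_mat <- function(seqs) {
  # L x n character matrix
  vapply(strsplit(seqs, "", fixed = TRUE), identity,
         character(nchar(seqs[1])))
}

#' Simulate amplicon reads with substitution errors
#'
#' Each read is a copy of its source species' reference fragment with i.i.d.
#' substitutions at `error_rate` per site (no indels: annotation binning
#' depends only on identity/coverage, so indel realism buys nothing here).
#' Source species are drawn per sample according to the abundance profile of
#' that sample's treatment, and every read's provenance is recorded.
#'
#' @param refs Reference tibble from [generate_reference_db()].
#' @param design Sample design tibble from [sample_design()].
#' @param reads_per_sample Reads to draw per sample.
#' @param abundance Optional tibble (`treatment`, `accession`, `weight`) of
#'   nonnegative species weights per treatment; defaults to uniform weights.
#' @param error_rate Per-site substitution probability.
#' @param seed Integer seed.
#' @return A list with `reads` (tibble: `read_id`, `sample_id`, `sequence`)
#'   and `truth` (tibble: `read_id`, `accession`) recording provenance.
#' @export
simulate_amplicons <- function(refs, design, reads_per_sample = 1000,
                               abundance = NULL, error_rate = 0.005,
                               seed = 1L) {
  assert_that(nrow(refs) > 0, "reference set must be nonempty")
  assert_that(reads_per_sample >= 1, "reads_per_sample must be positive")
  assert_that(error_rate >= 0 && error_rate < 1,
              "error_rate must be in [0, 1)")
  withr::local_seed(seed)

  L <- nchar(refs$sequence[1])
  assert_that(all(nchar(refs$sequence) == L),
              "reference fragments must share one length")
  ref_mat <- seq_to_mat(refs$sequence)
  bases <- c("A", "C", "G", "T")

  weight_for <- function(treatment) {
    if (is.null(abundance)) return(rep(1, nrow(refs)))
    w <- abundance |>
      dplyr::filter(.data$treatment == .env$treatment)
    out <- setNames(rep(0, nrow(refs)), refs$accession)
    out[w$accession] <- w$weight
    assert_that(all(out >= 0) && any(out > 0),
                paste0("abundance weights for ", treatment,
                       " must be nonnegative with at least one positive"))
    out
  }

  all_reads <- vector("list", nrow(design))
  all_truth <- vector("list", nrow(design))
  for (k in seq_len(nrow(design))) {
    sid <- design$sample_id[k]
    w <- weight_for(design$treatment[k])
    src <- sample.int(nrow(refs), reads_per_sample, replace = TRUE, prob = w)
    reads <- ref_mat[, src, drop = FALSE]
    if (error_rate > 0) {
      err <- matrix(runif(length(reads)) < error_rate, nrow = L)
      n_err <- sum(err)
      if (n_err > 0) {
        cur <- reads[err]
        reads[err] <- vapply(cur, function(b)
          sample(setdiff(bases, b), 1), character(1))
      }
    }
    ids <- sprintf("%s_r%05d", sid, seq_len(reads_per_sample))
    all_reads[[k]] <- tibble::tibble(
      read_id = ids, sample_id = sid,
      sequence = apply(reads, 2, paste, collapse = ""))
    all_truth[[k]] <- tibble::tibble(read_id = ids,
                                     accession = refs$accession[src])
  }
  list(reads = dplyr::bind_rows(all_reads),
       truth = dplyr::bind_rows(all_truth))
}

#' Simulate a BLAST-style tabular hit report
#'
#' For each read, emits hits to its nearest references by full-length Hamming
#' identity (the simulator models complete-coverage alignments, so query
#' coverage is always 100). Identity is `100 * matches / length`. The bit
#' score is `2 * (matches - 3 * mismatches)` and the e-value
#' `10^(-bitscore / 10)`: both strictly monotone in the mismatch count, so
#' reads tied in mismatches receive identical scores. References tied with
#' the `max_targets`-th nearest are all reported, preserving tie structure.
#'
#' The simulator is fully deterministic given its inputs.
#'
#' @param reads Read tibble from [simulate_amplicons()].
#' @param refs Reference tibble.
#' @param max_targets Number of nearest references reported per read (ties
#'   included).
#' @return A tibble in 13-column BLAST tabular layout (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`, `qcovs`).
#' @export
simulate_hit_table <- function(reads, refs, max_targets = 5) {
  assert_that(nrow(reads) > 0 && nrow(refs) > 0,
              "reads and refs must be nonempty")
  L <- nchar(refs$sequence[1])
  ref_mat <- seq_to_mat(refs$sequence)
  read_mat <- seq_to_mat(reads$sequence)
  assert_that(nrow(read_mat) == L, "reads and references differ in length")

  n_reads <- nrow(reads)
  mm <- matrix(0L, n_reads, nrow(refs))
  for (j in seq_len(nrow(refs)))
    mm[, j] <- colSums(read_mat != ref_mat[, j])

  keep <- lapply(seq_len(n_reads), function(i) {
    thr <- sort(mm[i, ], partial = min(max_targets, ncol(mm)))[
      min(max_targets, ncol(mm))]
    which(mm[i, ] <= thr)
  })
  n_hit <- lengths(keep)
  qi <- rep(seq_len(n_reads), n_hit)
  si <- unlist(keep, use.names = FALSE)
  mismatch <- mm[cbind(qi, si)]
  matches <- L - mismatch
  bitscore <- 2 * (matches - 3 * mismatch)
  tibble::tibble(
    qseqid = reads$read_id[qi],
    sseqid = refs$accession[si],
    pident = round(100 * matches / L, 3),
    length = L,
    mismatch = mismatch,
    gapopen = 0L,
    qstart = 1L, qend = L, sstart = 1L, send = L,
    evalue = 10^(-bitscore / 10),
    bitscore = bitscore,
    qcovs = 100
  ) |>
    dplyr::arrange(.data$qseqid, dplyr::desc(.data$bitscore), .data$sseqid)
}

#' Simulate a negative-binomial OTU count experiment
#'
#' Draws counts independently per cell from a negative-binomial distribution
#' with mean `mu_i * 2^lfc(i, treatment)` and dispersion `alpha_i` (variance
#' `mu + alpha * mu^2`); `alpha_i = 0` degenerates to Poisson. Group effects
#' enter as log2 fold changes relative to the baseline mean, so ground truth
#' for the differential-abundance stage is exact.
#'
#' @param n_otus Number of OTUs.
#' @param design Sample design tibble.
#' @param lfc Optional tibble (`otu_id`, `treatment`, `lfc`) of log2 effects;
#'   unlisted combinations have effect 0.
#' @param dispersion Per-OTU dispersion `alpha_i >= 0` (recycled if scalar).
#' @param baseline Per-OTU baseline mean `mu_i > 0` (recycled if scalar).
#' @param seed Integer seed.
#' @return A list with `counts` (wide tibble `otu_id` x samples) and `truth`
#'   (list with `lfc`, `dispersion`, `baseline`).
#' @export
simulate_count_experiment <- function(n_otus, design, lfc = NULL,
                                      dispersion = 0.1, baseline = 500,
                                      seed = 1L) {
  assert_that(n_otus >= 1, "n_otus must be positive")
  dispersion <- rep_len(dispersion, n_otus)
  baseline <- rep_len(baseline, n_otus)
  assert_that(all(dispersion >= 0), "dispersion must be nonnegative")
  assert_that(all(baseline > 0), "baseline means must be positive")
  withr::local_seed(seed)

  otu_ids <- sprintf("OTU%04d", seq_len(n_otus))
  lfc_mat <- matrix(0, n_otus, nrow(design),
                    dimnames = list(otu_ids, design$sample_id))
  if (!is.null(lfc)) {
    assert_that(all(lfc$otu_id %in% otu_ids) &&
                  all(lfc$treatment %in% design$treatment),
                "lfc refers to unknown OTUs or treatments")
    for (r in seq_len(nrow(lfc))) {
      cols <- design$sample_id[design$treatment == lfc$treatment[r]]
      lfc_mat[lfc$otu_id[r], cols] <- lfc$lfc[r]
    }
  }
  mu <- baseline * 2^lfc_mat
  counts <- matrix(0, n_otus, nrow(design),
                   dimnames = dimnames(lfc_mat))
  for (i in seq_len(n_otus)) {
    counts[i, ] <- if (dispersion[i] == 0) {
      rpois(ncol(counts), mu[i, ])
    } else {
      rnbinom(ncol(counts), mu = mu[i, ], size = 1 / dispersion[i])
    }
  }
  list(counts = as_count_tibble(counts),
       truth = list(lfc = lfc %||%
                      tibble::tibble(otu_id = character(),
                                     treatment = character(),
                                     lfc = double()),
                    dispersion = setNames(dispersion, otu_ids),
                    baseline = setNames(baseline, otu_ids)))
}

#' Write per-sample FASTA files
#'
#' @param reads Read tibble (`read_id`, `sample_id`, `sequence`).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (one FASTA per sample).
#' @export
write_sample_fasta <- function(reads, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(split(reads, reads$sample_id), function(d) {
    path <- file.path(dir, paste0(d$sample_id[1], ".fasta"))
    writeLines(paste0(">", d$read_id, "\n", d$sequence), path)
    path
  }, character(1))
  invisible(paths)
}

#' Write a hit table in headerless BLAST tabular form
#' @param hits Hit tibble from [simulate_hit_table()].
#' @param path Output TSV path.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits, path, col_names = FALSE)
  invisible(path)
}

#' Write the reference taxonomy as an accession-lineage TSV
#'
#' One row per accession with the full ranked lineage (names) and display
#' label, mirroring the lookup a real annotation run would perform.
#' @param refs Reference tibble.
#' @param taxonomy Taxonomy tibble.
#' @param path Output TSV path.
#' @export
write_taxonomy_table <- function(refs, taxonomy, path) {
  lin <- taxonomy_lineage(taxonomy)
  name_of <- setNames(taxonomy$name, taxonomy$taxon_id)
  wide <- lin |>
    dplyr::mutate(dplyr::across(dplyr::all_of(TAX_RANKS),
                                ~ unname(name_of[.x])))
  out <- refs |>
    dplyr::left_join(wide, by = c(taxon_id = "species_id")) |>
    dplyr::select("accession", dplyr::all_of(TAX_RANKS), "label")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write the sample metadata TSV
#' @param design Sample design tibble.
#' @param path Output TSV path.
#' @export
write_metadata <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}
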