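#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads to exactly `depth` reads, uniformly without
#' replacement, to equalise sequencing effort before binning.
#'
#' @param reads Read tibble with `read_id` and `sample_id` columns.
#' @param depth Target depth (every sample must have at least `depth` reads).
#' @param seed Integer seed; the subsample is reproducible.
#' @return The rarefied read tibble (same columns, `depth` rows per sample).
#' @export
rarefy_samples <- function(reads, depth, seed = 1L) {
  assert_that(depth >= 1, "depth must be positive")
  sizes <- table(reads$sample_id)
  shallow <- names(sizes)[sizes < depth]
  if (length(shallow) > 0)
    rlang::abort(sprintf("sample `%s` has %d reads, fewer than depth %d",
                         shallow[1], sizes[[shallow[1]]], depth))
  withr::local_seed(seed)
  reads |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::slice_sample(n = depth) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, .data$read_id)
}

#' Sparsity-filter thresholds
#'
#' @param min_replicates An OTU must appear (count > 0) in at least this many
#'   samples.
#' @param max_concentration An OTU is flagged when its maximum single-sample
#'   count is at least this fraction of its total (retention requires
#'   `max/total < max_concentration`).
#' @param min_total_normalized Strict lower bound on the total of normalized
#'   counts for [abundance_retention()].
#' @return A list of class `sparsity_config`.
#' @export
sparsity_config <- function(min_replicates = 4, max_concentration = 0.75,
                            min_total_normalized = 10) {
  assert_that(max_concentration > 0 && max_concentration <= 1,
              "max_concentration must be in (0, 1]")
  structure(list(min_replicates = min_replicates,
                 max_concentration = max_concentration,
                 min_total_normalized = min_total_normalized),
            class = "sparsity_config")
}

otu_id_of <- function(label, taxon_id) {
  paste0(gsub("[^A-Za-z0-9._-]+", "_", label), "|", taxon_id)
}

#' Round-1 OTU construction from annotations
#'
#' Each distinct `(taxon_id, label)` annotation founds one OTU; every
#' annotated read is assigned to exactly one OTU. Reads without an annotation
#' are untouched (candidates for round-2 rescue).
#'
#' @param annotations Annotation tibble from [annotate_queries()].
#' @param reads Read tibble (`read_id`, `sample_id`) covering all annotated
#'   reads.
#' @return A list of class `otu_binning`: `assignments` (tibble `read_id`,
#'   `sample_id`, `otu_id`, `accessions` list-column, `round`), `otus`
#'   (tibble `otu_id`, `taxon_id`, `rank`, `label`), and `unassigned`
#'   (read tibble).
#' @export
bin_round1 <- function(annotations, reads) {
  if (anyDuplicated(annotations$query_id))
    rlang::abort("a read was annotated more than once")
  if (nrow(annotations) == 0) {
    return(structure(list(
      assignments = tibble::tibble(read_id = character(),
                                   sample_id = character(),
                                   otu_id = character(),
                                   accessions = list(), round = integer()),
      otus = tibble::tibble(otu_id = character(), taxon_id = character(),
                            rank = character(), label = character()),
      unassigned = reads), class = "otu_binning"))
  }
  ann <- annotations |>
    dplyr::mutate(otu_id = otu_id_of(.data$label, .data$taxon_id))
  otus <- ann |>
    dplyr::distinct(.data$otu_id, .data$taxon_id, .data$rank, .data$label) |>
    dplyr::arrange(.data$otu_id)
  sample_of <- setNames(reads$sample_id, reads$read_id)
  assert_that(all(ann$query_id %in% reads$read_id),
              "annotations refer to reads absent from `reads`")
  assignments <- tibble::tibble(
    read_id = ann$query_id,
    sample_id = unname(sample_of[ann$query_id]),
    otu_id = ann$otu_id,
    accessions = ann$accessions,
    round = 1L) |>
    dplyr::arrange(.data$read_id)
  structure(list(assignments = assignments, otus = otus,
                 unassigned = reads[!(reads$read_id %in% ann$query_id), ]),
            class = "otu_binning")
}

#' Round-2 rescue of unannotated reads into established OTUs
#'
#' Unassigned reads are reconsidered at the relaxed round-2 thresholds, but
#' only hits whose accession is already registered in some round-1 OTU (i.e.
#' supported one of its member reads) qualify. Each read joins the OTU of its
#' highest-bit-score qualifying hit; no new OTU may be created. Ties at equal
#' (rounded) bit score across OTUs go to the OTU with the larger round-1
#' total, then to the lexicographically smallest `otu_id`. All decisions use
#' the round-1 registry and totals, so the result is independent of read
#' order.
#'
#' @param binning An `otu_binning` from [bin_round1()].
#' @param hits Full hit tibble (pre-filtering) covering the unassigned reads.
#' @param config A [filter_config()].
#' @return The updated `otu_binning`; rescued reads carry `round = 2`.
#' @export
bin_round2 <- function(binning, hits, config = filter_config()) {
  unassigned <- binning$unassigned
  if (nrow(unassigned) == 0 || nrow(binning$assignments) == 0)
    return(binning)

  registry <- binning$assignments |>
    dplyr::select("otu_id", "accessions") |>
    tidyr::unnest("accessions") |>
    dplyr::distinct(.data$otu_id, accession = .data$accessions)
  totals <- binning$assignments |>
    dplyr::count(.data$otu_id, name = "otu_total")

  qualifying <- hits |>
    dplyr::filter(.data$query_id %in% unassigned$read_id) |>
    filter_hits(config$round2_identity, config$round2_coverage,
                config$evalue_max) |>
    dplyr::inner_join(registry, by = "accession",
                      relationship = "many-to-many") |>
    dplyr::left_join(totals, by = "otu_id") |>
    dplyr::mutate(bs = round(.data$bitscore, 1))
  if (nrow(qualifying) == 0) return(binning)

  chosen <- qualifying |>
    dplyr::group_by(.data$query_id) |>
    dplyr::filter(.data$bs == max(.data$bs)) |>
    dplyr::arrange(dplyr::desc(.data$otu_total), .data$otu_id,
                   .by_group = TRUE) |>
    dplyr::summarise(otu_id = .data$otu_id[1],
                     accessions = list(sort(unique(
                       .data$accession[.data$otu_id == .data$otu_id[1]]))),
                     .groups = "drop")

  sample_of <- setNames(unassigned$sample_id, unassigned$read_id)
  rescued <- tibble::tibble(
    read_id = chosen$query_id,
    sample_id = unname(sample_of[chosen$query_id]),
    otu_id = chosen$otu_id,
    accessions = chosen$accessions,
    round = 2L)
  binning$assignments <- dplyr::bind_rows(binning$assignments, rescued) |>
    dplyr::arrange(.data$read_id)
  binning$unassigned <-
    unassigned[!(unassigned$read_id %in% rescued$read_id), ]
  binning
}

#' Build the OTU-by-sample count matrix
#'
#' @param binning An `otu_binning`.
#' @param design Sample design tibble; all its samples appear as columns,
#'   zero-filled where an OTU is absent.
#' @return A wide count tibble (`otu_id` plus one column per sample), rows
#'   and columns sorted.
#' @export
build_count_matrix <- function(binning, design) {
  assert_that(!anyDuplicated(binning$otus$otu_id), "duplicate otu_id")
  samples <- sort(design$sample_id)
  m <- matrix(0, nrow(binning$otus), length(samples),
              dimnames = list(sort(binning$otus$otu_id), samples))
  if (nrow(binning$assignments) > 0) {
    tab <- binning$assignments |>
      dplyr::count(.data$otu_id, .data$sample_id)
    assert_that(all(tab$sample_id %in% samples),
                "assignments refer to samples absent from the design")
    m[cbind(tab$otu_id, tab$sample_id)] <- tab$n
  }
  as_count_tibble(m)
}

#' Flag and remove sparse or single-sample-concentrated OTUs
#'
#' An OTU is flagged (and removed from the retained table) when it is present
#' in fewer than `min_replicates` samples, or when its largest single-sample
#' count makes up at least `max_concentration` of its total (a high total
#' concentrated in one sample). All-zero rows are flagged as absent.
#'
#' @param counts Wide count tibble or matrix.
#' @param config A [sparsity_config()].
#' @return A list: `retained` (count tibble) and `flags` (tibble `otu_id`,
#'   `reason` in `absent`, `replicates`, `concentration`).
#' @export
sparsity_filter <- function(counts, config = sparsity_config()) {
  m <- as_count_matrix(counts)
  n_present <- rowSums(m > 0)
  total <- rowSums(m)
  conc <- ifelse(total > 0, apply(m, 1, max) / total, 1)
  reason <- dplyr::case_when(
    total == 0 ~ "absent",
    n_present < config$min_replicates ~ "replicates",
    conc >= config$max_concentration ~ "concentration",
    .default = NA_character_)
  flags <- tibble::tibble(otu_id = rownames(m), reason = reason) |>
    dplyr::filter(!is.na(.data$reason))
  list(retained = as_count_tibble(m[is.na(reason), , drop = FALSE]),
       flags = flags)
}

#' Retain OTUs by total normalized abundance
#'
#' Keeps OTUs whose total of size-factor-normalized counts across samples is
#' strictly greater than `min_total_normalized`, reducing interference of
#' near-empty rows with the median-of-ratios estimator downstream.
#'
#' @param counts Wide count tibble or matrix.
#' @param size_factors Named positive per-sample size factors.
#' @param config A [sparsity_config()].
#' @return The retained count tibble.
#' @export
abundance_retention <- function(counts, size_factors,
                                config = sparsity_config()) {
  m <- as_count_matrix(counts)
  assert_that(all(size_factors > 0), "size factors must be positive")
  sf <- size_factors[colnames(m)]
  assert_that(!anyNA(sf), "size_factors must be named for every sample")
  norm_total <- rowSums(sweep(m, 2, sf, "/"))
  as_count_tibble(m[norm_total > config$min_total_normalized, ,
                    drop = FALSE])
}

#' Round-level binning bookkeeping
#'
#' Summarises how many rarefied reads were captured in strict round-1 OTU
#' construction and how many more were rescued in round 2, with percentages
#' of the rarefied total (rounded to two decimals, as conventionally
#' reported).
#'
#' @param n_round1 Reads binned in round 1.
#' @param n_round2 Additional reads rescued in round 2.
#' @param n_total Total rarefied reads.
#' @return A one-row tibble with counts, cumulative count, and percentages.
#' @export
binning_rates <- function(n_round1, n_round2, n_total) {
  assert_that(n_total > 0, "n_total must be positive")
  tibble::tibble(
    n_round1 = n_round1,
    n_round2 = n_round2,
    n_binned = n_round1 + n_round2,
    n_total = n_total,
    pct_round1 = round(100 * n_round1 / n_total, 2),
    pct_binned = round(100 * (n_round1 + n_round2) / n_total, 2))
}
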