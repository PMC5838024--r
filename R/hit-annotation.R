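BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send",
                "evalue", "bitscore")

#' Filtering thresholds for hit retention and the two binning rounds
#'
#' Defaults follow the analysis convention: hits are kept when the e-value is
#' strictly below `1e-10`; round-1 OTU construction requires >= 99% identity
#' and >= 99% query coverage; round-2 rescue into established OTUs relaxes
#' both to >= 98%. Identity/coverage thresholds are inclusive, the e-value
#' threshold strict.
#'
#' @param evalue_max Strict upper bound on retained e-values.
#' @param round1_identity,round1_coverage Round-1 thresholds (percent).
#' @param round2_identity,round2_coverage Round-2 thresholds (percent).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(evalue_max = 1e-10,
                          round1_identity = 99, round1_coverage = 99,
                          round2_identity = 98, round2_coverage = 98) {
  assert_that(round2_identity <= round1_identity &&
                round2_coverage <= round1_coverage,
              "round-2 thresholds must not exceed round-1 thresholds")
  structure(list(evalue_max = evalue_max,
                 round1_identity = round1_identity,
                 round1_coverage = round1_coverage,
                 round2_identity = round2_identity,
                 round2_coverage = round2_coverage),
            class = "filter_config")
}

#' Parse a BLAST-style tabular hit report
#'
#' Reads a headerless 12-column tabular report (standard `outfmt 6` order),
#' optionally extended by a 13th `qcovs` column carrying query coverage in
#' percent. Query coverage is taken from `qcovs` when present; otherwise it
#' is computed as `100 * (qend - qstart + 1) / query_length` from supplied
#' read lengths.
#'
#' @param path Path to the TSV file.
#' @param query_lengths Optional named vector of read lengths, required to
#'   derive coverage when the file has no `qcovs` column.
#' @return A tibble of hits: `query_id`, `accession`, `identity`, `coverage`,
#'   `evalue`, `bitscore`. Malformed numeric fields abort with the offending
#'   line number.
#' @export
parse_hit_table <- function(path, query_lengths = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("hit table not found: ", path))
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(query_id = character(), accession = character(),
                          identity = double(), coverage = double(),
                          evalue = double(), bitscore = double()))
  }
  assert_that(ncol(raw) >= 12,
              "hit table must have at least 12 tab-separated columns")
  names(raw)[1:12] <- BLAST_COLS
  has_qcovs <- ncol(raw) >= 13
  if (has_qcovs) names(raw)[13] <- "qcovs"

  num_cols <- c("pident", "qstart", "qend", "evalue", "bitscore",
                if (has_qcovs) "qcovs")
  parsed <- lapply(num_cols, function(cn) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !is.na(raw[[cn]]))
    if (length(bad) > 0)
      rlang::abort(sprintf("non-numeric `%s` field at line %d: '%s'",
                           cn, bad[1], raw[[cn]][bad[1]]))
    v
  })
  names(parsed) <- num_cols

  coverage <- if (has_qcovs) {
    parsed$qcovs
  } else {
    assert_that(!is.null(query_lengths),
                "no qcovs column: supply `query_lengths` to derive coverage")
    ql <- query_lengths[raw$qseqid]
    assert_that(!anyNA(ql), "query_lengths missing for some queries")
    100 * (parsed$qend - parsed$qstart + 1) / as.numeric(ql)
  }
  tibble::tibble(query_id = raw$qseqid, accession = raw$sseqid,
                 identity = parsed$pident, coverage = coverage,
                 evalue = parsed$evalue, bitscore = parsed$bitscore)
}

#' Filter hits on identity, coverage, and e-value
#'
#' Retains exactly the hits with `evalue < evalue_max` (strict, "below the
#' threshold"), `identity >= min_identity` and `coverage >= min_coverage`
#' (inclusive). Input order is preserved and the operation is idempotent.
#'
#' @param hits Hit tibble (see [parse_hit_table()]).
#' @param min_identity,min_coverage Inclusive percent thresholds.
#' @param evalue_max Strict e-value cutoff.
#' @return The retained hits, in input order.
#' @export
filter_hits <- function(hits, min_identity = 99, min_coverage = 99,
                        evalue_max = 1e-10) {
  assert_that(min_identity >= 0 && min_identity <= 100 &&
                min_coverage >= 0 && min_coverage <= 100,
              "identity/coverage thresholds must be percentages")
  hits |>
    dplyr::filter(.data$evalue < evalue_max,
                  .data$identity >= min_identity,
                  .data$coverage >= min_coverage)
}

#' Per-species lineage table
#'
#' @param taxonomy Taxonomy tibble.
#' @return A tibble with one row per species: `species_id` plus one column
#'   per rank holding the ancestor `taxon_id` at that rank.
#' @export
taxonomy_lineage <- function(taxonomy) {
  parent <- setNames(taxonomy$parent_id, taxonomy$taxon_id)
  rank_of <- setNames(taxonomy$rank, taxonomy$taxon_id)
  species <- taxonomy$taxon_id[taxonomy$rank == "species"]
  rows <- lapply(species, function(s) {
    path <- character(0)
    node <- s
    while (!is.na(node)) {
      path[rank_of[node]] <- node
      node <- parent[node]
    }
    tibble::as_tibble(as.list(path[TAX_RANKS]))
  })
  out <- dplyr::bind_rows(rows)
  names(out) <- TAX_RANKS
  dplyr::mutate(out, species_id = species, .before = 1)
}

root_path <- function(taxon, parent) {
  path <- character(0)
  node <- taxon
  while (!is.na(node)) {
    if (!(node %in% names(parent)))
      rlang::abort(paste0("unknown taxon_id: ", node))
    path <- c(node, path)
    node <- parent[[node]]
  }
  path
}

#' Lowest common taxon of a set of taxa
#'
#' Returns the deepest taxonomy node that is an ancestor-or-self of every
#' input taxon, by intersecting root paths.
#'
#' @param taxa Nonempty character vector of taxon ids (any rank).
#' @param taxonomy Taxonomy tibble.
#' @return A single `taxon_id`.
#' @examples
#' db <- generate_reference_db(n_species = 8, seed = 1)
#' lowest_common_taxon(db$refs$taxon_id[1:2], db$taxonomy)
#' @export
lowest_common_taxon <- function(taxa, taxonomy) {
  assert_that(length(taxa) >= 1, "taxa must be nonempty")
  parent <- as.list(setNames(taxonomy$parent_id, taxonomy$taxon_id))
  paths <- lapply(unique(taxa), root_path, parent = parent)
  shared <- Reduce(function(a, b) {
    n <- min(length(a), length(b))
    k <- which(a[seq_len(n)] != b[seq_len(n)])
    if (length(k) == 0) a[seq_len(n)] else a[seq_len(k[1] - 1)]
  }, paths)
  assert_that(length(shared) >= 1, "taxa share no common ancestor")
  shared[length(shared)]
}

LABEL_TOKENS <- c("unknown", "uncharacterized", "uncultured")

label_is_decorated <- function(x) {
  stringr::str_detect(tolower(x),
                      paste0("\\b(", paste(LABEL_TOKENS, collapse = "|"),
                             ")\\b"))
}

#' Choose a clean display label from candidates
#'
#' If any candidate lacks the tokens "unknown", "uncharacterized" or
#' "uncultured" (case-insensitive), the least-decorated such candidate is
#' returned; otherwise the decorated candidates are ranked the same way.
#' Ties are broken by fewest whitespace-separated tokens, then
#' lexicographically.
#'
#' @param raw_labels Nonempty character vector of candidate labels.
#' @return A single label.
#' @examples
#' clean_label(c("uncharacterized Chloroflexi", "Longilinea arvoryzae"))
#' @export
clean_label <- function(raw_labels) {
  assert_that(length(raw_labels) >= 1, "raw_labels must be nonempty")
  cand <- unique(raw_labels)
  clean <- cand[!label_is_decorated(cand)]
  pool <- if (length(clean) > 0) clean else cand
  n_tok <- stringr::str_count(pool, "\\S+")
  pool[order(n_tok, pool)][1]
}

#' Resolve one query's annotation from its filtered hits
#'
#' The hit with the highest bit score names the annotation. Bit scores are
#' compared after rounding to one decimal (tabular-report precision) so that
#' genuine ties are not split by float noise. When several hits tie at the
#' maximum, the annotation taxon is the lowest common taxon of the tied
#' species (accessions of one species tie at species level without lifting),
#' and the display label is chosen by [clean_label()] over the tied labels.
#'
#' @param hits_for_query Nonempty hit tibble for a single query, already
#'   filtered by [filter_hits()].
#' @param refs Reference tibble (accession, taxon_id, label).
#' @param taxonomy Taxonomy tibble.
#' @return A one-row tibble: `query_id`, `taxon_id`, `rank`, `label`,
#'   `accessions` (list column), `best_bitscore`.
#' @export
resolve_annotation <- function(hits_for_query, refs, taxonomy) {
  assert_that(nrow(hits_for_query) >= 1, "need at least one hit")
  assert_that(dplyr::n_distinct(hits_for_query$query_id) == 1,
              "hits_for_query must concern a single query")
  missing <- setdiff(hits_for_query$accession, refs$accession)
  if (length(missing) > 0)
    rlang::abort(paste0("accession absent from reference set: ", missing[1]))

  bs <- round(hits_for_query$bitscore, 1)
  top <- hits_for_query[bs == max(bs), ]
  accs <- sort(unique(top$accession))
  ridx <- match(accs, refs$accession)
  species <- unique(refs$taxon_id[ridx])
  taxon <- if (length(species) == 1) species else
    lowest_common_taxon(species, taxonomy)
  rank <- taxonomy$rank[match(taxon, taxonomy$taxon_id)]
  tibble::tibble(query_id = hits_for_query$query_id[1],
                 taxon_id = taxon, rank = rank,
                 label = clean_label(refs$label[ridx]),
                 accessions = list(accs),
                 best_bitscore = max(bs))
}

#' Annotate all queries in a hit table (round-1)
#'
#' Vectorised equivalent of applying [filter_hits()] at the round-1
#' thresholds followed by [resolve_annotation()] per query. Queries with no
#' surviving hit are absent from the result.
#'
#' @param hits Hit tibble for many queries.
#' @param refs Reference tibble.
#' @param taxonomy Taxonomy tibble.
#' @param config A [filter_config()].
#' @return Annotation tibble, one row per annotated query.
#' @export
annotate_queries <- function(hits, refs, taxonomy, config = filter_config()) {
  kept <- filter_hits(hits, config$round1_identity, config$round1_coverage,
                      config$evalue_max)
  if (nrow(kept) == 0) {
    return(tibble::tibble(query_id = character(), taxon_id = character(),
                          rank = character(), label = character(),
                          accessions = list(), best_bitscore = double()))
  }
  missing <- setdiff(kept$accession, refs$accession)
  if (length(missing) > 0)
    rlang::abort(paste0("accession absent from reference set: ", missing[1]))

  kept <- kept |>
    dplyr::mutate(bs = round(.data$bitscore, 1)) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::filter(.data$bs == max(.data$bs)) |>
    dplyr::ungroup() |>
    dplyr::distinct(.data$query_id, .data$accession, .keep_all = TRUE) |>
    dplyr::left_join(refs[c("accession", "taxon_id", "label")],
                     by = "accession")

  per_query <- kept |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(
      species = list(sort(unique(.data$taxon_id))),
      label = clean_label(.data$label),
      accessions = list(sort(unique(.data$accession))),
      best_bitscore = max(.data$bs),
      .groups = "drop")

  # lineage matrix (species x ranks) for fast LCA of tied species sets;
  # identical sets are resolved once
  lin <- taxonomy_lineage(taxonomy)
  lin_mat <- as.matrix(lin[TAX_RANKS])
  rownames(lin_mat) <- lin$species_id
  lca_of_set <- function(sp) {
    if (length(sp) == 1) return(sp)
    sub <- lin_mat[sp, , drop = FALSE]
    for (k in rev(seq_along(TAX_RANKS))) {
      anc <- unique(sub[, k])
      if (length(anc) == 1) return(anc)
    }
    NA_character_
  }
  keys <- vapply(per_query$species, paste, character(1), collapse = ";")
  uniq <- !duplicated(keys)
  lca_map <- vapply(per_query$species[uniq], lca_of_set, character(1))
  names(lca_map) <- keys[uniq]

  rank_of <- setNames(taxonomy$rank, taxonomy$taxon_id)
  per_query |>
    dplyr::mutate(taxon_id = unname(lca_map[keys]),
                  rank = unname(rank_of[.data$taxon_id]),
                  .after = "query_id") |>
    dplyr::select(-"species")
}
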