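#' Unpack an OTU into sub-OTUs by shared supporting accessions
#'
#' Builds a graph on the OTU's distinct member amplicon sequences with an
#' edge whenever two sequences share at least one supporting accession; the
#' connected components (i.e. the transitive closure of pairwise sharing)
#' are the sub-OTUs. Components are numbered `seq1, seq2, ...` by descending
#' member count; the representative of a component is its most read-abundant
#' exact sequence. Sub-OTUs of one parent partition its members and carry
#' pairwise-disjoint accession sets.
#'
#' @param members Tibble of the OTU's member reads: `read_id`, `sequence`,
#'   `accessions` (list column of supporting accessions, nonempty per read).
#' @param otu_id Parent OTU id used to build `subotu_id`s.
#' @return A tibble: `subotu_id`, `parent_otu_id`, `n_reads`,
#'   `representative`, `sequences` (list), `accession_set` (list),
#'   `read_ids` (list).
#' @export
unpack_otu <- function(members, otu_id = "OTU") {
  assert_that(nrow(members) >= 1, "OTU has no members")
  empty <- lengths(members$accessions) == 0
  if (any(empty))
    rlang::abort(paste0("member read with empty accession set: ",
                        members$read_id[which(empty)[1]]))

  per_seq <- members |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(n_reads = dplyr::n(),
                     accession_set = list(sort(unique(unlist(.data$accessions)))),
                     read_ids = list(.data$read_id),
                     .groups = "drop")
  n <- nrow(per_seq)

  # sequences sharing an accession are joined; components via igraph
  incidence <- per_seq |>
    dplyr::mutate(seq_idx = dplyr::row_number()) |>
    dplyr::select("seq_idx", "accession_set") |>
    tidyr::unnest("accession_set")
  edges <- incidence |>
    dplyr::inner_join(incidence, by = "accession_set",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$seq_idx.x < .data$seq_idx.y) |>
    dplyr::distinct(.data$seq_idx.x, .data$seq_idx.y)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]

  subs <- per_seq |>
    dplyr::mutate(component = unname(comp)) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      representative = .data$sequence[order(-.data$n_reads, .data$sequence)][1],
      n_reads = sum(.data$n_reads),
      sequences = list(.data$sequence),
      accession_set = list(sort(unique(unlist(.data$accession_set)))),
      read_ids = list(unlist(.data$read_ids)),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_reads), .data$representative) |>
    dplyr::mutate(subotu_id = sprintf("%s seq%d", otu_id, dplyr::row_number()),
                  parent_otu_id = otu_id, .before = 1) |>
    dplyr::select("subotu_id", "parent_otu_id", "n_reads", "representative",
                  "sequences", "accession_set", "read_ids")
  subs
}

GAP_CHARS <- c("-", ".", "N", "n")

#' Jukes-Cantor distance between two aligned sequences
#'
#' `d = -(3/4) ln(1 - 4p/3)` where `p` is the proportion of differing sites
#' among columns where both sequences carry a base (pairwise deletion of
#' gapped or ambiguous columns).
#'
#' @param a,b Equal-length aligned sequences (strings).
#' @param on_saturation `"error"` aborts when `p >= 0.75` (outside the model
#'   domain); `"cap"` caps the distance at the largest representable value.
#' @return Substitutions per site (nonnegative).
#' @examples
#' jc_distance("ACGTACGT", "ACGTACGA")
#' @export
jc_distance <- function(a, b, on_saturation = c("error", "cap")) {
  on_saturation <- match.arg(on_saturation)
  assert_that(nchar(a) == nchar(b), "sequences must be aligned (equal length)")
  va <- toupper(strsplit(a, "")[[1]])
  vb <- toupper(strsplit(b, "")[[1]])
  ok <- !(va %in% toupper(GAP_CHARS)) & !(vb %in% toupper(GAP_CHARS))
  if (!any(ok)) rlang::abort("no comparable (ungapped) columns")
  p <- mean(va[ok] != vb[ok])
  jc_from_p(p, on_saturation)
}

jc_from_p <- function(p, on_saturation = "error") {
  sat <- p >= 0.75
  if (any(sat)) {
    if (on_saturation == "error")
      rlang::abort(sprintf("Jukes-Cantor saturation: p = %.3f >= 0.75", max(p)))
    p[sat] <- 0.75 - 1e-9
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance matrix for an alignment
#'
#' @param alignment Named character vector of equal-length aligned sequences,
#'   or a character matrix (rows = sequences).
#' @param on_saturation See [jc_distance()].
#' @return A `dist` object in substitutions per site.
#' @export
jc_distance_matrix <- function(alignment, on_saturation = c("error", "cap")) {
  on_saturation <- match.arg(on_saturation)
  mat <- alignment_to_matrix(alignment)
  n <- nrow(mat)
  assert_that(n >= 2, "need at least two sequences")
  gap <- toupper(GAP_CHARS)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !(mat[i, ] %in% gap) & !(mat[j, ] %in% gap)
      if (!any(ok))
        rlang::abort(sprintf("no comparable columns between %s and %s",
                             rownames(mat)[i], rownames(mat)[j]))
      p <- mean(mat[i, ok] != mat[j, ok])
      d[i, j] <- d[j, i] <- jc_from_p(p, on_saturation)
    }
  }
  as.dist(d)
}

alignment_to_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    assert_that(!is.null(rownames(alignment)), "alignment needs row names")
    return(toupper(alignment))
  }
  assert_that(is.character(alignment) && !is.null(names(alignment)),
              "alignment must be a named character vector or matrix")
  L <- nchar(alignment)
  if (length(unique(L)) != 1)
    rlang::abort("unaligned input: sequences have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]); negative branch lengths are
#' clamped to zero and the total clamped deficit recorded in the
#' `"clamped_deficit"` attribute.
#'
#' @param d A `dist` object or symmetric matrix with >= 2 leaves.
#' @return An [ape::phylo] tree (unrooted for >= 3 leaves).
#' @export
nj_tree <- function(d) {
  d <- as_square_dist(d)
  n <- attr(d, "Size")
  assert_that(n >= 2, "need at least two leaves")
  if (n == 2) {
    labs <- attr(d, "Labels")
    tr <- ape::read.tree(text = sprintf("(%s:%.10f,%s:%.10f);",
                                        labs[1], d[1] / 2, labs[2], d[1] / 2))
    attr(tr, "clamped_deficit") <- 0
    return(tr)
  }
  tr <- ape::nj(d)
  neg <- tr$edge.length < 0
  attr(tr, "clamped_deficit") <- -sum(tr$edge.length[neg])
  tr$edge.length[neg] <- 0
  tr
}

#' Bootstrap support for the internal splits of an NJ tree
#'
#' Alignment columns are resampled with replacement; each replicate's
#' Jukes-Cantor NJ tree is scored against the original tree's bipartitions
#' (via [ape::boot.phylo()]). Support is the percentage of replicates
#' containing each split.
#'
#' @param alignment Named aligned sequences (vector or matrix).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return A list: `tree` (the original NJ tree), `support` (percent per
#'   internal node, in `tree$node.label` order; `NA` on the root node for
#'   trees with < 4 leaves there are no internal splits).
#' @export
bootstrap_support <- function(alignment, n_reps = 1000, seed = 1L) {
  assert_that(n_reps >= 1, "n_reps must be >= 1")
  mat <- alignment_to_matrix(alignment)
  build <- function(x) nj_tree(jc_distance_matrix(x, on_saturation = "cap"))
  tree <- build(mat)
  if (nrow(mat) < 4)
    return(list(tree = tree, support = setNames(numeric(0), character(0))))
  withr::local_seed(seed)
  counts <- ape::boot.phylo(tree, mat, build, B = n_reps, quiet = TRUE,
                            trees = FALSE, rooted = FALSE)
  support <- 100 * counts / n_reps
  # first internal node is the arbitrary root of the unrooted tree
  support[1] <- NA
  list(tree = tree, support = support)
}

#' Build a spiked Jukes-Cantor NJ tree with bootstrap supports
#'
#' Combines sub-OTU representative sequences with reference "spike"
#' sequences (closest isolated/cultured relatives) supplied as one multiple
#' alignment, computes Jukes-Cantor distances, builds the NJ tree, attaches
#' bootstrap supports as internal node labels (supports at or below
#' `threshold` are suppressed), and renders Newick text.
#'
#' @param subotus Sub-OTU tibble from [unpack_otu()] (may be empty if
#'   `spikes` alone carry >= 2 sequences).
#' @param spikes Named character vector of aligned spike sequences.
#' @param threshold Support percentage at or below which labels are hidden.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return A list of class `ambin_spiked_tree`: `tree` (phylo with
#'   `node.label` supports), `support` (full numeric vector), `newick`
#'   (string).
#' @export
spike_and_tree <- function(subotus, spikes, threshold = 50, n_boot = 1000,
                           seed = 1L) {
  # Newick leaf labels cannot carry spaces; write them as underscores
  leaf_ids <- gsub("\\s+", "_", subotus$subotu_id)
  seqs <- c(setNames(subotus$representative, leaf_ids), spikes)
  assert_that(length(seqs) >= 2, "need at least two aligned sequences")
  assert_that(!anyDuplicated(names(seqs)), "leaf labels must be unique")
  if (length(unique(nchar(seqs))) != 1)
    rlang::abort("unaligned input: sequences have unequal lengths")
  bs <- bootstrap_support(seqs, n_reps = n_boot, seed = seed)
  tree <- bs$tree
  if (length(bs$support) > 0) {
    lab <- ifelse(is.na(bs$support) | bs$support <= threshold, "",
                  sprintf("%d", round(bs$support)))
    tree$node.label <- lab
  }
  structure(list(tree = tree, support = bs$support,
                 newick = ape::write.tree(tree)),
            class = "ambin_spiked_tree")
}

#' @export
print.ambin_spiked_tree <- function(x, ...) {
  cat(sprintf("Spiked NJ tree: %d leaves, %d internal nodes\n",
              length(x$tree$tip.label), x$tree$Nnode))
  cat(x$newick, "\n")
  invisible(x)
}

#' Unpack every OTU of a binning into sub-OTUs
#'
#' @param binning An `otu_binning` (after both rounds).
#' @param reads Read tibble with `read_id` and `sequence`.
#' @return A tibble stacking [unpack_otu()] results over all OTUs.
#' @export
unpack_all_otus <- function(binning, reads) {
  seq_of <- setNames(reads$sequence, reads$read_id)
  binning$assignments |>
    dplyr::mutate(sequence = unname(seq_of[.data$read_id])) |>
    dplyr::group_by(.data$otu_id) |>
    dplyr::group_map(~ unpack_otu(.x, otu_id = .y$otu_id)) |>
    dplyr::bind_rows()
}
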