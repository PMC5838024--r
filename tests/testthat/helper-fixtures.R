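# Hand-built 7-rank taxonomy: two phyla under one superkingdom, species
# s1/s2 congeneric, s3 in a different phylum.
tiny_taxonomy <- function() {
  tibble::tribble(
    ~taxon_id, ~name,            ~rank,          ~parent_id,
    "k1", "Bacteria",            "superkingdom", NA,
    "p1", "PhylumOne",           "phylum",       "k1",
    "p2", "PhylumTwo",           "phylum",       "k1",
    "c1", "ClassOne",            "class",        "p1",
    "c2", "ClassTwo",            "class",        "p2",
    "o1", "OrderOne",            "order",        "c1",
    "o2", "OrderTwo",            "order",        "c2",
    "f1", "FamilyOne",           "family",       "o1",
    "f2", "FamilyTwo",           "family",       "o2",
    "g1", "GenusOne",            "genus",        "f1",
    "g2", "GenusTwo",            "genus",        "f2",
    "s1", "GenusOne alpha",      "species",      "g1",
    "s2", "GenusOne beta",       "species",      "g1",
    "s3", "GenusTwo gamma",      "species",      "g2")
}

tiny_refs <- function() {
  tibble::tibble(
    accession = c("ACC1", "ACC2", "ACC3"),
    taxon_id = c("s1", "s2", "s3"),
    label = c("GenusOne alpha", "GenusOne beta", "GenusTwo gamma"),
    sequence = c("ACGTACGT", "ACGTACGA", "TTTTCCCC"))
}

make_hit <- function(query_id, accession, identity = 100, coverage = 100,
                     evalue = 1e-50, bitscore = 500) {
  tibble::tibble(query_id = query_id, accession = accession,
                 identity = identity, coverage = coverage,
                 evalue = evalue, bitscore = bitscore)
}

# independent LCA oracle: intersect explicit root paths
brute_force_lca <- function(taxa, taxonomy) {
  parent <- setNames(taxonomy$parent_id, taxonomy$taxon_id)
  path_of <- function(t) {
    p <- t
    while (!is.na(parent[[t]])) {
      t <- parent[[t]]
      p <- c(t, p)
    }
    p
  }
  paths <- lapply(taxa, path_of)
  common <- Reduce(intersect, paths)
  common[length(common)]
}

depth_of <- function(taxon, taxonomy) {
  parent <- setNames(taxonomy$parent_id, taxonomy$taxon_id)
  d <- 0
  while (!is.na(parent[[taxon]])) {
    taxon <- parent[[taxon]]
    d <- d + 1
  }
  d
}

# hand implementation of the Bray-Curtis formula, used as an oracle
bray_oracle <- function(a, b) {
  1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# path-indicator matrix of a topology: rows = leaf pairs (in fixed label
# order), columns = edges; entry 1 when the edge lies on the pair's path
path_indicator_matrix <- function(tree, labs) {
  pairs <- t(combn(labs, 2))
  n_edge <- nrow(tree$edge)
  A <- matrix(0, nrow(pairs), n_edge)
  tr <- tree
  for (e in seq_len(n_edge)) {
    el <- rep(0, n_edge)
    el[e] <- 1
    tr$edge.length <- el
    cp <- ape::cophenetic.phylo(tr)
    A[, e] <- cp[pairs]
  }
  A
}

# unconstrained least-squares branch-length fit of a fixed topology to a
# distance matrix; returns the residual sum of squares
ls_topology_rss <- function(A, d, labs) {
  dm <- as.matrix(d)[labs, labs]
  y <- dm[t(combn(labs, 2))]
  fit <- lm.fit(A, y)
  sum(fit$residuals^2)
}
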