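#' Default configuration for an end-to-end synthetic run
#'
#' One seed per stochastic stage is derived from the master seed (small
#' offsets, kept within integer range), so every stage is independently
#' reproducible and the whole run is deterministic under a fixed config.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Master integer seed.
#' @param n_species,reads_per_sample,error_rate,divergence Synthetic
#'   community settings (see [generate_reference_db()] and
#'   [simulate_amplicons()]).
#' @param rarefaction_depth Common depth for [rarefy_samples()].
#' @param alpha Significance level for differential abundance.
#' @param permutations PERMANOVA permutation count.
#' @param bootstrap Tree bootstrap replicates.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, n_species = 30,
                       reads_per_sample = 500, error_rate = 0.004,
                       divergence = 0.02, rarefaction_depth = NULL,
                       alpha = 0.05, permutations = 999, bootstrap = 200) {
  assert_that(is.numeric(seed) && !is.na(seed) && abs(seed) < 2^31 - 10,
              "seed must be a small integer")
  seed <- as.integer(seed)
  assert_that(!is.na(seed),
              "seed must be a small integer")
  structure(list(
    out_dir = out_dir,
    n_species = n_species,
    reads_per_sample = reads_per_sample,
    error_rate = error_rate,
    divergence = divergence,
    rarefaction_depth = rarefaction_depth %||%
      floor(0.9 * reads_per_sample),
    alpha = alpha,
    permutations = permutations,
    bootstrap = bootstrap,
    filter = filter_config(),
    sparsity = sparsity_config(),
    seeds = list(reference = seed, amplicons = seed + 1L,
                 rarefaction = seed + 2L, counts = seed + 3L,
                 permanova = seed + 4L, bootstrap = seed + 5L)),
    class = "run_config")
}

validate_run_config <- function(config) {
  needed <- c("reference", "amplicons", "rarefaction", "permanova",
              "bootstrap")
  missing <- setdiff(needed, names(config$seeds))
  if (length(missing) > 0)
    rlang::abort(paste0("run config missing seed for stage: ", missing[1]))
  assert_that(config$rarefaction_depth <= config$reads_per_sample,
              "rarefaction depth exceeds reads per sample")
  invisible(config)
}

stage_files <- function(dir) {
  fs <- list.files(dir, full.names = TRUE, recursive = TRUE)
  tibble::tibble(file = basename(fs), md5 = unname(tools::md5sum(fs)))
}

#' Run the full synthetic-community analysis pipeline
#'
#' Executes: (1) reference/taxonomy generation, (2) amplicon simulation and
#' hit-table construction, (3) rarefaction and two-round annotation binning,
#' (4) sparsity and abundance filtering with size-factor normalization,
#' (5) diversity, ordination and PERMANOVA, and (6) pairwise NB Wald
#' differential abundance. Stage outputs are written as plain-text tables
#' under `config$out_dir` and a manifest of per-file checksums is returned;
#' rerunning with the same config reproduces identical checksums.
#'
#' @param config A [run_config()].
#' @param treatment_effects Optional tibble (`treatment`, `accession`,
#'   `weight`) of species weights per treatment; defaults to a built-in
#'   profile in which a subset of species respond to the metal treatments.
#' @return A list of class `run_manifest`: per-stage results plus `manifest`
#'   (file checksums) and the echoed `config`.
#' @export
run_pipeline <- function(config, treatment_effects = NULL) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  design <- sample_design()

  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      rlang::abort(sprintf("stage `%s` failed: %s", name,
                           conditionMessage(e))))
    stages <<- c(stages, name)
    out
  }

  db <- run_stage("reference", generate_reference_db(
    n_species = config$n_species, divergence = config$divergence,
    seed = config$seeds$reference))
  abundance <- treatment_effects %||%
    default_treatment_profile(db$refs, design, seed = config$seeds$reference)

  sim <- run_stage("amplicons", simulate_amplicons(
    db$refs, design, reads_per_sample = config$reads_per_sample,
    abundance = abundance, error_rate = config$error_rate,
    seed = config$seeds$amplicons))
  hits <- run_stage("hits", simulate_hit_table(sim$reads, db$refs))

  binned <- run_stage("binning", {
    rar <- rarefy_samples(sim$reads, config$rarefaction_depth,
                          seed = config$seeds$rarefaction)
    rar_hits <- hits |> dplyr::filter(.data$qseqid %in% rar$read_id)
    hit_tbl <- tibble::tibble(query_id = rar_hits$qseqid,
                              accession = rar_hits$sseqid,
                              identity = rar_hits$pident,
                              coverage = rar_hits$qcovs,
                              evalue = rar_hits$evalue,
                              bitscore = rar_hits$bitscore)
    ann <- annotate_queries(hit_tbl, db$refs, db$taxonomy, config$filter)
    b <- bin_round1(ann, rar)
    n1 <- nrow(b$assignments)
    b <- bin_round2(b, hit_tbl, config$filter)
    list(binning = b, rarefied = rar,
         rates = binning_rates(n1, nrow(b$assignments) - n1, nrow(rar)))
  })

  filtered <- run_stage("filtering", {
    counts <- build_count_matrix(binned$binning, design)
    sp <- sparsity_filter(counts, config$sparsity)
    sf <- size_factors_median_of_ratios(sp$retained)
    retained <- abundance_retention(sp$retained, sf, config$sparsity)
    list(counts = counts, retained = retained, flags = sp$flags,
         size_factors = sf)
  })

  stats <- run_stage("stats", {
    groups <- setNames(design$treatment, design$sample_id)
    div <- alpha_diversity(filtered$retained)
    d <- bray_curtis(filtered$retained)
    list(diversity = div,
         diversity_tests = diversity_ttests(div, design),
         bray = d,
         cap = cap(d, groups),
         permanova = permanova(d, groups, n_perm = config$permutations,
                               seed = config$seeds$permanova))
  })

  da <- run_stage("differential_abundance", {
    res <- da_all_contrasts(filtered$retained, design,
                            size_factors = filtered$size_factors)
    list(results = res,
         summary = pairwise_da_summary(res, alpha = config$alpha,
                                       n_retained = nrow(filtered$retained)))
  })

  # stage outputs on disk
  readr::write_tsv(design, file.path(config$out_dir, "samples.tsv"))
  write_taxonomy_table(db$refs, db$taxonomy,
                       file.path(config$out_dir, "taxonomy.tsv"))
  readr::write_tsv(filtered$counts, file.path(config$out_dir, "counts_raw.tsv"))
  readr::write_tsv(filtered$retained,
                   file.path(config$out_dir, "counts_retained.tsv"))
  readr::write_tsv(filtered$flags, file.path(config$out_dir, "otu_flags.tsv"))
  readr::write_tsv(stats$diversity, file.path(config$out_dir, "diversity.tsv"))
  readr::write_tsv(tibble::as_tibble(as.matrix(stats$bray), rownames = "sample_id"),
                   file.path(config$out_dir, "bray_curtis.tsv"))
  da_out <- tibble::as_tibble(da$results) |>
    dplyr::mutate(log2fc = format_log2fc(da$results))
  readr::write_tsv(da_out, file.path(config$out_dir, "da_results.tsv"))
  readr::write_tsv(da$summary$per_contrast,
                   file.path(config$out_dir, "da_per_contrast.tsv"))

  structure(list(
    config = config, design = design, reference = db,
    truth = sim$truth, rates = binned$rates, binning = binned$binning,
    reads = binned$rarefied,
    counts = filtered$counts, retained = filtered$retained,
    flags = filtered$flags, size_factors = filtered$size_factors,
    stats = stats, da = da,
    stages = stages, manifest = stage_files(config$out_dir)),
    class = "run_manifest")
}

#' Built-in treatment abundance profile
#'
#' Gives every species a log-normal baseline weight and marks a subset of
#' species as responders whose weight is scaled up or down in the metal
#' treatments (strongest under the three-metal mix, intermediate under zinc
#' and copper, none under lead), mirroring a community where most members
#' resist treatment and a minority respond.
#'
#' @param refs Reference tibble.
#' @param design Sample design tibble.
#' @param responder_fraction Fraction of species that respond to treatment.
#' @param seed Integer seed.
#' @return Tibble (`treatment`, `accession`, `weight`).
#' @export
default_treatment_profile <- function(refs, design, responder_fraction = 0.3,
                                      seed = 1L) {
  withr::local_seed(seed)
  treatments <- unique(design$treatment)
  base <- exp(stats::rnorm(nrow(refs), mean = 0, sd = 1))
  n_resp <- max(1, floor(responder_fraction * nrow(refs)))
  resp <- sample.int(nrow(refs), n_resp)
  dir <- sample(c(-1, 1), n_resp, replace = TRUE)
  effect <- c(control = 0, Pb = 0, Zn = 1, Cu = 1, three_metal = 2)
  purrr::map(treatments, function(tr) {
    w <- base
    e <- if (tr %in% names(effect)) effect[[tr]] else 0
    w[resp] <- w[resp] * 2^(dir * e)
    tibble::tibble(treatment = tr, accession = refs$accession, weight = w)
  }) |> dplyr::bind_rows()
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("ambin run: %d stages completed (%s)\n", length(x$stages),
              paste(x$stages, collapse = ", ")))
  cat(sprintf("  %d OTUs constructed, %d retained; %s%% of reads binned\n",
              nrow(x$counts), nrow(x$retained), x$rates$pct_binned))
  print(x$stats$permanova)
  invisible(x)
}
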