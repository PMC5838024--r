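#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: each sample's factor is the median,
#' over reference OTUs, of its counts divided by that OTU's geometric mean
#' across samples. Reference OTUs are those with all-positive rows; when no
#' such row exists the estimator falls back, with a warning, to geometric
#' means over positive counts only.
#'
#' @param counts Wide count tibble or matrix (OTU x sample).
#' @return A named vector of positive per-sample size factors.
#' @examples
#' m <- matrix(c(10, 20, 30, 5, 10, 15), nrow = 3,
#'             dimnames = list(paste0("o", 1:3), c("A", "B")))
#' size_factors_median_of_ratios(m)
#' @export
size_factors_median_of_ratios <- function(counts) {
  m <- as_count_matrix(counts)
  assert_that(all(colSums(m) > 0),
              "every sample needs at least one nonzero count")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (any(all_pos)) {
    logg <- rowMeans(log(m[all_pos, , drop = FALSE]))
    ratios <- log(m[all_pos, , drop = FALSE]) - logg
    sf <- exp(apply(ratios, 2, median))
  } else {
    rlang::warn("no all-positive OTU row; using positive-count-only geometric means")
    logm <- log(m)
    logm[!is.finite(logm)] <- NA
    logg <- rowMeans(logm, na.rm = TRUE)
    keep <- is.finite(logg)
    ratios <- logm[keep, , drop = FALSE] - logg[keep]
    sf <- exp(apply(ratios, 2, median, na.rm = TRUE))
  }
  assert_that(all(is.finite(sf) & sf > 0), "size factor estimation failed")
  sf
}

fisher_alpha_solve <- function(S, N, tol = 1e-12) {
  if (S >= N) {
    rlang::warn("all counts are singletons; Fisher's alpha diverges")
    return(Inf)
  }
  f <- function(a) a * log1p(N / a) - S
  uniroot(f, lower = 1e-12, upper = 1e12, tol = tol)$root
}

alpha_diversity_one <- function(x) {
  assert_that(sum(x) > 0, "all-zero sample")
  x <- x[x > 0]
  N <- sum(x)
  p <- x / N
  S <- length(x)
  F1 <- sum(x == 1)
  F2 <- sum(x == 2)
  simpson_D <- sum(p^2)
  tibble::tibble(
    observed = S,
    chao1 = S + F1 * (F1 - 1) / (2 * (F2 + 1)),
    shannon = -sum(p * log(p)),
    simpson = 1 - simpson_D,
    inv_simpson = 1 / simpson_D,
    fisher_alpha = fisher_alpha_solve(S, N))
}

#' Six alpha-diversity indices per sample
#'
#' Observed richness, bias-corrected Chao1
#' (`S + F1 (F1 - 1) / (2 (F2 + 1))` from singleton/doubleton counts),
#' Shannon entropy (natural log), Simpson's `1 - D`, inverse Simpson `1/D`,
#' and Fisher's alpha (the root of `S = alpha * ln(1 + N / alpha)`, solved to
#' 1e-12).
#'
#' @param counts Wide count tibble or matrix, or a single sample's
#'   nonnegative count vector.
#' @return A tibble with one row per sample and one column per index (plus
#'   `sample_id` for matrix input).
#' @export
alpha_diversity <- function(counts) {
  if (is.numeric(counts) && is.null(dim(counts)))
    return(alpha_diversity_one(counts))
  m <- as_count_matrix(counts)
  purrr::map(colnames(m), ~ alpha_diversity_one(m[, .x])) |>
    dplyr::bind_rows() |>
    dplyr::mutate(sample_id = colnames(m), .before = 1)
}

welch_pair <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y))
      return(tibble::tibble(t = 0, p = 1, degenerate = TRUE))
    return(tibble::tibble(t = sign(mean(y) - mean(x)) * Inf, p = 0,
                          degenerate = TRUE))
  }
  ht <- t.test(x, y)
  tibble::tibble(t = unname(ht$statistic), p = ht$p.value,
                 degenerate = FALSE)
}

#' Welch t-tests between all treatment pairs
#'
#' Compares a per-sample quantity (e.g. a diversity index) between every pair
#' of treatments with a two-sided Welch (unequal-variance) t-test. Pairs with
#' zero variance in both groups are reported as degenerate (t = 0, p = 1 when
#' means agree; p -> 0 limit flagged otherwise).
#'
#' @param values Named numeric vector (names are sample ids).
#' @param groups Named character vector mapping sample id to treatment.
#' @return A tibble: `group_a`, `group_b`, `t`, `p`, `degenerate`.
#' @export
group_ttest <- function(values, groups) {
  groups <- groups[names(values)]
  assert_that(!anyNA(groups), "every value needs a group")
  sizes <- table(groups)
  assert_that(all(sizes >= 2), "every group needs at least two samples")
  pairs <- combn(sort(unique(groups)), 2)
  purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    welch_pair(values[groups == a], values[groups == b]) |>
      dplyr::mutate(group_a = a, group_b = b, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Welch t-tests per diversity index and treatment pair
#'
#' @param diversity Tibble from [alpha_diversity()] (matrix form).
#' @param design Sample design tibble.
#' @return Tidy tibble: `index`, `group_a`, `group_b`, `t`, `p`,
#'   `degenerate`.
#' @export
diversity_ttests <- function(diversity, design) {
  groups <- setNames(design$treatment, design$sample_id)
  idx <- setdiff(names(diversity), "sample_id")
  purrr::map(idx, function(ix) {
    v <- setNames(diversity[[ix]], diversity$sample_id)
    group_ttest(v, groups) |> dplyr::mutate(index = ix, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = 1 - 2 * sum_i min(a_i, b_i) / (sum_i a_i + sum_i b_i)` over the
#' columns of the count table.
#'
#' @param counts Wide count tibble or matrix (OTU x sample), raw or
#'   normalized; every sample must have a positive total.
#' @return A `dist` object over samples with entries in `[0, 1]`.
#' @export
bray_curtis <- function(counts) {
  m <- as_count_matrix(counts)
  assert_that(all(colSums(m) > 0), "sample with zero total count")
  vegan::vegdist(t(m), method = "bray")
}

as_square_dist <- function(d) {
  if (inherits(d, "dist")) return(d)
  m <- as.matrix(d)
  assert_that(isTRUE(all.equal(m, t(m), tolerance = 1e-12)),
              "distance matrix must be symmetric")
  assert_that(all(diag(m) == 0), "distance matrix must have zero diagonal")
  as.dist(m)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Negative eigenvalues are reported but their axes dropped (no
#' Lingoes/Cailliez correction).
#'
#' @param d A `dist` object or symmetric matrix.
#' @return An object of class `ambin_pcoa`: `points` (tibble `sample_id` +
#'   `Axis1..k`), `eigenvalues` (all, descending), `negative_eigenvalues`.
#' @export
pcoa <- function(d) {
  d <- as_square_dist(d)
  n <- attr(d, "Size")
  res <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- res$eig
  tol <- 1e-8 * max(abs(eig))
  npos <- sum(eig > tol)
  pts <- res$points[, seq_len(npos), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(npos))
  structure(list(
    points = tibble::as_tibble(pts) |>
      dplyr::mutate(sample_id = attr(d, "Labels") %||%
                      rownames(res$points), .before = 1),
    eigenvalues = sort(eig, decreasing = TRUE),
    negative_eigenvalues = eig[eig < -tol]),
    class = c("ambin_pcoa", "ambin_ordination"))
}

#' Constrained analysis of principal coordinates (CAP)
#'
#' Distance-based redundancy analysis of a dissimilarity matrix constrained
#' on treatment membership: principal coordinates are regressed on treatment
#' indicators and the fitted variation eigendecomposed, yielding at most
#' (number of groups - 1) constrained axes. Backed by [vegan::capscale()].
#'
#' @param d A `dist` object or symmetric matrix over samples.
#' @param groups Named character vector mapping sample id to treatment.
#' @return An object of class `ambin_cap`: `points` (site scores on
#'   constrained axes, with treatment), `eigenvalues` (constrained),
#'   `residual_eigenvalues`, `constrained_fraction`.
#' @export
cap <- function(d, groups) {
  d <- as_square_dist(d)
  labs <- attr(d, "Labels")
  groups <- groups[labs]
  assert_that(!anyNA(groups), "every sample needs a group")
  assert_that(dplyr::n_distinct(groups) >= 2,
              "CAP needs at least two groups")
  df <- data.frame(treatment = factor(groups))
  fit <- vegan::capscale(d ~ treatment, data = df)
  eig_c <- unname(fit$CCA$eig)
  eig_r <- unname(fit$CA$eig)
  k <- length(eig_c)
  pts <- vegan::scores(fit, display = "sites", choices = seq_len(k))
  colnames(pts) <- paste0("CAP", seq_len(k))
  structure(list(
    points = tibble::as_tibble(pts) |>
      dplyr::mutate(sample_id = labs, treatment = unname(groups),
                    .before = 1),
    eigenvalues = eig_c,
    residual_eigenvalues = eig_r,
    constrained_fraction = sum(eig_c) /
      (sum(eig_c) + sum(eig_r[eig_r > 0]))),
    class = c("ambin_cap", "ambin_ordination"))
}

#' Permutational multivariate analysis of variance
#'
#' Partitions distance-based variance between and within groups and compares
#' the observed pseudo-F against label permutations:
#' `p = (1 + #(F* >= F)) / (1 + n_perm)`. Labels are permuted freely by
#' default; supplying `strata` restricts permutation to within blocks (the
#' split-plot layout). Backed by [vegan::adonis2()].
#'
#' @param d A `dist` object or symmetric matrix.
#' @param groups Named character vector mapping sample id to treatment.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @param strata Optional named vector of block labels per sample.
#' @return An object of class `ambin_permanova` with `pseudo_F`, `p`,
#'   `n_perm`, `r_squared` and the underlying ANOVA `table`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L, strata = NULL) {
  assert_that(n_perm >= 1, "n_perm must be at least 1")
  d <- as_square_dist(d)
  labs <- attr(d, "Labels")
  groups <- groups[labs]
  assert_that(!anyNA(groups), "every sample needs a group")
  df <- data.frame(treatment = factor(groups))
  ctrl <- if (is.null(strata)) {
    permute::how(nperm = n_perm)
  } else {
    permute::how(nperm = n_perm,
                 blocks = factor(strata[labs]))
  }
  withr::local_seed(seed)
  tab <- vegan::adonis2(d ~ treatment, data = df, permutations = ctrl)
  structure(list(pseudo_F = tab$F[1], p = tab$`Pr(>F)`[1],
                 n_perm = n_perm, r_squared = tab$R2[1],
                 table = as.data.frame(tab)),
            class = "ambin_permanova")
}

#' @export
print.ambin_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
    x$pseudo_F, x$r_squared, x$p, x$n_perm))
  invisible(x)
}

#' @method tidy ambin_permanova
#' @export
tidy.ambin_permanova <- function(x, ...) {
  tab <- x$table
  tibble::tibble(term = rownames(tab), df = tab$Df, sum_of_squares = tab$SumOfSqs,
                 r_squared = tab$R2, statistic = tab$F, p_value = tab$`Pr(>F)`)
}

#' @method glance ambin_permanova
#' @export
glance.ambin_permanova <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, r_squared = x$r_squared,
                 p_value = x$p, n_perm = x$n_perm)
}

#' @export
print.ambin_pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d positive axes (first eigenvalue %.3f)\n",
              ncol(x$points) - 1, x$eigenvalues[1]))
  invisible(x)
}

#' @export
print.ambin_cap <- function(x, ...) {
  cat(sprintf("CAP: %d constrained axes, %.1f%% of positive inertia constrained\n",
              length(x$eigenvalues), 100 * x$constrained_fraction))
  invisible(x)
}

#' @method tidy ambin_cap
#' @export
tidy.ambin_cap <- function(x, ...) {
  tibble::tibble(axis = paste0("CAP", seq_along(x$eigenvalues)),
                 eigenvalue = x$eigenvalues,
                 proportion = x$eigenvalues / sum(x$eigenvalues))
}
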