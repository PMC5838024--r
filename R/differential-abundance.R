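# Vectorised maximum-likelihood fit of one NB group mean per OTU with fixed
# dispersion: solves sum_j (y_ij - s_j q_i) / (1 + alpha_i s_j q_i) = 0 by
# Newton iteration. `alpha` recycles along rows (one value per OTU).
fit_nb_group <- function(Y, s, alpha, n_iter = 40) {
  S <- matrix(s, nrow(Y), ncol(Y), byrow = TRUE)
  q <- rowMeans(Y / S)
  pos <- q > 0
  for (it in seq_len(n_iter)) {
    mu <- q * S
    denom <- 1 + alpha * mu
    f <- rowSums((Y - mu) / denom)
    fp <- -rowSums(S * (1 + alpha * Y) / denom^2)
    step <- f / fp
    step[!pos] <- 0
    q <- pmax(q - step, 1e-12)
    if (all(abs(step) < 1e-10)) break
  }
  q[!pos] <- 0
  q
}

nb_information <- function(q, s, alpha) {
  # expected Fisher information for the log-mean parameter
  mu <- q %o% s
  rowSums(mu / (1 + alpha * mu))
}

#' Per-OTU negative-binomial dispersion estimates
#'
#' A simplified moments-plus-trend scheme: the raw dispersion is the
#' method-of-moments value `max(0, (s2 - mu) / mu^2)` from the pooled
#' within-group variance of normalized counts, with a small-sample
#' chi-squared recentring of `s2` on the log scale (the robust trend and
#' geometric shrinkage below track the median of the skewed variance
#' estimate, which would otherwise bias dispersions low and inflate Wald
#' statistics); a monotone mean-dispersion
#' trend `a1 / mu + a0` is fitted to positive raw values by robust
#' regression; the final value shrinks the raw estimate toward the trend
#' geometrically with weight 0.5 (OTUs with zero raw dispersion take the
#' trend value), floored at 1e-8. All-zero OTUs receive no estimate.
#'
#' @param counts Wide count tibble or matrix.
#' @param size_factors Named per-sample size factors.
#' @param groups Named character vector mapping sample id to treatment
#'   (every group needs >= 2 samples).
#' @return A tibble: `otu_id`, `mean_norm`, `raw_dispersion`,
#'   `fitted_dispersion`, `final_dispersion`.
#' @export
estimate_dispersions <- function(counts, size_factors, groups) {
  m <- as_count_matrix(counts)
  sf <- size_factors[colnames(m)]
  assert_that(!anyNA(sf), "size_factors must cover every sample")
  groups <- groups[colnames(m)]
  assert_that(!anyNA(groups), "groups must cover every sample")
  sizes <- table(groups)
  assert_that(all(sizes >= 2), "every group needs at least two samples")

  norm <- sweep(m, 2, sf, "/")
  keep <- rowSums(m) > 0
  norm <- norm[keep, , drop = FALSE]

  df_tot <- 0
  mu_bar <- rowMeans(norm)
  ss_within <- rep(0, nrow(norm))
  for (g in names(sizes)) {
    cols <- which(groups == g)
    gm <- rowMeans(norm[, cols, drop = FALSE])
    ss_within <- ss_within +
      rowSums((norm[, cols, drop = FALSE] - gm)^2)
    df_tot <- df_tot + length(cols) - 1
  }
  s2 <- ss_within / df_tot
  # small-sample correction: s2 ~ sigma^2 chi^2_df / df is right-skewed, so
  # downstream robust/geometric summaries track its low median; recentre on
  # the log scale (E[log chi^2_df/df] = digamma(df/2) - log(df/2))
  bias <- exp(log(df_tot / 2) - digamma(df_tot / 2))
  raw <- pmax(0, (bias * s2 - mu_bar) / mu_bar^2)

  floor_val <- 1e-8
  use <- raw > 0 & mu_bar > 0
  if (sum(use) >= 3) {
    fit <- tryCatch(
      MASS::rlm(raw[use] ~ I(1 / mu_bar[use]), maxit = 50),
      error = function(e) NULL)
    cf <- if (is.null(fit)) c(median(raw[use]), 0) else coef(fit)
    a0 <- max(cf[1], 0); a1 <- max(cf[2], 0)
    if (a0 == 0 && a1 == 0) a0 <- max(median(raw[use]), floor_val)
  } else {
    a0 <- max(median(raw), floor_val); a1 <- 0
  }
  trend <- pmax(a1 / mu_bar + a0, floor_val)
  final <- ifelse(raw <= floor_val, pmax(trend, floor_val),
                  sqrt(pmax(raw, floor_val) * trend))
  tibble::tibble(otu_id = rownames(norm), mean_norm = unname(mu_bar),
                 raw_dispersion = unname(raw),
                 fitted_dispersion = unname(trend),
                 final_dispersion = unname(pmax(final, floor_val)))
}

#' Negative-binomial Wald test for one treatment contrast
#'
#' Fits a two-group NB model with log link and fixed per-OTU dispersion; the
#' log2 fold change `log2(mu_b / mu_a)` is tested against its standard error
#' (from the inverse expected information) with a two-sided normal reference.
#' OTUs with counts in exactly one of the two groups are reported with
#' status `infinite_fc` (the sign of the change is still meaningful); their
#' p-value comes from the same fit with the absent group's mean floored at
#' 0.5 normalized counts. OTUs with zero counts in both groups are
#' `untested_allzero`.
#'
#' @param counts Wide count tibble or matrix.
#' @param size_factors Named per-sample size factors.
#' @param dispersions Tibble from [estimate_dispersions()].
#' @param groups Named character vector mapping sample id to treatment.
#' @param contrast Length-2 character vector `c(a, b)`; the fold change is b
#'   over a.
#' @return A tibble of per-OTU results: `otu_id`, `contrast_a`,
#'   `contrast_b`, `base_mean`, `log2fc`, `lfc_se`, `stat`, `pvalue`,
#'   `padj` (NA; see [bh_adjust()]), `status`.
#' @export
wald_test <- function(counts, size_factors, dispersions, groups,
                      contrast) {
  assert_that(length(contrast) == 2, "contrast must be c(a, b)")
  m <- as_count_matrix(counts)
  sf <- size_factors[colnames(m)]
  groups <- groups[colnames(m)]
  a_cols <- which(groups == contrast[1])
  b_cols <- which(groups == contrast[2])
  assert_that(length(a_cols) >= 2 && length(b_cols) >= 2,
              "both contrast groups need at least two samples")

  alpha <- setNames(dispersions$final_dispersion, dispersions$otu_id)[
    rownames(m)]
  alpha[is.na(alpha)] <- 1e-8

  base_mean <- rowMeans(sweep(m, 2, sf, "/"))
  Ya <- m[, a_cols, drop = FALSE]; sa <- sf[a_cols]
  Yb <- m[, b_cols, drop = FALSE]; sb <- sf[b_cols]
  zero_a <- rowSums(Ya) == 0
  zero_b <- rowSums(Yb) == 0

  qa <- fit_nb_group(Ya, sa, alpha)
  qb <- fit_nb_group(Yb, sb, alpha)
  status <- dplyr::case_when(
    zero_a & zero_b ~ "untested_allzero",
    xor(zero_a, zero_b) ~ "infinite_fc",
    .default = "tested")

  # pseudo-mean floor for the absent group of infinite-fold-change OTUs
  qa_f <- ifelse(status == "infinite_fc" & zero_a, 0.5, qa)
  qb_f <- ifelse(status == "infinite_fc" & zero_b, 0.5, qb)

  info_a <- nb_information(qa_f, sa, alpha)
  info_b <- nb_information(qb_f, sb, alpha)
  se <- sqrt(1 / info_a + 1 / info_b) / log(2)
  lfc_fit <- log2(qb_f / qa_f)
  stat <- lfc_fit / se
  pval <- 2 * pnorm(-abs(stat))

  lfc <- ifelse(status == "infinite_fc",
                ifelse(zero_a, Inf, -Inf), lfc_fit)
  untested <- status == "untested_allzero"
  lfc[untested] <- NA; se[untested] <- NA
  stat[untested] <- NA; pval[untested] <- NA

  tibble::tibble(otu_id = rownames(m),
                 contrast_a = contrast[1], contrast_b = contrast[2],
                 base_mean = base_mean, log2fc = lfc, lfc_se = se,
                 stat = stat, pvalue = pval, padj = NA_real_,
                 status = status)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjustment with enforced monotonicity. `NA` entries (untested
#' OTUs) are excluded from the family size and returned as `NA`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  assert_that(all(pvalues[ok] >= 0 & pvalues[ok] <= 1),
              "p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' All pairwise treatment contrasts
#'
#' Runs [wald_test()] for every unordered pair of treatments (in design
#' order) and applies [bh_adjust()] within each contrast separately, so each
#' comparison forms its own multiple-testing family.
#'
#' @param counts Wide count tibble or matrix.
#' @param design Sample design tibble.
#' @param size_factors Optional named size factors (estimated by
#'   median-of-ratios when omitted).
#' @param dispersions Optional dispersion tibble (estimated when omitted).
#' @return An `ambin_da` tibble stacking all per-contrast results.
#' @export
da_all_contrasts <- function(counts, design, size_factors = NULL,
                             dispersions = NULL) {
  groups <- setNames(design$treatment, design$sample_id)
  if (is.null(size_factors))
    size_factors <- size_factors_median_of_ratios(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, size_factors, groups)
  pairs <- combn(unique(design$treatment), 2)
  res <- purrr::map(seq_len(ncol(pairs)), function(k) {
    r <- wald_test(counts, size_factors, dispersions, groups,
                   contrast = pairs[, k])
    r$padj <- bh_adjust(r$pvalue)
    r
  }) |> dplyr::bind_rows()
  class(res) <- c("ambin_da", class(res))
  res
}

#' Pairwise differential-abundance bookkeeping
#'
#' An OTU counts as differentially abundant (DA) in a contrast when it was
#' testable (not all-zero) and both its raw p-value and its BH-adjusted
#' p-value fall below `alpha`; infinite-fold-change OTUs are testable.
#' Reports per-contrast DA counts, the total number of pairwise DA
#' instances, the number of distinct DA OTUs, and (when the number of
#' retained OTUs is supplied) the non-DA fraction of the community.
#'
#' @param results DA result tibble (stacked contrasts, e.g. from
#'   [da_all_contrasts()]).
#' @param alpha Significance level for both cutoffs.
#' @param n_retained Optional number of OTUs in the tested table.
#' @return A list: `per_contrast` (tibble `contrast_a`, `contrast_b`,
#'   `n_da`) and `summary` (one-row tibble with `total_instances`,
#'   `distinct_da_otus`, and when available `n_retained`, `n_non_da`,
#'   `non_da_pct`).
#' @export
pairwise_da_summary <- function(results, alpha = 0.05, n_retained = NULL) {
  if (nrow(results) == 0) {
    per <- tibble::tibble(contrast_a = character(),
                          contrast_b = character(), n_da = integer())
    smry <- tibble::tibble(total_instances = 0L, distinct_da_otus = 0L)
    return(list(per_contrast = per, summary = smry))
  }
  res <- results |>
    dplyr::mutate(is_da = .data$status %in% c("tested", "infinite_fc") &
                    !is.na(.data$pvalue) & .data$pvalue < alpha &
                    !is.na(.data$padj) & .data$padj < alpha)
  per <- res |>
    dplyr::group_by(.data$contrast_a, .data$contrast_b) |>
    dplyr::summarise(n_da = sum(.data$is_da), .groups = "drop")
  distinct_da <- dplyr::n_distinct(res$otu_id[res$is_da])
  smry <- tibble::tibble(total_instances = sum(per$n_da),
                         distinct_da_otus = distinct_da)
  if (!is.null(n_retained)) {
    smry$n_retained <- n_retained
    smry$n_non_da <- n_retained - distinct_da
    smry$non_da_pct <- round(100 * (1 - distinct_da / n_retained))
  }
  list(per_contrast = per, summary = smry)
}

#' Shifted-log variance-stabilizing transform
#'
#' `log2(count / size_factor + 1)`, for diagnostics and plotting only (tests
#' always run on raw counts with the NB model).
#'
#' @param counts Wide count tibble or matrix.
#' @param size_factors Named positive per-sample size factors.
#' @return A numeric matrix of transformed values.
#' @export
vst_transform <- function(counts, size_factors) {
  m <- as_count_matrix(counts)
  sf <- size_factors[colnames(m)]
  assert_that(all(!is.na(sf) & sf > 0), "size factors must be positive")
  log2(sweep(m, 2, sf, "/") + 1)
}

#' Render log2 fold changes with infinite statuses
#'
#' @param results DA result tibble.
#' @return Character vector: numeric fold changes formatted, infinite ones
#'   as `"+INF"`/`"-INF"`, untested as `NA`.
#' @export
format_log2fc <- function(results) {
  dplyr::case_when(
    results$status == "infinite_fc" & is.infinite(results$log2fc) &
      results$log2fc > 0 ~ "+INF",
    results$status == "infinite_fc" ~ "-INF",
    results$status == "untested_allzero" ~ NA_character_,
    .default = sprintf("%.3f", results$log2fc))
}

#' @method glance ambin_da
#' @export
glance.ambin_da <- function(x, alpha = 0.05, ...) {
  pairwise_da_summary(x, alpha = alpha)$summary
}

#' @method tidy ambin_da
#' @export
tidy.ambin_da <- function(x, ...) {
  tibble::as_tibble(x)
}
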