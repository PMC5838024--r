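---
title: "Annotation-binned amplicon community analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-binned amplicon community analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambin)
```

## What the package models

Sequence-similarity OTU clustering builds consensus sequences and discards
the identity of individual amplicons. `ambin` takes the opposite route: each
amplicon keeps its best database annotation, and an OTU is simply the set of
reads sharing one resolved taxonomic call. This preserves species-level
signal where the amplified region is discriminative, and it makes the loss
of resolution explicit where it is not — ties between database records
collapse the call to the lowest taxon shared by all tied hits, so an OTU's
rank honestly reflects what the amplicon can distinguish.

The package covers the full path from alignment hit tables to publishable
statistics: two-round annotation binning, sparsity filtering, alpha
diversity, Bray–Curtis ordination (PCoA and CAP), PERMANOVA, pairwise
negative-binomial Wald tests, and sub-OTU unpacking with spiked
neighbor-joining trees. A seeded synthetic-community generator supplies
ground truth for every stage.

## The binning procedure and its thresholds

Hits are retained at e-value strictly below `1e-10` ("below the threshold"
is read as strict; identity and coverage thresholds are inclusive, matching
their "at least" phrasing). Round 1 requires ≥ 99% identity and ≥ 99% query
coverage; the top bit score wins, with bit scores compared after rounding to
one decimal because tabular alignment reports print one decimal — comparing
raw floats would split genuinely tied hits. Ties across species lift the
call to the lowest common taxon; multiple records of one species tie at
species rank without lifting. Display labels drop "unknown",
"uncharacterized" and "uncultured" candidates when an undecorated
alternative exists, preferring the shortest label (fewest tokens, then
lexicographic) deterministically.

Round 2 revisits unannotated reads at ≥ 98%/98% but may only place them
into OTUs that already registered the hit's accession in round 1 — the
step recovers error-bearing copies of sequences the data already supports,
rather than founding less confident OTUs. Ties across candidate OTUs go to
the larger round-1 OTU, then the lexicographically smaller id; registry and
totals are frozen at the end of round 1 so the rescue is independent of
read order.

Rarefaction (uniform subsampling without replacement to a common depth) is
applied once, before binning: it is read-level preprocessing, and binning
afterwards keeps the two rounds' percentages interpretable against a single
rarefied total. The sparsity filter flags OTUs present in fewer than 4
samples or with max-sample:total ≥ 0.75 (retention requires the ratio to be
strictly below 0.75 — such rows are a high total concentrated in one
sample, which no replicated effect can explain), and the abundance filter
keeps OTUs with strictly more than 10 total normalized counts so that
near-empty rows do not perturb the median-of-ratios estimator.

## The count model

Counts are modeled as negative binomial with `Var = μ + αμ²`. Size factors
are median-of-ratios: the median across reference OTUs of a sample's counts
over that OTU's geometric mean, using all-positive rows as references (with
a positive-counts-only fallback plus warning for very sparse tables).

Dispersion is estimated in three steps, per OTU:

1. **Moments.** `α_raw = max(0, (c·s² − μ̄)/μ̄²)` from the pooled
   within-group variance `s²` of normalized counts. The factor
   `c = exp(log(df/2) − digamma(df/2))` recentres `s²` on the log scale:
   with a handful of residual degrees of freedom the variance estimate is
   strongly right-skewed, and the robust/geometric steps below track its
   median rather than its mean. Without the recentring, dispersions come
   out low and Wald statistics inflate; with it, null rejection sits at the
   nominal level in the package's own calibration tests.
2. **Trend.** A monotone mean-dispersion trend `α(μ) = a₁/μ + a₀` fitted to
   positive raw values by Huber robust regression (coefficients clamped
   nonnegative), so individual noisy estimates borrow strength across OTUs.
3. **Shrinkage.** `α_final = √(α_raw · α_trend)` (geometric, weight 0.5);
   OTUs with zero raw dispersion take the trend value; everything is
   floored at `1e-8`.

The Wald test fits one mean per group by Newton iteration on the NB score
equation with the dispersion held fixed, and tests
`log₂(μ_b/μ_a)` against its standard error from the inverse expected
information, with a two-sided normal reference. OTUs observed in exactly
one group are reported as ±INF fold change — a reporting status, not a
numeric — while their p-value comes from the same machinery with the absent
group's mean floored at 0.5 normalized counts. Benjamini–Hochberg control
is applied within each treatment pair separately (ten families), because
the bookkeeping of interest is per-comparison DA counts; an OTU is declared
DA only when both raw and adjusted p fall below 0.05. Whether a joint
family across contrasts is preferable was genuinely open; per-contrast was
chosen and is visible in the output layout (one `padj` column per stacked
contrast).

The shifted log `log₂(count/size_factor + 1)` is provided for diagnostics
and plotting only; tests always run on raw counts.

## Ordination and permutation inference

Bray–Curtis dissimilarities feed PCoA (Gower double-centering; negative
eigenvalues are reported but their axes dropped — no Lingoes/Cailliez
correction, since the package's ordinations are descriptive) and CAP
(distance-based RDA on treatment indicators, at most `groups − 1`
constrained axes). PERMANOVA permutes labels freely by default with
`p = (1 + #{F* ≥ F})/(1 + n_perm)` and 999 permutations as the
conventional default; a `strata` argument permutes within blocks for
split-plot designs. Welch's unequal-variance t-test compares diversity
indices between groups: with n = 4 per group, variance homogeneity is
unverifiable, so the safer test is the default. Groups with zero variance
on both sides are reported as degenerate rather than silently producing a
p-value.

## Sub-OTUs and trees

Within one OTU, distinct amplicon sequences are joined when their
supporting-accession sets intersect; sub-OTUs are the connected components
(the transitive closure — pairwise splitting alone would not partition the
members). Jukes–Cantor distances use pairwise deletion of gapped columns,
tolerating ragged fragment alignments; `p ≥ 0.75` is outside the model and
raises an error (bootstrap replicates cap instead, since resampling can
push borderline pairs over). Neighbor joining clamps negative branch
lengths to zero and records the deficit. Bootstrap supports resample
alignment columns, rebuild the JC/NJ tree, and report the percentage of
replicates containing each original split; supports at or below 50% are
suppressed in labels. Replicate trees are built from JC distances (not raw
p-distances) for consistency with the reported tree. Multiple sequence
alignment is an input contract: representatives and spikes must arrive
aligned to one length.

## The synthetic generator

The generator emulates the study design the analysis assumes: five
treatments (control, Pb, Zn, Cu, three-metal) × four blocks, a seven-rank
taxonomy, one ~400 bp reference fragment per species (matching typical
partial 16S amplicon length), within-genus divergence of 2–5%, a
configurable fraction of genera with byte-identical fragments (forcing the
tie machinery to work), substitution-only read errors, full-coverage hits
with `bitscore = 2(matches − 3·mismatches)` and `evalue = 10^(−bitscore/10)`
(strictly monotone in mismatches, preserving tie structure — real
alignment statistics are out of scope), and NB counts with per-OTU
baselines, dispersions and log₂ treatment effects. The built-in treatment
profile perturbs a 30% subset of species under Zn/Cu (±1 log₂) and the
three-metal mix (±2 log₂) and leaves Pb neutral, mirroring a community in
which most members resist treatment and the strongest response follows the
combined stress.

What it does **not** emulate: indels and homopolymer errors (binning uses
only identity/coverage fields, so they buy nothing), chimeras, primer
bias, 16S copy-number variation, partial-coverage alignments (injected only
by explicit test fixtures), or real database label noise beyond the
decorated-label fraction. Passing the synthetic benchmarks therefore
demonstrates that the machinery is correct and calibrated under the stated
model — not that any particular real community will be recovered at a given
accuracy.

## Numerical choices and degenerate inputs

* Fisher's α is solved by `uniroot` to `1e-12`; an all-singleton sample has
  no finite solution and returns `Inf` with a warning.
* Newton iteration for group means starts at the ratio-of-means estimate,
  stays positive, and converges in a handful of steps at any `α ≥ 0`
  (`α = 0` reduces to Poisson).
* All-zero OTUs are untested; all-zero samples are rejected at the door.
* Every stochastic stage takes an explicit integer seed
  (`withr::local_seed`, restoring the caller's RNG); `run_pipeline`
  validates that every stage has a seed before anything executes and
  manifests md5 checksums of all outputs, so a rerun with the same
  configuration is byte-identical.

The test suite and the acceptance script size their simulations to run on
one CPU in minutes: 10–30 species, 20 samples, 80–1000 reads per sample for
binning oracles; 500–2000 OTUs for Wald calibration and power; 500 null
datasets for PERMANOVA level; 50–100 random 5-leaf additive matrices for
NJ recovery. These sizes give binomial confidence intervals narrow enough
for the bands being checked while keeping full-suite runtime small.

## Interfaces

The package exposes plain functions over tibbles — the natural command
surface for an R analysis package. `run_pipeline(run_config(...))` plays
the role of a one-shot orchestrated run (staged execution, fail-fast with
the failing stage named, checksum manifest); the individual stages
(`simulate_*`, `annotate_queries`, `bin_round1`/`bin_round2`,
`sparsity_filter`, `alpha_diversity`, `bray_curtis`/`cap`/`permanova`,
`da_all_contrasts`, `unpack_otu`/`spike_and_tree`) are directly scriptable,
and all stage outputs are written as plain TSV/FASTA/Newick for
interoperability with standard viewers and downstream tools.

## Known limitations

* The dispersion machinery is deliberately simpler than full
  profile-likelihood shrinkage; its fidelity target is calibration of the
  resulting tests, not numerical identity with any particular
  implementation. Independent filtering and fold-change shrinkage are
  omitted.
* Only single-factor (treatment) designs are supported; blocks enter only
  as optional permutation strata.
* Annotation quality is bounded by the reference database: the method
  inherits any taxonomic errors in it, and the lowest-common-taxon rule can
  only make that explicit, not fix it.
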