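# ambin — annotation-binned 16S rRNA amplicon community analysis

`ambin` implements an annotation-based alternative to similarity-clustered
OTUs for 16S rRNA gene amplicon surveys, aimed at microbial ecologists who
want taxon-resolved community comparisons (e.g. soils under heavy-metal
stress) without consensus-sequence clustering. Reads are binned by their
best database annotation, and everything downstream — diversity, ordination,
differential abundance, per-amplicon phylogenies — operates on those bins.

## The method

**Two-round annotation binning.** For each amplicon, alignment hits with
e-value < 10⁻¹⁰ are retained, then filtered at ≥ 99% identity and ≥ 99%
query coverage. The hit with the highest bit score names the annotation;
for ties (identical bit score after rounding to tabular precision) the
annotation is the lowest common taxon of all tied species. Each distinct
annotation founds one OTU. A second round re-examines unannotated reads at
≥ 98% / ≥ 98% but may only place them into OTUs whose supporting accessions
already exist — no new OTU construction. OTUs present in fewer than four
replicates, or with max-sample : total count ≥ 0.75, are flagged and
removed, and only OTUs with > 10 total normalized counts are tested.

**Community statistics.** Six alpha-diversity indices (observed, Chao1
`S + F₁(F₁−1)/(2(F₂+1))`, Shannon `−Σ pᵢ ln pᵢ`, Simpson `1−Σpᵢ²`, inverse
Simpson, Fisher's α solving `S = α ln(1 + N/α)`) with Welch t-tests between
treatments; Bray–Curtis distances `1 − 2Σmin(aᵢ,bᵢ)/(Σaᵢ+Σbᵢ)`; PCoA and
constrained analysis of principal coordinates (CAP); PERMANOVA with
`p = (1 + #{F* ≥ F}) / (1 + n_perm)`.

**Differential abundance.** Per-OTU negative-binomial model
(`Var = μ + αμ²`) with median-of-ratios size factors, a moments + trend +
geometric-shrinkage dispersion estimate (with a small-sample χ² recentring),
and a Wald test of `log₂(μ_b/μ_a)` per treatment pair with per-contrast
Benjamini–Hochberg control. OTUs detected in only one condition are
reported as ±INF fold change with a pseudo-mean-floored test.

**Sub-OTU unpacking and trees.** Within an OTU, distinct amplicon sequences
that share no supporting accession are split into sub-OTUs (connected
components of the sharing relation); representatives plus reference "spike"
sequences go into Jukes–Cantor (`d = −¾ ln(1 − 4p/3)`) neighbor-joining
trees with column-bootstrap support, exported as Newick.

A seeded synthetic-community generator (taxonomy, reference fragments,
error-bearing reads, BLAST-style hit tables, NB count experiments) provides
ground truth for every stage.

## Worked example

```r
library(ambin)
cfg <- run_config(out_dir = tempfile("run"), seed = 7, n_species = 30,
                  reads_per_sample = 500, permutations = 999)
mf <- run_pipeline(cfg)
print(mf)
#> ambin run: 7 stages completed (reference, amplicons, hits, binning,
#>   filtering, stats, differential_abundance)
#>   29 OTUs constructed, 29 retained; 100% of reads binned
#> PERMANOVA: pseudo-F = 14.251, R2 = 0.792, p = 0.001 (999 permutations)
```

The run simulates a 5-treatment × 4-block design (control and soils spiked
with Pb, Zn, Cu, or all three metals), 500 reads per sample rarefied to
450, and executes the full analysis. 30 species collapse to 29 OTUs because
one genus carries species with identical fragments, which tie at equal bit
score and are binned at genus level — exactly the ambiguity the
lowest-common-taxon rule handles.

```r
mf$rates
#>   n_round1 n_round2 n_binned n_total pct_round1 pct_binned
#> 1     8807      193     9000    9000       97.9        100
```

With a 0.4% per-site error rate, 97.9% of reads annotate at the strict
99/99 thresholds and round 2 rescues the remaining 2.1% into established
OTUs (none create new ones). Differential abundance across all 10 treatment
pairs:

```r
glance(mf$da$results)
#>   total_instances distinct_da_otus
#> 1              25                4
head(mf$stats$diversity, 3)
#>   sample_id  observed chao1 shannon simpson inv_simpson fisher_alpha
#> 1 control_b1       28    28    2.79   0.914        11.7         6.61
#> 2 control_b2       28    31    2.73   0.911        11.3         6.61
#> 3 control_b3       28    28    2.76   0.911        11.2         6.61
```

Here 25 pairwise DA instances concentrate in 4 responder OTUs (the built-in
abundance profile perturbs a 30% subset of species under Zn, Cu and the
three-metal mix, and leaves Pb neutral). Sub-OTUs and a spiked tree:

```r
subs <- unpack_all_otus(mf$binning, mf$reads)
head(subs[c("subotu_id", "n_reads")], 3)
#>   subotu_id             n_reads
#> 1 Genus01_sp1|s001 seq1     903
#> 2 Genus02_sp3|s003 seq1      46
#> 3 Genus02_sp4|s004 seq1      63
spikes <- setNames(mf$reference$refs$sequence[1:2], c("Spike1", "Spike2"))
tree <- spike_and_tree(subs[1:4, ], spikes, n_boot = 1000, seed = 1)
```

`autoplot()` methods draw the CAP ordination with dispersion ellipses and
per-contrast fold-change panels; `plot_alpha_diversity()` draws the
box plots.

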