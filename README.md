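# microscape

Multiscale diversity, nestedness and environment specificity for amplicon
surveys.

`microscape` is an R (Bioconductor-style, S4) implementation of the
analysis pipeline used by large multi-study 16S rRNA surveys whose samples
are organised by a structured environment ontology (EMPO: free-living vs
host-associated; saline/non-saline or animal/plant; ~17 fine
environments). It is aimed at microbial ecologists who want the survey's
statistical machinery — not its raw data — as tested, reusable functions,
together with a truth-known synthetic world generator for validating every
stage.

## What it computes

* **Data model** — a samples × tag-sequences (ASV) count table
  (`ObservationTable`, extending `SummarizedExperiment`), QIIME-style
  mapping files with EMPO validation, newick phylogenies (via `ape`),
  ranked taxonomies, and the survey's filtering rules: features with
  ≥ 25 reads total, samples with ≥ 1,000 (QC) or ≥ 5,000 (analysis)
  observations, rarefaction without replacement, and
  environment/study-balanced subsetting.
* **Alpha diversity** — observed richness, Shannon *H = −Σ p log₂ p*,
  Chao1 *S + F₁²/(2F₂)*, and Faith's PD (rooted convention).
* **Beta diversity** — unweighted UniFrac
  (unique branch length / branch length in either community), weighted
  UniFrac *Σ_b l_b |p_A(b) − p_B(b)|* (normalization optional), a
  block-decomposed computation equal to the full one to 1e-12, classical
  PCoA, and PERMANOVA.
* **Nestedness** — the NODF statistic on [0, 1]: for row (or column)
  pairs with strictly decreasing marginal totals, the mean fraction of
  the sparser vector's presences contained in the denser one's. Null
  models shuffle presences with fixed rows or fixed columns; for the
  matching axis the null overlap of a pair with fills *kᵢ > kⱼ* over *R*
  categories is Hypergeometric(*R*, *kᵢ*, *kⱼ*), giving analytic moments,
  SES = (obs − mean)/sd, and Wald p values, with an empirical null as the
  fallback authority.
* **Environment specificity** — per-tag appearance distributions *W*
  across level-3 environments, Shannon entropy in bits, count-pooled
  cluster profiles over taxonomic groups and phylogenetic subtrees,
  permutation nulls (shuffled taxonomy or tip placement), sliding-window
  entropy-vs-branch-length profiles.
* **Richness envelopes** — per-bin upper percentiles (99th; 100 pH bins,
  120 temperature bins) fit by multi-start Nelder–Mead to Laplace
  *S₀ exp(−|x−μ|/b)* and Gaussian *S₀ exp(−(x−μ)²/2σ²)* curves, compared
  by SSE.
* **Effect sizes (mdFDR)** — quartile-binned predictors (categories
  ≥ 0.3 % of samples), pairwise Mann–Whitney (alpha) or PERMANOVA (beta),
  a pooled p per predictor (Simes by default; Fisher/Stouffer optional),
  Benjamini–Hochberg across predictors, then per-pair retention at
  *Rα/(m qᵢ)* with pooled-SD standardized mean differences.
* **Community metrics** — abundance-weighted average 16S copy number
  (raw sum / copy-number-normalized sum; samples > 10,000 reads),
  prevalence and prevalence-vs-depth profiles, and per-tag "trading card"
  summaries with the top-10 / entropy < 1 / proportion ≥ 25 % /
  ≥ 1,000-observation selection rule.
* **Synthetic worlds** — `generateWorld()` plants an EMPO hierarchy,
  rank-based nested presence structure (strength ν), tip-level
  environment specificity under cosmopolitan genera (concentration κ),
  Laplace richness envelopes (pH mode 7, temperature mode 10 °C),
  two-regime copy numbers (animal 3.4, others 2.2) and lognormal depths,
  and records the full truth for parameter-recovery tests.

## Worked example

```r
library(microscape)

world <- generateWorld(worldConfig(nSamples = 120, nTags = 200, seed = 1))
world$table
#> ObservationTable: 200 features x 120 samples, 4,042,445 total counts

tab   <- rarefy(qcFilterSamples(world$table, 5000), 5000, seed = 1)
alpha <- alphaMetrics(tab, world$tree)
head(as.data.frame(alpha), 3)
#>        observed_features shannon chao1 faith_pd
#> S00001                43    4.08  44.5    15.35
#> S00002                34    3.42  42.0    15.38
#> S00003                 7    1.29   7.0     3.86

nodfTest(preparePresence(collapseByTaxonomy(tab, world$taxonomy, "phylum")),
         nNull = 199, seed = 2)
#> NODF cols = 0.8117 (rows 0.8757, cols 0.8117) | null equiprobable_rows_fixed_cols
#>   null mean 0.6647, sd 0.002254 (analytic), SES 65.23, p_analytic 0, p_empirical 0.005

td <- tagEnvironmentDistribution(tab, world$metadata, minSamples = 10)
entropyByTaxonomicLevel(td, world$taxonomy, minTags = 3)
#>    level n_groups mean_entropy
#> 1 phylum       10         2.71
#> ...
#> 6    tag      100         2.06

summary(acn(world$table, world$copyNumbers))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>    2.02    2.17    2.36    2.63    3.00    3.97
```

Reading the output: the phylum-level presence matrix is strongly nested
(NODF 0.81 against a null mean of 0.66, SES ≫ 2) because the generator
plants rank-based nesting; per-tag environment entropy (2.06 bits) sits
well below the entropy of taxonomic groupings (~2.6–2.7 bits), the
signature of specificity concentrated at the tips; and the per-sample
average 16S copy number spans the two planted regimes near 2.2
(free-living/plant) and 3.4 (animal).

`runPipeline()` chains all stages (simulated or file inputs) and writes
flat TSVs plus a manifest; `inst/scripts/run-pipeline.R` is a thin
command-line wrapper around it.

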