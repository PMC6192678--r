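---
title: "Methods and design notes for microscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for microscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`microscape` implements the statistical machinery of a large multi-study
16S rRNA amplicon meta-analysis organised by a structured environment
ontology (EMPO). This vignette is the package's own account of the models
it fits, the parameters that matter, the synthetic data it validates
itself on, and the design choices that were genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

# The data model and preprocessing rules

The central object is an `ObservationTable`, a sparse non-negative
integer matrix of tag sequences (exact amplicon sequence variants used as
stable feature identifiers) by samples, carried inside a
`SummarizedExperiment`. Sample metadata is a `DataFrame` subclass whose
loader maps the mapping-file missing tokens (`""`, `NA`, `na`,
`not applicable`, `Unknown`) to `NA` and validates the EMPO structure:
level 2 must be Saline/Non-saline exactly under Free-living and
Animal/Plant exactly under Host-associated, pH must lie in [0, 14] and
latitude in [−90, 90]. Because the upstream archives do not say whether
offending samples were dropped or corrected, violations are **reported
and retained** (`validationIssues()`); the analyst decides.

Preprocessing follows the survey's conventions: tag sequences with fewer
than 25 reads total are removed; quality control keeps samples with at
least 1,000 observations and analysis subsets require 5,000; rarefaction
draws reads without replacement to exactly the target depth and drops
(never pads) shallower samples. Balanced subsets allocate a quota
round-robin across level-3 environments and, within each environment,
across studies, in lexicographic order so remainders land deterministically
on the earliest categories; an exhausted category hands its surplus to the
rest. Collapsing by taxonomy sums counts over full lineage prefixes, with
an explicit `unassigned` row so the grand total is conserved.

# Diversity

Shannon diversity and all entropies in the package use log base 2
(bits), matching the convention of the toolchain this pipeline mirrors.
Chao1 uses the classic form $S + F_1^2/(2F_2)$ and switches to the
bias-corrected $S + F_1(F_1-1)/(2(F_2+1))$ only when there are no
doubletons. Faith's PD uses the **rooted** convention — the path from the
root to the observed tips is included — again matching the toolchain;
users comparing against unrooted-PD implementations should expect a
constant offset per tree. These two conventions are deliberately
documented because implementations in the wild differ.

Unweighted UniFrac is unique branch length over branch length present in
either community; weighted UniFrac is $\sum_b l_b\,|p_A(b)-p_B(b)|$ with
subtree relative abundances $p$, and the normalized variant divides by
$\sum_b l_b\,(p_A(b)+p_B(b))$. Survey practice is split on whether
weighted distances are normalized; the common default (unnormalized) is
used, with the flag exposed.

The block-decomposed UniFrac exists because the all-pairs computation
holds a nodes × samples structure in memory. Each block pair is computed
on the tree pruned to the block's observed features, **without collapsing
single-child nodes**: branches from a pruned clade to the original root
are shared by every sample in the block and still belong in the
denominators. With that rule, pruning removes only branches that
contribute zero to every within-block term, so the blocked result equals
the full one to numerical precision (asserted at 1e-12); only the
decomposition contract is in scope, not a parallel runtime.

PCoA double-centres $-\tfrac12 d^2$ and eigendecomposes. Negative
eigenvalues (non-Euclidean inputs) are reported, excluded from
coordinates, and excluded from the proportion-explained denominator — no
Cailliez or Lingoes correction, favouring transparency over adjustment.
PERMANOVA computes the Anderson pseudo-F directly from the distance
matrix and uses the permutation p value $(1 + \#\{F_\pi \ge F\})/(1+n_\pi)$.

# Nestedness

NODF is reported on [0, 1] (the 0–100 literature scale is a flag). For
each ordered same-axis pair whose marginal totals strictly decrease, the
paired term is the shared presences divided by the smaller marginal;
equal-marginal pairs contribute zero (the decreasing-fill condition of
the canonical definition). One practical consequence, visible in the
tests: even a structurally perfectly nested matrix scores below 1
wherever marginals tie, so exact-1 assertions are made on untied
submatrices.

Two null models are provided — fixed rows/equiprobable columns and
equiprobable rows/fixed columns — and the fixed-columns model is the
default, as it is the one consistent with rarefied tables. Under it, each
column's presences are a uniform draw without replacement among the $R$
rows, independently across columns, so the overlap of a column pair with
fills $k_i > k_j$ is $\mathrm{Hypergeometric}(R, k_i, k_j)$: the paired
term has mean $k_i/R$ and variance
$k_j \frac{k_i}{R}(1-\frac{k_i}{R})\frac{R-k_j}{R-1} / k_j^2$. For the
variance of the statistic we originally planned a cross-pair independence
approximation, but the approximation turns out to be exact: writing the
overlap as $O_{ij} = \sum_r X_{ri}X_{rj}$ with columns independent, the
cross moments of any two pairs sharing a column factorise
($E[O_{ij}O_{il}] = k_i^2 k_j k_l / R^2 = E[O_{ij}]E[O_{il}]$, and
likewise when the shared column is the smaller one), so all pairwise
covariances vanish and the statistic's null variance is exactly the sum
of paired variances over the squared pair count. The test suite checks
both moments against 10,000-shuffle Monte-Carlo intervals. The row
component under fixed columns has no hypergeometric form; inference for
it (and for the overall statistic) falls back to empirical moments, and
the empirical null remains the fallback authority throughout.

SES is $(\mathrm{obs}-\mu_0)/\sigma_0$ with a two-sided Wald p; the
empirical p is one-sided toward nestedness,
$(1+\#\{\mathrm{null} \ge \mathrm{obs}\})/(1+n)$. When the null variance
is zero and the observation is off the mean, the p value is reported at
the $1/(1+n)$ sentinel floor.

# Environment specificity

A tag's environment distribution counts **appearances** — presence in a
sample, not abundance — per level-3 environment, normalized to a vector
$W$; a count of 1 and a count of 10,000 contribute equally. This follows
the appearance-based wording of the design and the balanced-subset logic
(the caller supplies an environment-balanced sample set, mirroring the
2,000-sample even-representation design); an abundance-weighted variant
sits behind a flag. Tags must appear in at least 10 samples; groups
(taxonomic or subtree) need at least 20 member tags in survey-scale data
(tests and the acceptance script use smaller worlds and smaller
thresholds, stated where used).

Whether the cluster vector pools member counts or averages member $W$s
is a genuinely open choice; both are implemented and
**count-pooling is the default**, because it is well defined when members
differ in sample support and it makes pooled entropy obey the concavity
bound (pooled entropy ≥ support-weighted mean of member entropies), which
the suite asserts. Per-level summaries weight group entropies by member
counts. Permutation nulls shuffle the tag→lineage (or tag→tip)
assignment **among the analyzed tags only** — tags that survived the
appearance threshold — so group sizes after filtering are preserved by
construction and the tag-level mean is invariant, which is exactly what
makes the null informative about grouping rather than about inclusion.

Subtree profiles pair each internal node's pooled entropy with the
maximum tip-to-tip path length inside its clade; the taxonomic levels are
placed on that axis by the mean clade span of their groups, and the
conventional 97% identity line sits at 0.06 substitutions/site (twice
the 3% divergence). Sliding windows over the profile report the mean and
the 20th/80th percentiles on an even grid.

# Richness envelopes

The upper envelope of richness against a covariate is the per-bin 99th
percentile (equal-width bins; 100 for pH, 120 for temperature), with the
type-7 linear-interpolation percentile stated explicitly because
percentile conventions differ. Bins with fewer than 5 points are dropped:
a 99th percentile of a handful of points is degenerate; the threshold is
ours, no published convention existing. Both envelope families —
Laplace $S_0 e^{-|x-\mu|/b}$ and Gaussian $S_0 e^{-(x-\mu)^2/2\sigma^2}$
— are least-squares fit by multi-start Nelder–Mead over
$(\mu, \log b, \log S_0)$, since the $|x-\mu|$ kink breaks gradient
methods; initialisation uses the argmax bin, the max percentile and the
half-width at $S_0/e$, with a small restart grid. Equal parameter counts
make the SSE comparison AIC-equivalent, so the winner is simply the lower
SSE. Which sample set to fit on (all samples, or an environment subset)
is left to the caller.

# mdFDR effect sizes

Numeric predictors are quartile-binned (boundary values fall in the lower
bin); categories must cover 0.3% of samples (75 of 25,000). Pairwise
tests are Mann–Whitney for alpha diversity — exact null when both sides
are small and untied, normal approximation with tie correction otherwise,
and no continuity correction so identical groups give p = 1 — and
PERMANOVA on the pair's submatrix for beta diversity.

Three design points were genuinely open:

* **Pooling.** The pooled per-predictor p value defaults to the Simes
  combination $\min_k (q\,p_{(k)}/k)$ rather than Fisher's chi-square.
  Pairwise comparisons within a predictor share groups and are positively
  dependent; Fisher (and Stouffer) assume independence and become
  anti-conservative there — the package's own global-null simulation
  exhibits the inflation — while Simes remains valid under this
  dependence and matches the screening logic of published
  multi-dimensional pairwise FDR procedures. Fisher and Stouffer remain
  available behind `poolMethod`.
* **Retention direction.** Written descriptions of this procedure
  sometimes state the pair-retention inequality as "greater than
  $(R/m \times q_i)\alpha$", which contradicts the multiplicity logic
  (it would keep the *least* significant pairs); pairs are retained at
  $p \le R\alpha/(m q_i)$, the Bonferroni-like reading, and this choice
  is documented rather than hidden.
* **Beta effect size.** The standardized mean difference needs univariate
  per-sample values; for distances the package uses each sample's
  distance to its own group centroid in full PCoA space; the choice is
  ours and is documented as such.

Benjamini–Hochberg across the $m$ pooled p values defines the significant
set of size $R$; lowering $\alpha$ never increases $R$ (asserted). Effect
sizes are $|\bar x_1 - \bar x_2|/s_{pooled}$ with the usual pooled SD; a
zero pooled SD with unequal means reports an infinite sentinel.

# Community metrics

The average community 16S copy number of a sample is its raw count total
divided by its copy-number-normalized total — algebraically a
count-weighted **harmonic** mean of member copy numbers; samples need
more than 10,000 reads. Copy numbers are a user-supplied table; nearest-
genome inference is out of scope. Prevalence is the fraction of samples
containing a feature; the depth profile rarefies at each depth with three
replicate rarefactions and counts features absent at a depth as zeros
(the alternative — dropping them — would mechanically inflate shallow
depths). Trading-card selection follows the published rule: top-10 by
prevalence or abundance, or the most abundant tag of an environment with
distribution entropy < 1 bit, dominant-environment proportion ≥ 25% and
at least 1,000 observations; rank ties break lexicographically by tag id
for determinism.

# The synthetic world

There is no canonical generative model for such surveys; every generator
choice is ours and is recorded here. The generator exists to give each
statistic a truth-known surface, not to simulate sequencing physics — no
chimeras, primer bias or error profiles.

* **Environments.** `nEnvironmentsL3` (default 8) level-3 environments
  are assigned round-robin to the four level-2 branches; each has
  `nStudiesPerEnv` (2) studies.
* **Tree and taxonomy.** A Yule-type random topology with exponential
  branch lengths; ranks are clades cut at decreasing fractions of the
  tree diameter (0.55, 0.40, 0.28, 0.16, 0.08 for phylum…genus). The
  fractions were chosen so a 400-tip world yields on the order of 15–20
  phyla and 200+ genera — coarse cuts with only a handful of phyla make
  most samples contain *every* phylum, and the tied fills then suppress
  phylum-level NODF below class-level for an artefactual reason real
  surveys (hundreds of phyla) do not exhibit.
* **Nestedness** (ν, default 0.6): a sample of planted richness $S$
  takes $\nu S$ tags from the top of the global prevalence ranking and
  fills the rest by weighted draw; ν = 1 with `noise = FALSE` yields an
  exactly nested presence matrix.
* **Specificity** (κ, default 3): each genus draws a pool of half the
  environments and each member tag a home within the pool, so genus
  spread is broad while tips are narrow; a tag's odds of filling a
  non-nested slot, and its abundance weight, are multiplied by
  $e^\kappa$ at home. κ = 0 gives uniform distributions in expectation.
* **Richness envelopes.** Free-living non-saline samples carry pH
  (uniform on [2, 12]); free-living saline samples carry temperature
  (uniform on [−2, 40] °C) — mirroring real surveys, where the two
  covariates are measured on largely disjoint sample sets; host-associated
  samples have a flat cap (80). The richness bound is the Laplace
  envelope (pH mode 7, scale 2; temperature mode 10 °C, scale 8;
  amplitude 150) and realized richness is uniform on [1, bound], so the
  bound is never exceeded — exactly, by construction.
* **Copy numbers.** Per-branch targets (animal 3.4, others 2.2) are the
  community-ACN values the generator must reproduce. Because ACN is a
  count-weighted harmonic mean and every community carries a predictable
  share of cosmopolitan reads from other regimes, the per-branch
  tag-level harmonic means are obtained by solving a small linear system
  in inverse copy numbers (the expected matched-read share follows from
  ν, κ and the environment count) before drawing each tag from a
  floor/ceiling two-point integer mixture in [1, 15] with that harmonic
  mean.
* **Depths.** Lognormal (meanlog log 30,000, sdlog 0.5) floored at
  2,000; counts are multinomial over included tags with lognormal
  relative abundances.

What passing tests show — and what they do not: the suite demonstrates
that the estimators recover *planted* structure of these specific kinds
at desk scale (hundreds of samples, hundreds of tags), that the analytic
nulls match brute-force and Monte-Carlo oracles, and that the pipeline is
bit-reproducible under a seed. It does not show that real communities
are nested, specific, or Laplace-bounded, and it cannot detect biases
the generator does not model (compositionality of relative abundances,
contamination, batch effects, phylogenetic signal in abundances).

# Problem sizes and numerical choices

Tests and the acceptance script size their simulations for a desk-class
single-CPU run: oracle comparisons on 100 matrices up to 20 × 20;
null-moment checks on 20 15 × 15 matrices with 10,000 shuffles each
(inside a 99% *simultaneous* Monte-Carlo band, Bonferroni-adjusted across
the 40 moment comparisons — per-comparison 99% bands would be expected to
fail somewhere among 40 checks even for exact moments); calibration and
recovery runs with 120–200 replicates; synthetic worlds of 100–500
samples (2,000 for envelope recovery). These sizes are the package's
choices, stated so others can scale them up.

Other numerical conventions collected in one place: seeds enter through
`withr::with_seed` so library calls never disturb the caller's RNG
stream, and derived child seeds stay below $2^{31}-1$; stable sorts with
ties kept in input order everywhere a sort is internal (NODF
preparation, balanced subsetting); `type = 7` percentiles; Nelder–Mead
with a restart grid for the envelope fits; p = 0 inputs to pooling are
clamped to the machine minimum with a notice; degenerate inputs
(all-zero tables, single-category axes, empty partitions) error or report
rather than silently proceed.

# Known limitations

The blocked UniFrac implements the decomposition contract, not the
map-reduce runtime. The analytic NODF moments cover the null-matching
axis only. Entropy analyses treat environments as exchangeable
categories; no abundance weighting or hierarchy-aware distance is used by
default. The mdFDR beta effect size depends on the PCoA embedding and is
not comparable across distance metrics. The synthetic generator's
realism limits are listed above; in particular its per-sample covariate
regime (pH *or* temperature) means joint covariate analyses have no
truth surface. Specificity statistics are distributional descriptions
only; they imply nothing about adaptation or causality.
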