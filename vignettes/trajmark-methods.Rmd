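---
title: "trajmark: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trajmark: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmark)
```

# What the package computes

trajmark analyses a bulk RNA-seq time course over five perinatal
developmental stages (E15, P1, P7, P15, P30) together with a labeled
single-cell UMI data set (cells annotated with one of 11 cell types and
one of 47 nested subtypes), and produces four linked results:

1. **Temporal clusters of the bulk transcriptome.** Every pair of stages
   is compared with a negative-binomial Wald test; transcripts with
   $|Z| \ge 5$ in at least two of the ten comparisons are *developmentally
   regulated*. Their signed Z-scores form an $m \times 10$ matrix that is
   discretized per comparison into five levels at the 10th, 30th, 70th and
   90th percentiles. The number of *real trajectories* — distinct level
   tuples collecting at least a fraction `min_el` (default 1%) of the
   transcripts — is the estimated cluster number $k$; the original (not
   discretized) Z matrix is then partitioned by k-means with $k$ clusters.
   Each cluster is classified as decreasing, increasing, or transient from
   its E15-normalized mean stage profile.
2. **Cell-type and subtype markers** from the single-cell data, by voting
   over all $\binom{47}{2} = 1081$ pairwise subtype comparisons: a subtype
   marker must win (adjusted $p<0.05$, up-regulated) at least
   $(s-1)-2$ of its $s-1$ contests; a cell-type marker must be
   homogeneous across the type's subtypes (all internal comparisons
   non-significant) and up-regulated against every other type. Genes
   marking several subtypes are assigned to the subtype of highest mean
   normalized expression.
3. **Enrichment integration**: hypergeometric over/under-representation of
   marker sets in temporal clusters (Bonferroni), the term-by-cell-type
   interaction matrix of a chosen cluster (both tails, matrix-wide
   Bonferroni, non-marker genes as a depletion control), and the splitting
   of any annotated gene set by cluster direction.
4. **Differentiation-driver prediction**: the exact intersection of each
   type's exclusive markers with the decreasing clusters — genes that mark
   a single adult cell population but are silenced during development.

A synthetic-data module emulates both modalities with planted ground
truth so that each stage, and the whole pipeline, is testable offline.

# The differential-expression core

The DE engine is a deliberately small stand-in for a full NB GLM
framework, with an identical interface contract (log2 fold change,
BH-adjusted p, signed Z), so that externally computed tables with the
same schema can be dropped in at the TSV level.

For a two-group comparison it computes size-factor-normalized group means
$\hat\mu_A, \hat\mu_B$, a per-gene moment estimate of the NB dispersion
$\alpha$ (variance $\mu + \alpha\mu^2$) pooled over both groups, and the
delta-method Wald statistic
$W = (\ln\hat\mu_B - \ln\hat\mu_A) / \sqrt{\widehat{Var}}$, with a
two-sided normal p-value and BH adjustment within the comparison.

**Dispersion information sharing.** With three replicates per stage the
raw per-gene moment estimate is far too noisy for a normal reference:
measured type-I error was ~12% at a nominal 5%. A t reference would fix
calibration but its heavy tails make adjusted p-values of $3\cdot10^{-7}$
(the $Z=5$ selection threshold) unreachable at $n=3$, which would empty
the selection. We therefore do what mainstream NB DE tools do: the
per-gene moment estimates are smoothed into a mean–dispersion trend
(means of expression-ranked bins, linear interpolation) and the Wald test
uses the fitted value. Measured type-I error is 5.2–5.5% at both $n=3$
and $n=10$ (within binomial 99% bounds). `dispersion = "gene"` restores
the raw per-gene estimator, and a numeric value supplies known
dispersions.

**Signed Z.** The conversion treats the adjusted p one-sidedly:
$Z = \Phi^{-1}(1-p)$ signed by the fold-change direction, so that an
adjusted p of $2.87\cdot10^{-7}$ maps to $Z = 5$; $|Z|$ is capped at 38
where the normal tail underflows double precision. Inside `nb_wald_test`
the quantile is floored at zero before signing, so that the sign of Z
always equals the sign of the fold change and $|Z|$ is monotone in the
adjusted p — for $p > 0.5$ the raw one-sided quantile would otherwise
flip sign.

**Degenerate genes** are reported, not dropped: all-zero genes get
$p = 1$, $\log_2\mathrm{FC} = 0$ and flag `all_zero`; genes with fewer
than two nonzero samples are flagged `low_count` with $p = 1$. A 0.5
pseudocount enters the fold change only when a group mean is exactly
zero, preserving exact antisymmetry under group swap.

# Trajectory discretization choices

* **Percentile scope.** Cutpoints are computed per comparison column by
  default, because each comparison has its own Z scale; a global-matrix
  mode is available (`scope = "global"`).
* **Percentile definition.** Linear interpolation between order
  statistics (R's type 7), fixed for reproducibility.
* **Boundary ties.** Levels are assigned by half-open intervals closed on
  the left: a value exactly at a cutpoint takes the higher level. A
  constant column yields all-zero levels with a warning.
* **Direction-agnostic selection.** The "at least two comparisons" rule
  counts $|Z| \ge 5$ regardless of sign.
* **k-means.** Squared-Euclidean objective, k-means++ seeding, best of 50
  restarts by total within-cluster sum of squares, deterministic given
  the seed. Exact duplicate seed points are nudged by $10^{-6}$ noise to
  keep the underlying solver happy.
* **Direction classes.** A cluster is decreasing/increasing when
  $|\log_2(\mathrm{P30}/\mathrm{E15})| \ge t$ of its E15-normalized mean
  profile (default $t = 1$, i.e. a two-fold end-to-end change), transient
  otherwise. A 0.5 pseudocount on normalized means guards silent stages.

# The synthetic world, and what a green test does not establish

## Bulk time course

`simulate_bulk()` draws NB counts with per-gene baselines (log-normal on
the gene's geometric-mean expression), a planted temporal archetype per
gene, log-normal library-size jitter (sd 0.2), and NB dispersion 0.1 —
typical for tissue-level mouse RNA-seq across littermates. Gene-to-
archetype assignment is deterministic (largest remainder), so realized
proportions match the requested ones exactly.

The 13 default archetypes (4 decreasing, 4 increasing, 5 transient) are
the package's definition of "well-separated temporal patterns", and they
are *constructed*, not hand-waved. Recovering the planted cluster number
through adaptive percentile discretization imposes two requirements that
we solved exactly:

1. **Mass alignment.** In every one of the ten comparison columns, the
   archetype masses must group into blocks of 10/20/40/20/10% so that the
   percentile cutpoints fall *between* discretization classes — a cut
   landing inside a class splits it into two tuples that can both pass
   `min_el` and inflate $k$. The default archetypes are built from six
   mirror pairs plus one center archetype whose stage-level equality
   patterns form an exact cover: every column receives exactly 15% of
   flat mass per side plus the center, and the nonzero contrasts split
   2:4 units per side. This mirror structure is also why the composition
   is 4/4/5 rather than 5/4/4 over the direction classes: a mirror-pair
   design forces equal decreasing and increasing counts.
2. **Effective Z gaps.** The Wald Z of a contrast scales with the
   stage-pair fold but is compressed at low expression (the count term in
   the standard error). Adjacent classes at a percentile cut therefore
   need fold-change gaps large enough *after* compression; the default
   magnitudes (on a half-log2 grid, centered per archetype on the
   geometric mean so no stage drops to unmeasurable counts) keep every
   cut-adjacent gap at roughly 4 or more Z units. The narrow default
   baseline spread (sdlog 0.25) is part of this: it keeps significance
   comparable across the genes of a class.

With the default world, the estimated cluster number is 13 with
archetype/cluster ARI 1.0 across seeds. What this establishes is that
the pipeline's logic — selection, discretization, trajectory counting,
k-means — correctly recovers a signal *that satisfies its assumptions*.
It does not establish that a real transcriptome's temporal structure is
this clean: real archetype masses are not percentile-aligned, real genes
span five orders of expression, and real trajectory censuses have heavy
tails of near-threshold tuples, so the estimated $k$ on real data is a
data-dependent summary, not a recovered truth.

## Single-cell data

`simulate_sc()` draws sparse NB UMI counts (dispersion 0.5, mean depth
2000 with log-normal cell-depth jitter, log-normal gene abundances) over
a nested type/subtype structure (default 11 types / 47 subtypes matching
the granularity of the adult atlas the marker rules were designed for).
Planted type markers are raised `fold_change`-fold (default 8) in every
cell of the owning type, subtype markers only in the owning subtype.
`fold_change = 1` is allowed as an explicit null world (with a warning),
since the false-positive control of the voting rule is itself under
test; fold changes below 1 are a configuration error. The simulator does
not model doublets, ambient RNA, or batch effects, so marker
precision/recall here bounds only the statistical, not the technical,
error of the voting procedure.

## Gene sets

`simulate_genesets()` produces GMT-writable collections with a
controlled fraction of each planted term drawn from a chosen truth group
(`planted_overlap`), the remainder uniform from the universe, plus fully
random terms. Term sizes follow a log-normal law (median ~40).

# Enrichment and driver conventions

* **Universe.** All genes expressed in the bulk data (nonzero in at least
  two samples); configurable.
* **Families.** GO-like term enrichment uses Benjamini–Hochberg; all
  other enrichments use Bonferroni. For matrix-valued tests (marker sets
  x clusters; terms x cell types) Bonferroni spans the whole matrix —
  both tails counted for the interaction matrix — with per-family modes
  available.
* **Interaction matrix.** Restricted to the chosen cluster's genes; terms
  enter only if enriched in the cluster at Benjamini p < 0.01; output is
  the smaller-tail corrected p signed + for enrichment, − for depletion.
  The non-marker set (genes owned by no type) is the depletion control
  column.
* **Drivers.** Strictly the intersection of combined marker lists with
  decreasing-cluster genes — no expression floor or manual curation is
  added, so on real data the table is the raw candidate set. Driver
  profiles are five-stage RPKM scaled to their maximum.
* **Type/subtype precedence.** A gene passing both the type rule and the
  subtype vote (possible when a type has at most three subtypes, since
  the vote forgives two losses) is catalogued once, at the type level.

# Numerical and reproducibility notes

* All randomness flows from a single root seed; sub-seeds are derived
  arithmetically and kept below $2^{31}$. `with_seed()` restores the
  caller's RNG state, so library calls do not perturb user code.
* Size factors are median-of-ratios against per-gene geometric means,
  normalized to geometric mean 1 (factors are defined up to a constant;
  ratios are exactly scale-equivariant). A sparse fallback (geometric
  means over nonzero entries) covers UMI matrices where no gene is
  positive in every cell.
* Ties in the multiple-marker resolution go to the first subtype in
  label order, with a warning.
* `run_all()` writes every artifact as TSV/GMT and a JSON manifest with
  MD5 checksums; re-running with the same config and seed reproduces the
  checksums bit-for-bit. The manifest is written atomically (temp file +
  rename).
* Config files are flat `key: value` text (YAML-compatible subset); the
  CLI returns exit status 2 for usage/validation errors and 1 for
  runtime failures instead of aborting the session.

# Known limitations

* The DE stand-in has no shrinkage of fold changes, no covariates, and
  no outlier handling; its p-values at extreme tails rely on the normal
  approximation of the Wald statistic.
* Library-size (total-count) normalization of the single-cell matrix is
  compositional: with few genes or very dominant markers it can induce
  spurious shifts. At realistic gene counts the effect is negligible, but
  toy worlds below a few hundred genes should be interpreted with care.
* The trajectory-count estimator $\hat k$ is a census statistic; its
  variance on data that violate the separation assumptions is not
  characterized here.
* Marker rules take the cell labels as given; re-clustering of cells is
  out of scope.
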