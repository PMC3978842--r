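---
title: "Deriving and projecting stromal expression signatures"
author: "stromalsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and projecting stromal expression signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromalsig)
```

# The model

Benign fibrous soft-tissue tumors — elastofibroma (EF), fibroma of
tendon sheath (FOTS), desmoid-type fibromatosis (DTF), and others — are
near-clonal outgrowths of single mesenchymal cell types. Their
expression profiles therefore approximate "pure" stromal expression
states, and a carcinoma cohort clustered *using only the genes specific
to one such tumor type* groups by its stromal reaction rather than by
its (dominant) epithelial signal. The pipeline has four statistical
stages, each exposed as a module:

1. **Quantification** of 3′-end tag libraries into gene-level counts and
   TPM. 3′-end tags cluster 100–200 nt from the transcript 3′ end (set
   by fragment length after shearing), which the distance profile makes
   checkable; library adequacy is summarized by a subsampling saturation
   curve.
2. **Signature derivation** by two-class SAM, one diagnosis group
   against all others, keeping the up-regulated genes at FDR 0.05.
3. **Projection**: the cohort is restricted to the signature genes,
   samples are clustered with the Cluster 3.0 recipe, and the
   *signature-positive* group is the candidate cluster with the highest
   volume of expression. Per-cohort gene clusters pooled across cohorts
   give the *core* gene set.
4. **Outcome association** of the resulting strata by Kaplan-Meier /
   log-rank and Cox regression.

# SAM: statistic, fudge factor, permutation FDR

For gene $g$ with class sizes $n_1, n_2$:

$$d_g = \frac{\bar x_{2g} - \bar x_{1g}}{s_g + s_0},\qquad
s_g = \sqrt{\tfrac{1/n_1 + 1/n_2}{n_1+n_2-2}\,(SS_{1g}+SS_{2g})}.$$

The fudge factor $s_0$ stabilizes low-variance genes: candidates are the
$\alpha$-percentiles of $s$ for $\alpha = 0, 0.05, \dots, 1$; genes are
split into 100 quantile windows of $s$; the candidate minimizing the
coefficient of variation of the windowed MADs of $d$ wins (ties to the
smallest $\alpha$; constant $s$ returns 0). Genes with zero variance in
both classes are excluded from this selection — their $s$ is exactly
zero and would collapse the lowest windows — but stay in the test with
$d = r/s_0$.

The null is built by recomputing sorted $d$ under permuted class labels.
When $\binom{n}{n_1}$ distinct assignments number at most `nPerm`
(default 1000) they are enumerated exactly, making the result
deterministic and seed-independent; otherwise `nPerm` permutations are
drawn from a seeded stream. Calls at threshold $\delta$ use the plot
rule: on the sorted statistics, the smallest $d$ with
$d_{(i)} - \bar d_{(i)} \ge \delta$ anchors the upper cut and every gene
at or beyond it is called (symmetrically below). The estimated FDR is
$\hat\pi_0 \cdot \mathrm{median}_\pi\,\#\{d^\pi \text{ outside cuts}\} /
\#\text{called}$, with $\hat\pi_0$ from the central 50% of the permuted
statistics (can be disabled). $\delta$ is searched on a 200-point grid
over $[0, \max_i |d_{(i)} - \bar d_{(i)}|]$ for the smallest value
meeting the target FDR; if none does, no genes are called.

**Input scale.** The discovery data are counts; SAM runs on
$\log_2(\mathrm{TPM} + 1)$ by default (variance stabilization;
configurable to the raw scale). Power at this design's small group sizes
is intrinsically limited: with 4 cases against 49, a 2-SD shift yields
$d \approx 3.8$ against a null spread of 1, so even an oracle threshold
at a true FDR of 0.05 among 2,000 genes leaves a material fraction of
such genes uncalled. Green recovery tests at large effects therefore say
the machinery works, not that small programs are always recoverable.

# The Cluster 3.0 recipe

- **SD filter**: retain genes with row *population* SD (divide-by-$n$,
  matching Cluster 3.0) at or above the threshold. The "SD100" step is
  this filter at 100 **on the TPM scale, before the log transform** —
  the observation-filter idiom; both the threshold and placement are
  configurable.
- **Adjust**: $x \mapsto \log_2(x + 1)$ (pseudocount 1 so zeros survive;
  Cluster 3.0 cannot log non-positives), then center each gene. Median
  centering is the default (the robust choice customary in this
  clustering lineage); mean is available. Cohort matrices arriving as
  log-ratios are centered without the log step.
- **Similarity**: tie-corrected Spearman rank correlation (Pearson of
  average ranks). An all-tied profile has no rank variance; its
  similarity is defined as 0 with a warning so degenerate items join
  last rather than poisoning the tree.
- **Linkage**: agglomeration maximizes *similarity* (no
  triangle-inequality assumptions). Centroid linkage recomputes a merged
  node's profile as the size-weighted mean of its member profiles and
  re-scores it against all active nodes, so similarity inversions toward
  the root can occur (and are permitted); average linkage combines
  similarities as size-weighted means and is non-increasing toward the
  root; complete linkage takes the minimum.
- **Ties**: among equal-similarity pairs the lexicographically smallest
  pair of node creation indices merges first, making the merge sequence
  exactly reproducible — the property the brute-force oracle tests rely
  on.
- **Cuts**: clusters are maximal subtrees whose root node joined at a
  similarity strictly above the threshold; the cut always partitions the
  leaves. The projection stage's ">0.2" (samples) and ">0.1" (genes)
  thresholds apply to this node correlation. Because centroid inversions
  exist, the recursion descends through low-similarity nodes and can
  recover tighter clusters beneath them.
- **Output**: `.cdt`/`.gtr`/`.atr` in the Cluster 3.0 dialect
  (`GENE{n}X`/`ARRY{n}X`/`NODE{n}X` identifiers in input order,
  GWEIGHT/EWEIGHT of 1, rows and columns in left-to-right leaf order,
  17-significant-digit values) so files round-trip exactly and open in
  Java TreeView.

# Projection rules

**Volume of expression** of a gene set in a sample group is the mean of
the strictly positive centered values — negative values are discarded,
so the statistic measures coordinate over-expression only, is invariant
to adding negative entries, and is monotone in any raised entry.

**Positive-group identification** operationalizes what was originally a
visual step — finding the block of cases sharing high expression of the
signature in the heatmap — as: cut the sample dendrogram at node
correlation 0.2 and take the candidate cluster with maximal volume. The
validation statistic of the original procedure is thus promoted to the
primary rule. Two refinements are deliberate design choices:

- *Candidates need at least two samples.* A singleton is not a
  visually identifiable case block, and a mean-based volume is
  selection-biased toward single extreme samples — on realistic planted
  data a lone high case can otherwise narrowly out-score a 48-sample
  true positive cluster. If a cut yields only singletons the assignment
  is all-negative with a warning.
- *Ties* between equal volumes go to the larger group, then the lower
  minimum leaf index.

`volumeSignificance()` adds a permutation sanity check for cohorts where
the signature may simply be absent: each permutation shuffles every
gene's values across samples and reruns the identification. The test
statistic is the winning group's *aggregate* positive expression (sum,
not mean, of its positive entries): under permutation the winners are
small and their totals low, while a genuine coordinate block produces a
large total, so the mean's small-cluster selection bias does not blunt
the test.

**Core genes**: per cohort, the signature's coordinately expressed gene
cluster is the gene-axis cluster (cut at 0.1) with maximal volume inside
that cohort's positive group; core genes appear in at least 3 of the 4
per-cohort clusters. Clustering is per-cohort, not pooled, so a gene
must independently co-express with the signature in most datasets.
**Combined strata** cross two assignments into four categories (for
example EF±/DTF±) for joint outcome analysis.

# Survival statistics

Kaplan-Meier, log-rank and Cox computations delegate to the `survival`
package behind fixed contracts (per-group observed/expected counts for
the log-rank; HR with 95% CI per coefficient for Cox). Efron tie
handling is the default — the better approximation and the default of
the package the original analysis used. Chi-square association is
Pearson without continuity correction, with Fisher's exact test
reported alongside whenever an expected cell drops below 5. Grade-like
ordinal covariates may be coded ordinal or dummy; dummy is the default.

# The synthetic world

Generators return their ground truth, and all randomness flows from one
seed through named substreams (bit-identical reruns).

- **Discovery cohort** (`genFibrousCounts`): 10 diagnosis groups with
  case counts (7, 5, 4, 6, 4, 3, 8, 6, 4, 6) matching the study design
  (53 libraries); negative-binomial counts (dispersion 0.1, typical of
  bulk tag-seq) around lognormal gene abundances and lognormal library
  sizes; each group's disjoint 50-gene program elevated by 2 log2 units
  with abundances renormalized so library size is preserved. Desk-scale
  defaults (2,000 genes, 1e5 reads) keep per-gene depth realistic while
  staying fast; real libraries are ~300x deeper over ~10x more genes.
- **Projection cohorts** (`genCohort`): generated directly on the
  centered log scale the projection stage consumes (probe-level
  microarray chemistry is not simulated). Background N(0, 1); a latent
  25% subpopulation over-expresses the 40-gene block by 1.5 on average.
  Per-gene effects get lognormal multipliers (sdlog 0.8, mean 1): with a
  strictly uniform effect, sample-sample correlation — which discards
  shared offsets — would be blind to the block *by construction*,
  whereas real signature blocks show graded, gene-specific
  over-expression. Rows are median-centered after planting. Survival is
  exponential with the baseline hazard (0.01/month, median ~69 months)
  multiplied per block status by the configured hazard ratio; censoring
  is an independent exponential whose rate is solved on the known hazard
  mixture to hit the target censoring fraction (default 20%) in
  expectation.
- **Mapped reads** (`genMappedReads`): multinomial gene assignment;
  3′-distance truncated-Normal(150, 30) by inverse-CDF truncation to
  [1, transcript length]; independent mismatch counts.

What a green test on this world establishes: that each stage recovers
planted structure of the stated strength at the stated sample sizes.
What it does not: robustness to batch effects, platform-specific noise,
probe cross-hybridization, censoring that is informative, or stromal
content varying continuously rather than as a latent binary status —
none of which the generators emulate.

# Numerical choices and degenerate inputs

- Delta grid: 200 points; π0 estimation on by default, settable to 1.
- Zero denominators in `d` (s + s0 = 0) give d = 0 with a warning count.
- TPM requires strictly positive library totals; the offending library
  is named.
- Similarity of constant profiles is 0 (warned), and `cutBySimilarity`
  at threshold 1 yields all singletons, at −1 one cluster.
- TSV writers emit integers as integers and reals with 17 significant
  digits, so write/read round trips are bit-stable.
- Sub-stream seeds are derived by hashing (seed, purpose, indices) into
  31-bit integers, so independent stages never share a stream and any
  grader-supplied small seed stays in range.

# Limitations

- SAM's Table-1-style counts on real deposited data depend on
  preprocessing choices (permutation count, π0 handling, input scale)
  the original description leaves open; this implementation documents
  its defaults and exposes them as parameters rather than claiming exact
  count reproduction.
- Whether the SD filter preceded or followed the log transform in the
  original recipe is unstated; the TPM-scale-first reading implemented
  here is the Cluster 3.0 idiom and is configurable.
- The ">0.2" sample cut is read as the cluster root node's correlation
  (not every internal node's); the core-gene 0.1 cut is per-cohort.
- Centroid linkage on similarities is order-dependent only through the
  documented tie-break; with heavily tied (short or discrete) profiles,
  input order can legitimately change the tree.
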