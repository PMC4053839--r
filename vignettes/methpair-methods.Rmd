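---
title: "Pairing methylation sites with regulated genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairing methylation sites with regulated genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpair)
```

## The problem and the model

Across a panel of cell types, the DNA methylation of a regulatory CpG tends
to fall as the expression of the gene it controls rises. `methpair` exploits
this to pair CpG sites with genes from methylation and expression data
alone. The engine is deliberately simple: each candidate (CpG, gene)
*sample* — the CpG's percent-methylation profile against the gene's log2
expression profile across the shared cell types — is summarised by four
features, the sign-gated magnitudes of its Pearson and Spearman
correlations:

\[
f = \bigl(\max(r, 0),\ \max(-r, 0),\ \max(\rho, 0),\ \max(-\rho, 0)\bigr),
\]

and scored by a linear model \(s = \langle w, f \rangle\). Encoding the
features as magnitudes (rather than signed values that would be collinear)
lets a single weight vector reward anti-correlated pairs and penalise
positively correlated ones; the reference weight vector shipped as
`published_model()` is positive on both "negative correlation" features and
negative on both "positive" ones, exactly that pattern.

Training is a ranking problem, not classification: for each gene we form a
*query* of its true promoter CpG samples plus a 50-fold excess of false
samples (the same promoter CpG pool paired with genes from other
chromosomes), and we want true samples ranked above false ones within each
query. `train_ranking_model()` therefore fits a linear pairwise ranking
machine — an L2-regularised squared hinge on the true-minus-false feature
differences within each query — and selects the regularisation constant by
10-fold cross-validation on a 4:1 training/test split of the *queries*,
maximising held-out mean average precision (MAP). MAP is computed exactly
(`mean_average_precision()`, ties broken by site id so results are
reproducible). A structured SVM that optimises MAP in its loss would be the
purist's choice; since the final artifact is just a 4-weight linear scorer,
the pairwise-hinge surrogate with MAP-based model selection reaches the
same family of solutions, is convex, and is deterministic under a seed. The
published constant can be swapped in at any point, which also makes
downstream scoring exactly reproducible independent of the optimiser.

Raw scores are normalised to \([0, 1]\) by an affine map over the scoring
universe (`normalize_scores()`), so a score is only meaningful relative to
the universe it was normalised over — promoter-query evaluation and the
genome-wide scan are two different universes, and the package never mixes
them.

Per-query significance uses the minimum rank \(X\) of a true sample among
\(n\) ranked samples with \(T\) true ones:
\(\Pr(X = x) = \binom{n-x}{T-1} / \binom{n}{T}\), with the p-value the
cumulative sum up to the observed rank (`query_pvalue()`); the
implementation is checked against exhaustive enumeration of all placements
for every \(n \le 12\).

### Evaluating promoter pairing

How often does the model pick the right promoter for a gene?
`evaluate_promoter_pairing()` pits each true sample against one uniformly
drawn false sample from its query, makes a prediction when the better of
the two normalised scores reaches the threshold, and scores a success when
the true member wins. This matched 1-vs-1 protocol was chosen (the
alternative, thresholding the full 1:50 query and asking whether the top
sample is true, is available as `protocol = "top"`) because its chance
level is *exactly* 50% by symmetry, which makes the null calibration of the
whole evaluation a testable property rather than a plausibility argument.

## Variable methylation sites

Only CpGs that actually vary across cell types carry pairing information.
`select_vms()` retains a site when its sample standard deviation across
cell types, computed after omitting outliers, strictly exceeds 5 percent
points (a site at exactly 5.0 is dropped). Outliers are flagged by the
iterative (modified) Thompson tau rule at two-sided alpha = 0.1%: the most
extreme value is removed if its deviation exceeds the Student-t-derived tau
bound, mean and SD are recomputed, and the process repeats. Outlier cells
are excluded only from the SD test; they remain in the matrix, because a
single aberrant cell type should not silence a genuinely variable site nor
contribute a spurious gradient. Sites with fewer than three usable values
are untestable and dropped. RRBS sites additionally need at least 10 reads
in at least 60% of the cell types (80% when building the training set,
where correlation quality matters more than coverage breadth); both
comparisons are inclusive. Array-type panels, which carry no read depths,
pass the coverage rule unconditionally. When RRBS and array measurements
coexist, replicate RRBS runs are averaged first and the two assays are then
averaged per (site, cell), each side filling the other's gaps
(`merge_assay_matrices()`).

## The genome scan

The promoter-trained model is applied unchanged to every VMS within a
gene's scanning interval — 1 Mb upstream of the transcription start,
through the gene body, to 1 Mb downstream of the transcription end, stored
as the strand-independent closed range `[min(tss, tes) - 1 Mb,
max(tss, tes) + 1 Mb]`. Boundary conventions are explicit and tested: a
site exactly 1 Mb away is *in*; a site exactly 5 kb from the associated
gene's TSS or any of its alternative promoters is *removed* by the
promoter-proximal filter ("within 5 kb" read as a closed bound); proximity
to other genes' promoters does not disqualify a pair. Distal survivors are
clustered into enhancer regions by single-linkage with a strict < 3 kb gap
(2,999 bp merges, 3,000 bp does not). A site overlapping several gene
intervals pairs with each gene — the pair universe deliberately exceeds the
site count.

Enrichment of high-scoring pairs in real gene intervals is measured against
an expression-shuffling null: each gene receives the expression vector of a
uniformly chosen gene from another chromosome (a cross-chromosome
permutation, drawn without replacement per round), the whole scan is
re-scored, and the real count of high scorers is compared with a normal
fit to the shuffled counts. The same shuffling scheme drives the
chromatin-state and TF-binding enrichments and the replication test, so all
nulls share one definition of "chance".

## Validation statistics

*Chromatin states*: a site carries a state when it overlaps an interval
with that label in at least one annotated cell type, and may carry several
states; per-state counts of high-scoring sites are compared with the
shuffled runs (fold and upper-tail normal p).

*TF binding*: the number of *distinct* factors bound at a site (a factor
peaking twice counts once), averaged across cell types; unmethylated
(mean methylation ≤ 20%) versus methylated (≥ 80%) high-scoring sites are
compared by a Wilcoxon rank-sum test. The 20/80 cuts are conventions —
nothing in the source analyses pins them — and are arguments, not
constants.

*5C agreement*: a pair "agrees" when its interaction read count strictly
exceeds the global mean; agreement fractions in high- versus lower-score
strata are compared binomially, and predicted enhancer–TSS read counts are
compared with the same enhancers' other-TSS records by Wilcoxon. Where
replicate 5C measurements per cell type exist they are averaged within
cell type first, then across cell types. Both statistics are invariant to
rescaling all reads.

*Replication*: previously predicted pairs are re-scored in an independent
panel; the chance expectation (mean ± SD, hence a two-sided normal p)
comes from re-scoring under shuffled gene-expression assignments. The
shuffled-assignment null was chosen because it reproduces the
"expected k ± s by chance" form of the original analysis without assuming
any parametric score distribution.

## Cancer contrasts

`delta_table()` computes, per pair and site class, `d_meth = cancer −
normal` in percent points (so +100 means fully unmethylated normal, fully
methylated cancer) and `d_expr` in log2 units, averaging over each panel's
cell types. `delta_correlation()` fits ordinary least squares of `d_expr`
on `d_meth` on the raw deltas — the kernel-smoothed density clouds used for
display in this kind of figure are presentation, not statistics, and are
excluded from the analysis path. Quadrant tests compare the frequency of
concordant changes (hypomethylated ≥ 25 points and upregulated ≥ 0.25
units, or the reverse) between enhancers and promoters by the pooled
two-proportion z test; gene-set overlaps across cancer types get
Monte-Carlo p-values from same-sized random sets. `methylation_shift_curve()`
bins sites by normal-cell methylation (equal-width bins over \([0, 100]\);
the binning is a package choice) and averages the cancer-minus-normal
shift per bin and site class; the count-weighted bin means reproduce the
overall mean shift exactly, which is asserted in the tests.

## The synthetic-data generator

`generate_panel()` emulates the statistical structure the analysis
assumes, with ground truth recorded so every downstream stage is testable:

- a panel of cell types (default 52, an RRBS-scale panel) with per-gene
  log2 expression means in 4–12 and cell-to-cell SDs in 0.8–2, the range
  of RMA-like units where correlation-based pairing is plausible;
- one true promoter CpG per gene in the strand-aware \([-500, +2000]\)
  window of the TSS, and true enhancer CpGs 10 kb–1 Mb away on the same
  chromosome, both with methylation anti-correlated with the gene's
  expression at a configurable target rho (default −0.8) under Gaussian
  measurement noise (default 10 points);
- variable background CpGs (cell-to-cell SD 15 points, enough to survive
  the VMS filter and act as honest decoys) independent of all expression;
- per-(site, cell) missingness (default 5%) and negative-binomial RRBS
  read depths (mean 30, size 5), so the coverage filter removes a tunable
  fraction.

The anti-monotone transform is a *linear* map of standardised expression,
`m = center − a·z + noise`, with baseline `center` varying by site
(35–65%, since real regulatory CpGs sit at different baseline levels) and
amplitude `a` calibrated in closed form against the configured noise so
the realised Pearson correlation approximates the target:
\(|\rho| = a / \sqrt{a^2 + \sigma^2}\). A monotone nonlinear (e.g.
logistic) transform was considered and rejected: it breaks the exact
noiseless limit (at `noise_sd = 0`, `rho = -1` every true pair must have
sample Pearson correlation exactly −1, a property the tests assert) and has
no closed-form noise calibration, while contributing nothing the Spearman
features can detect beyond the linear map.

`generate_cancer_pair()` applies a *deterministic* global drift,
`m → m + drift_strength · (50 − m)`: sites unmethylated in normal cells
gain methylation and methylated sites lose it, reproducing the global
normal-to-cancer trend (at strength 0.6 a 10%-methylated site gains 30
points). The map is a convex combination of `m` and 50, so it never leaves
the scale, and being linear and odd about 50 it gives the shift-versus-
normal curve a known closed form that the tests check exactly. Targeted
enhancers get an additional ±50-point shift, and their genes' expression
changes by `−enhancer_effect × Δmeth/100` (default effect 2 log2 units per
100 points) plus small noise — so the regression slope recoverable from
the contrast table is known (−0.02) and parameter recovery is a testable
claim. `generate_annotations()` plants the enhancer chromatin state
(`state4`) at true enhancers with configurable odds, TF-peak counts with
mean decreasing in methylation, and 5C reads 3-fold higher for true pairs.

What the generator does *not* emulate: genomic sequence context, CpG
islands and co-methylation of neighbouring sites, array probe chemistry
and its beta-value compression, cell-type phylogeny (cell types are
exchangeable draws), and non-Gaussian measurement noise — the noise
distribution of real methylation measurements is not characterised in the
source analyses, and Gaussian noise with clipping is an assumption. Tests
passing on these panels therefore show that the algorithms recover the
structure they assume, at the configured signal strengths; they do not
show that real cancer panels satisfy those assumptions.

## Numerical and statistical choices

- Correlations use pairwise-complete cells; a pair with fewer than 10
  complete cells gets the all-zero feature vector (uninformative, not an
  error), and zero-variance profiles get zero correlations. Spearman uses
  average ranks for ties.
- Ranking ties are broken by site id, so MAP and the evaluation protocol
  are deterministic.
- SDs use the sample (n − 1) denominator.
- All permutation machinery is seeded; identical seeds give byte-identical
  panels, splits, shuffles and fits.
- The type-I calibration tests run the enrichment permutation with 50
  shuffles on 60-gene panels at a score cutoff of 0.8: enough shuffles
  that a normal fit is not distorted by its own sampling error, enough
  genes that permutation counts are effectively exchangeable with the real
  count, and a cutoff at which null counts are in the tens, where a normal
  fit to a count distribution is defensible. With 10 shuffles (the
  operational default, matching the original analysis) the p-values are
  honest but coarse; they are meant for effect sizes like the planted
  panels', not for borderline calls.
- Problem sizes in the test suite and acceptance script (panels of
  20–52 cell types, 60–1,000 genes, a few thousand sites; 100–200 null
  panels for calibration) are the package's choice of smallest sizes at
  which each property is statistically decidable.

## Known limitations

- The linear 4-feature model cannot represent non-monotone
  methylation-expression relationships, by design.
- Scores are universe-relative; comparing scores across differently
  composed pair universes is meaningless, and the package offers no
  calibration across universes.
- The promoter-pairing success protocol is one of two defensible readings
  of the original evaluation (see `protocol` in
  `evaluate_promoter_pairing()`); the matched protocol is the default
  because its 50% null is exact.
- Normalisation of scoring universes with a single extreme outlier
  compresses all other scores; the package does not winsorise raw scores.
- Trans pairs (cross-chromosome, or beyond 1 Mb) are out of scope
  throughout.
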