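---
title: "Methods: age-correlation screening, regulon attrition, and permutation-FDR proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-correlation screening, regulon attrition, and permutation-FDR proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascage)
options(vascage.quiet = TRUE)
```

`vascage` implements two linked analysis workflows for studying
age-dependent remodelling of arterial tissue: a transcriptome-wide
age-correlation screen over multiple arteries with gene-panel ("regulon")
deviation statistics, and a label-free proteomics differential-expression
stage with permutation-based FDR control. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic cohorts used for validation do and do not establish about real
data.

## The age-correlation screen

For each gene in each artery, expression in transcripts per million (TPM)
is correlated with donor age by the Pearson product-moment coefficient
$R$, with the two-sided p-value from the exact transform
$t = R\sqrt{(n-2)/(1-R^2)}$ on $n-2$ degrees of freedom, plus the ordinary
least-squares slope (TPM/year) and the mean TPM. The trend is modelled
linearly on TPM scale — not log scale — because that is the scale on which
the screen's correlation operates. Benjamini–Hochberg q-values are
computed within each tissue only, never pooled across tissues, so that
each artery's q-values stand on their own cohort size. Genes with zero
expression variance (silent genes are common in genome-wide annotation
sets) are flagged degenerate, excluded from the BH denominator, and
carried through the output with an explicit flag rather than an error: a
screen over tens of thousands of genes must not stop on a degenerate row.

Two concordance filters then summarise the three per-tissue tables:

* **Pan-arterial set** — genes with q below `alpha` (default 0.05) in all
  three arteries and the same correlation sign throughout. Requiring a
  triple q-threshold intersection with sign concordance is conservative,
  which is exactly why a fully null cohort yields an empty set in
  essentially every run.
* **Extended set** — genes significant in the two better-powered arteries,
  with $|\sum_{\text{3 tissues}} R| >$ `sum_r_cut` (default 0.5) and a
  directionally consistent secondary-artery R with absolute value above
  `sec_r_cut` (default 0.1). The sum-of-R cutoff is applied to the
  *absolute* sum with a sign-consistency requirement, so declining and
  rising transcripts are treated symmetrically; the secondary artery (the
  smallest cohort) contributes direction, not significance.

Genes are ranked by the effect-size proxy `mean TPM × slope`, which
promotes large absolute expression changes over large relative changes in
rare transcripts. Ties are broken lexicographically by gene id so ranking
is deterministic. Age-bin summaries use closed decade-pair bins (20–39,
40–59, 60–79 years) with ages floored to integers first — public
repository ages are integer or bracketed, and flooring makes the boundary
rule exact — and differences between bins are tested by the tie-corrected
Kruskal–Wallis rank test. Donor ages may be exact years or decade-bracket
midpoints; both input styles are accepted and should be declared in the
metadata, since the correlation is computed from whatever ages are given.

## Regulon attrition

The panel deviation statistic asks whether a panel of co-regulated genes
(for example, targets of the SRF/myocardin or YAP/TAZ programs) declines
with age *as a group*. The panel members' R-values are extracted from a
tissue's correlation table and tested against the median R of all
non-degenerate genes in that tissue — typically close to 0 — with a
one-sample Wilcoxon signed-rank test. Using the genome-wide median as the
null centre makes the statistic robust to global shifts in the R
distribution. Panel members missing from the table (or degenerate) are
excluded and logged; a run aborts if more than half the panel is
unmapped, or if fewer than five members map, because a deviation test on
a sliver of a panel does not test the panel.

The signed-rank test is implemented in full rather than delegated,
because panels routinely contain tied R-values and an exact, tie-aware
two-sided p-value is needed at panel sizes of 10–30. Values equal to the
null centre are dropped (the classic Wilcoxon zero convention). For
effective $n \le 25$ the exact null distribution of the signed-rank sum
is computed by a generating-function convolution over the (midrank,
possibly half-integer) ranks; beyond that a normal approximation with the
standard tie correction and no continuity correction is used. The
two-sided p is `min(1, 2 × min(lower tail, upper tail))`. The exact mode
is validated against exhaustive enumeration of all $2^n$ sign
assignments, and its discreteness makes the test conservative under the
null — the calibration experiments bound the rejection rate at the
nominal level plus Monte-Carlo error.

The confounder-adjusted model regresses a target gene's TPM on age, sex,
and covariate transcripts (by default marker transcripts for
inflammation, blood pressure and transcription-factor level) by ordinary
least squares with coefficient t-tests. Sex enters as coded (1 = male,
2 = female), not recentred, to keep coefficients comparable across
analyses. Rank-deficient designs raise an error naming the collinear
columns. qPCR fold-changes use the 2^−ΔΔCt construction with a declared
reference gene and control group; the control group's geometric mean fold
is 1 by construction, and downstream statistics should use the emitted
log2 folds.

## The proteomics stage

The differential-expression stage mirrors the standard label-free
workflow for two-group comparisons. Raw quantities are log2-transformed
(missing cells preserved), then filtered to proteins with at least
`min_valid` (default 3) present values in *every* group. The test
statistic per protein is $d = (\bar{x}_\text{trt} - \bar{x}_\text{ref}) /
(\text{pooled SE} + s_0)$, the pooled-variance Student t when $s_0 = 0$.
The default is $s_0 = 0$ — a plain two-sided Student t — with $s_0$
exposed for users of SAM-style moderation. The contrast is oriented
second factor level minus first, so with groups named `Ctrl` and `KO` a
positive log2FC means higher in the knockout.

FDR control is by label permutation: group labels are reassigned
`n_perm` times (default 250), each assignment drawn uniformly without
replacement from the distinct balanced reassignments excluding the
identity (for 6 vs 6 there are 924 − 1 such assignments, so 250 are a
proper subsample; designs with fewer distinct assignments use all of
them, which also makes the result seed-invariant). For a symmetric
threshold $|d| \ge c$ the estimated FDR is the mean permutation count of
$|d^\ast| \ge c$ divided by the observed count; estimates are made
monotone non-increasing in $c$ by a suffix minimum, and the significant
set is the largest threshold set with estimated FDR at most `fdr`
(default 0.05). Ties in $|d|$ at the threshold are all included. The
plain count ratio is used without a $\pi_0$ correction — the simplest
defensible permutation-FDR estimator; this choice makes the estimator
slightly conservative when many proteins are truly null. No numerical
identity with any particular desktop implementation of this workflow is
claimed; the calibration experiments below are the evidence that the
estimator controls what it says it controls.

Missing values are imputed *only* for PCA, from the standard downshifted
Gaussian: per sample column with observed mean $\mu$ and SD $\sigma$,
missing cells are drawn from $N(\mu - 1.8\sigma, (0.4\sigma)^2)$ (width
0.4, downshift 1.8), modelling the fact that intensities are missing
because they are low. Observed cells are never altered, bitwise.
z-scoring uses the sample-SD ($n-1$) convention throughout. Hierarchical
clustering uses Euclidean distance with average linkage over rows and
columns separately, with optional seeded k-means row preprocessing
(default off — matrices at this scale do not need it). PCA scores come
from the SVD of the row-centred matrix with a deterministic sign
convention (the coordinate with the largest absolute loading is made
positive).

## Signature comparisons

Overlap analytics operate on the DE results' significance flags — never a
raw p cut — so their semantics inherit the permutation FDR. Directional
overlap reports proteins significant in two contrasts with concordant
fold-change signs (and the discordant set alongside); regulator
consistency counts annotated pathway activators that rise and inhibitors
that fall; the novel-target construction is
`(reduced ∩ induced) \ known`, sorted. Identifier matching is exact and
case-insensitive with no alias or ortholog resolution: symbol
harmonisation across species is an editorial decision that belongs to the
user, not a silent transformation.

## The synthetic cohorts

The generators define the package's evaluation conditions and are
first-class, tested code. The expression generator emulates three
arterial cohorts (defaults: 663, 432 and 240 donors, matching the
relative sizes of public tibial/aorta/coronary collections) with ages
uniform over 20–79, per-gene log-normal baseline TPM (meanlog log 10,
sdlog 1.5), and for age-dependent genes an expected TPM of
$b\,(1 + s\,(a - \bar a)/h)$ with $h$ the age half-span — so $|s|$ is the
relative change between the age midpoint and either extreme. Ten percent
of genes carry trends with $|s|$ uniform on [0.1, 0.6]; two 25-gene
panels carry coordinated negative trends; multiplicative log-normal noise
has CV 0.5. These noise and effect scales were chosen once as values a
bulk-RNA-seq analyst would call realistic for inter-donor variation; no
claim is made that they match any public cohort's empirical moments.
"Strong" trends in the recovery experiments means $|s| \ge 0.3$.
Negative expected TPM would be truncated at zero, and a spec producing
more than 1% truncation is rejected outright with advice to lower the
slope scale.

The proteome generator produces two groups of six samples with
per-protein baselines $N(25, 2^2)$ on log2 scale, replicate SD 0.3, and
10% of proteins shifted by ±2 log2 units. A literal single shared
baseline would make dropout uniform across proteins, so baselines are
spread (the `mean_spread` parameter) to produce the abundance range that
drives intensity-dependent missingness: each cell is set missing with
probability $\mathrm{sigmoid}((20 - x) \cdot 1)$, giving a few percent
overall missingness concentrated in low-abundance proteins, with the
empirical missingness rate verified to rise as intensity falls.

One user seed expands into named child streams (baselines, trends, ages,
sex, noise, dropout, …) via a small multiplicative hash, so adding a new
random stream to a generator never perturbs existing draws, and identical
spec + seed reproduces byte-identical output.

What passing these tests shows: the screen's filters recover the trends
the generator injected at the stated sizes and reject nulls at the stated
rates, under linear trends, log-normal noise, independent genes and
uniform ages. What they do not show: robustness to correlated genes,
batch structure, non-linear trajectories, heteroscedastic noise, or the
heavy-tailed abundance distributions of real cohorts — none of which the
generator emulates.

## Numerical and design choices

* p-values are never reported as exactly 0; they are floored at the
  smallest representable double (and capped at 1 against backend
  rounding overshoot).
* The 2×2 chi-squared test defaults to no continuity correction; the
  canonical small-table comparison this pipeline was built around (4/7
  vs 0/7) is significant only without the correction, and Fisher's exact
  test ships alongside as the small-table companion. One published
  comparison of 3/6 vs 2/5 is reported in its source as p = 0.99, which
  no standard chi-squared variant reproduces (uncorrected ≈ 0.74, Yates
  ≈ 1.0); this implementation reports the uncorrected value and does not
  force agreement.
* Degenerate inputs (constant genes, all-equal groups, values all at the
  Wilcoxon null) return flagged results, not exceptions, wherever a
  pipeline iterates over thousands of features; single-shot entry points
  (constant age, zero table margins, collinear designs) raise named
  errors instead.
* Workflow runs write a JSON manifest with package version, parameters,
  seeds and MD5 digests of all inputs and outputs; identical runs differ
  only in timestamp.

## Problem sizes used in validation

The test suite and the acceptance script run the recovery and calibration
experiments at 2,000 genes × 300/200/120 donors (20 simulation seeds,
plus 20 null-cohort seeds), 1,000 random null panels of 20 genes for
panel-test calibration, and 2,000-protein 6 vs 6 proteomes with 250
permutations (20 null and 20 mixed seeds). These sizes give Monte-Carlo
errors small enough for the stated bounds (e.g. ±1.4 percentage points on
a 5% rejection rate) while keeping a full validation run in the order of
a minute.

## Known limitations

Correlation tables assume one expression matrix per tissue with a shared
gene universe; meta-analytic pooling across studies is out of scope, as
are batch/surrogate-variable correction, transcript-level
quantification, GO enrichment (an external-service step), and any raw
mass-spectrum processing upstream of the protein quantity matrix. The
permutation FDR requires exactly two groups; multi-group designs need a
different statistic. The covariate model is ordinary least squares on
TPM; it does not model counts or mean-variance relationships.
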