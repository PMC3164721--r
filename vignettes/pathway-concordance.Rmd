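---
title: "Cross-platform pathway concordance: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform pathway concordance: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcord)
```

## The scientific problem

A recurring design in tumor transcriptomics compares tumor and normal
tissue on two independent microarray platforms and asks which *pathways* —
predefined gene sets, typically KEGG — are coordinately deregulated in
both series. Requiring a pathway to reach significance independently in
two datasets is a simple and interpretable replication filter: at a
per-dataset level of $\alpha = 0.05$ a null pathway passes both screens
with probability $\alpha^2 = 1/400$, which is why no further
multiple-testing correction is applied to the jointly significant list
(`joint_chance_risk()`).

`pathcord` implements that workflow end to end: admission filtering of
the expression matrix, a parametric set-level statistic, set P-values by
a normal reference or by sample-label permutation, and classification of
every pathway (and gene) into cross-dataset concordance categories. A
companion toolkit covers the quantitative follow-up such screens feed
into: qPCR standard curves, percent-of-methylated-reference (PMR)
methylation calls, and rank-based clinicopathological association tests.

## The model and its statistic

For each gene $g$ the two-class comparison uses the classical
pooled-variance t-statistic $t_g$ with $n_1 + n_2 - 2$ degrees of freedom
(`two_class_ttest()`), two-sided, and the log fold change is the
difference of group means on the log2 intensity scale
(`log_fold_change()`). For a set $S$ with $n = |S|$ measured genes the
enrichment score is

$$Z_S = \frac{\sum_{g \in S} t_g}{\sqrt{n}}.$$

If the $t_g$ were independent with zero mean and unit variance, $Z_S$
would be approximately standard normal; a positive $Z_S$ means the set
is upregulated in tumors. Two set-level P-values are offered
(`set_pvalue()`):

* **normal** (default): $p = 2\,\Phi(-|Z_S|)$. Fast, but mildly
  anticonservative for two reasons: a t-statistic with $\nu$ degrees of
  freedom has variance $\nu/(\nu-2) > 1$, and co-expressed genes within a
  set violate independence.
* **permutation**: sample class labels are permuted, the entire per-gene
  t vector and set score are recomputed per assignment, and
  $p = (1 + \#\{|Z^{perm}| \ge |Z|\})/(B + 1)$. When the number of
  distinct label assignments $\binom{n_1+n_2}{n_1}$ is at most $B$, all
  of them are enumerated and $p$ is the exact tail fraction — so on small
  designs the permutation P-value is exact, not estimated. The
  permutation null preserves inter-gene correlation, which is why it is
  the rigorous option.

The two routes are deliberately both exposed: the set-level probability
model of the original analysis style is under-determined, and neither
route claims to reproduce any particular published P-value; they bracket
the reasonable readings.

Scores are undefined when a gene's t-statistic is infinite (zero pooled
variance with unequal means); `run_enrichment()` refuses to score such
data rather than silently clamping. Score exactly zero is reported with
direction `"none"`.

## Admission filters

The pipeline admits genes and sets in a fixed order
(`preprocess_dataset()`):

1. **Variability filter.** Reporters with interquartile range
   (IQR) $< 0.5$ log2 units across all samples are excluded; IQR exactly
   0.5 is retained (the rule is a strict `<`). IQR is computed with
   linear interpolation between order statistics (quantile type 7), the
   mainstream default; the same convention is used everywhere so the
   filter and the collapse never disagree (`compute_iqr()`).
2. **Probe collapse.** Genes measured by several reporters keep the
   single reporter with the largest IQR; exact ties go to the
   lexicographically smallest reporter id for determinism
   (`collapse_to_genes()`).
3. **Annotation restriction.** Genes in no set are dropped
   (`restrict_to_annotated()`).
4. **Set pruning.** A set's effective size is its number of measured
   genes; sets with fewer than 10 are removed, again with a strict `<`
   (`prune_small_sets()`).

Whether the variability filter should run before or after probe collapse
is not dictated by the workflow's usual description; the default here is
filter-first (a gene survives if *any* reporter survives), with
`filter_before_collapse = FALSE` available for the other order. The two
orders coincide whenever every reporter of a gene is on the same side of
the threshold. Matrices with missing or non-finite values are rejected
outright: no imputation rule is defined, and silently dropping cells
would change the t-test's degrees of freedom per gene.

## Concordance classification

`classify_item()` reduces a pathway's (or gene's) two-dataset outcome to
one of eight categories: `concordant-up`, `concordant-down`, `opposite`,
`single-A`, `single-B`, `neither`, `unmeasured-A`, `unmeasured-B`.
Significance is *inclusive* ($p \le \alpha$), honoring the conventional
"P ≤ 0.05" phrasing literally; the boundary case therefore counts as
significant. An item absent from one platform is `unmeasured` for it no
matter how strong the other platform's evidence is — gene-level tables
(`gene_concordance_table()`) still list such genes, with `NA` standing
for the printed "-" convention, and partition them by the platform that
did measure them. `joint_chance_risk()` assumes independence of the two
datasets; that is an idealization (different platforms profile the same
biology), documented rather than asserted.

## The synthetic-data generator

`simulation_design()` fixes the study conditions; all defaults were
chosen once, up front, to emulate a two-platform colorectal study:

| parameter | default | rationale |
|---|---|---|
| `samples_a` | 46 tumors / 4 normals | the smaller array series of the motivating design |
| `samples_b` | 91 tumors / 6 normals | the larger series |
| `n_genes`, `n_sets` | 1000, 200 | desk-scale stand-in for a few thousand annotated genes in ~200 pathways |
| `set_size_range` | 10–30 | typical post-pruning pathway sizes |
| `frac_sets_up`, `frac_sets_down` | 0.2, 0.2 | a substantial but minority planted signal |
| `effect_size` | 1.0 log2 | a twofold shift, recoverable but not trivial at 4–6 normals |
| `noise_sd` | 1.0 log2 | of the order of array log-intensity spread |
| `platform_overlap` | 0.8 | partially overlapping gene universes |
| `multiprobe_frac` | 0.2 | exercises the collapse rule |
| `lowvar_frac` | 0.1 | exercises the IQR filter |

Baseline intensities are Normal(8, 1) per gene, shared across platforms;
observations add i.i.d. Normal(0, `noise_sd`); tumor samples of planted
genes shift by ±`effect_size`. Genes recruited into a planted set inherit
its direction, and later sets of the opposite direction never recruit
them, so no gene carries conflicting truth. Low-variability genes are
rescaled to IQR 0.25 and drawn preferentially from unplanted genes so the
rescaling does not erase signal. A single master seed feeds deterministic
per-component child streams: regenerating one component never perturbs
another, and identical designs reproduce byte-identical outputs.

What the generator deliberately does **not** emulate: inter-gene
correlation (the score's normal reference assumes independence — this is
the statistic's known weakness, and the permutation option exists largely
because real data violate it), platform-specific noise models, batch
effects, and copy-number-driven expression. Passing tests on this
generator therefore validate the *pipeline logic and its statistics
under the stated model*, not fidelity to any particular deposited
dataset.

Two consequences of the design are worth knowing when reading results.
First, sets overlap: a nominally null set can contain genes planted by
an up- or downregulated set, and will then legitimately reject — null
calibration is meaningful only on an all-null design (`effect_size = 0`),
which is how the package's calibration checks and the acceptance script
measure it. Second, with partial platform overlap a planted set can fall
below 10 measured genes on one platform and be pruned there; it is then
reported `unmeasured`, and recovery rates are computed among sets
actually tested on both platforms, where concordance is defined.

## Quantitation arm

* `standard_curve_quantify()` fits `Ct = a + b·log10(q)` by least squares
  and inverts it; a slope below `1e-8` in magnitude is an error (a flat
  curve cannot be inverted).
* `normalize_expression()` aggregates replicates by the **median**
  (robust to one aberrant well of a triplicate) and divides by the mean
  of the endogenous controls' medians.
* `pmr()` is `100 × (target/ALU)_sample / (target/ALU)_control`; it is
  invariant to rescaling a sample's two quantities, as a DNA-input
  normalization must be.
* `call_methylation()` calls a sample methylated when its PMR *strictly
  exceeds* the maximum of the normal panel (floor 0). With an all-zero
  normal panel this is the familiar "PMR > 0" rule; the general form is
  kept so panels with background signal behave sensibly.
* `mww_test()` uses the exact rank-sum null when both groups have ≤ 8
  observations and no ties (two-sided P = doubled smaller tail, capped at
  1), otherwise the tie-corrected normal approximation *without*
  continuity correction — chosen so that the two-group Kruskal–Wallis
  test (`kruskal_wallis_test()`) gives the identical P-value, since
  $\chi^2_1 = z^2$. `association_screen()` routes binary covariates to
  MWW and multi-level ones (stage, localization) to Kruskal–Wallis, and
  attaches a note that no multiplicity correction is applied.

## Numerical choices

* Permutation score comparisons use a `1e-12` absolute tolerance when
  counting `|Z_perm| ≥ |Z_obs|`: in balanced designs complementary label
  assignments are algebraically sign-mirrored, and the tolerance keeps
  last-ulp noise from flipping an exact tie.
* Vectorized per-gene t-statistics are computed from group sums and sums
  of squares with the within-group sum of squares clamped at 0 to absorb
  cancellation; they are tested to agree with `t.test()` per gene.
* Expression TSVs are written with 17 significant digits so doubles
  round-trip exactly.
* Degenerate rank tests (all observations identical) return H = 0,
  p = 1 rather than NaN.

## Problem sizes used in validation

The packaged checks run the full two-platform pipeline at the default
design (1000 genes, 200 sets, 46/4 and 91/6 samples) with 1000 label
permutations; permutation exactness is verified by complete enumeration
on designs of up to 6 samples, and the rank-sum enumeration oracle sweeps
all group sizes up to 6. These sizes make the whole suite run in well
under a minute while keeping every binomial tolerance tight enough to be
meaningful (about 200 sets per calibration estimate).

## Known limitations

* The sum-of-t score ignores inter-gene correlation; with correlated
  expression its normal reference is anticonservative. Use the
  permutation method when it matters.
* Gene identity is the bare case-sensitive symbol; no alias resolution.
* No missing-data support; matrices must be complete and finite.
* The joint-risk argument assumes dataset independence.
* `lfc` is a difference of log2 group means; published "fold change"
  columns computed by other conventions (or on other scales) will not be
  numerically comparable.
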