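---
title: "Methods: compartment-specific gene sets and germ-cell fate shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-specific gene sets and germ-cell fate shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compartshift)
```

## The problem

A fetal gonad is a mixed tissue: germ cells (the gamete lineage) develop
inside a much larger somatic compartment (Sertoli or granulosa cells and
their precursors). A bulk expression profile of a testis or ovary is
therefore a weighted blend of two cell-type programs, and a question such
as "did the germ cells in this mutant ovary switch to a male program?"
cannot be answered by naive differential expression: a change in the
tissue profile could come from either compartment.

The trick this package implements is to use *germ-cell-ablated* gonads as
subtraction controls. In a genotype whose gonads lack germ cells
entirely, whatever expression remains must be somatic. Contrasting normal
(heterozygous control) gonads against ablated gonads therefore attributes
genes to the germ compartment, and combining that contrast with a
testis-vs-ovary contrast yields four gene classes per sex and
compartment: male-germ, female-germ, male-soma, female-soma.

## Gene-set extraction

All contrasts use the same fold-change definition. For gene $g$ and
sample groups $A$, $B$ with log2 intensities $x$,

$$\mathrm{FC}_g(A,B) =
  \frac{\tfrac{1}{|A|}\sum_{i \in A} 2^{x_{gi}}}
       {\tfrac{1}{|B|}\sum_{j \in B} 2^{x_{gj}}},$$

i.e. the ratio of *linear-scale* group means, reported as
$\log_2 \mathrm{FC}$. Averaging unlogged intensities (rather than log
values) matches the reading of "fold change in expression level" as a
ratio of expression levels; with three replicates and moderate noise the
two definitions rarely disagree about a 1.5-fold cut, but a convention
has to be fixed and this one is used everywhere in the pipeline.

The extraction rule, with fold threshold $T = 1.5$:

1. **Sex-specific**: $\mathrm{FC}(\text{het testis}, \text{het ovary})
   \ge T$ defines male-specific genes; the reciprocal contrast defines
   female-specific genes.
2. **Germ-cell-specific**: a male-specific gene is male-germ if
   $\mathrm{FC}(\text{het testis}, \text{ablated testis}) \ge T$
   (expression lost when germ cells are absent); female-germ genes use
   the ovary contrast.
3. **Somatic-specific**: the sex-specific genes that are *not*
   germ-cell-specific. No additional het-vs-ablated equivalence test is
   imposed.
4. Everything else is unclassified. The output is a partition of the
   gene universe.

Two genuinely open choices are fixed as defaults and exposed as options:

* **Matching-sex germ rule** (default). The ablation contrast is
  evaluated only in the gene's own sex. A male-specific gene is
  near-baseline in ovaries, so the ovary het-vs-ablated contrast carries
  no information about it; requiring it would reject genes on noise.
  `extraction_config(germ_rule = "both")` switches to the stricter
  intersection across both sexes.
* **Inclusive comparison** (`>=`). Ties at the threshold are
  measure-zero on real intensities, but tests need a fixed convention.
  Comparisons carry a 1e-12 guard on the log2 scale so that a gene
  planted exactly on the cut cannot flip sides through floating-point
  representation of `log2()`; the guard is far below any meaningful
  expression margin.

## Shift quantification

Given the gene classes and a mutant-vs-control fold-change vector (for
the target application: double-knockout ovary vs control ovary),
`quadrant_classify()` labels each gene against the $\pm\log_2 T$ cut
lines on both axes, and `shift_fractions()` reports the two headline
fractions: the percentage of male-germ genes at least $T$-fold *up* in
the mutant, and of female-germ genes at least $T$-fold *down*.
Percentages are printed with one decimal, rounded half-away-from-zero —
the convention that reproduces count-to-percent reporting such as
43/104 = 41.3% (`proportion_percent()`).

## Subset PCA and factor loadings

`run_subset_pca()` restricts the matrix to a gene subset (all genes,
soma-specific, or germ-specific), mean-centers each gene across samples
and decomposes the centered sample-by-gene matrix by SVD. Choices:

* **Centering only, no unit-variance scaling** (default). Scaling genes
  to unit variance would erase exactly the effect-size differences the
  loading analysis measures. `scale_genes = TRUE` is available.
* **Percent variance** is $100\,\lambda_k / \sum_k \lambda_k$ over the
  $\min(n_\text{samples}-1, n_\text{genes})$ retained components, so the
  reported percentages always sum to 100.
* **Factor loadings are gene–score Pearson correlations**, not raw
  rotation entries: they are bounded in $[-1, 1]$, which is the scale on
  which "a gene that tracks the axis has loading near $\pm 1$" is
  meaningful. Zero-variance genes get loading 0.
* **Orientation**: the sign of PC1 is chosen so that a designated
  reference group (by default the control testes) has positive mean
  score. SVD signs are otherwise arbitrary; pinning them makes "shifted
  toward the male side" reproducible across runs.

`contribution_test()` compares the absolute PC1 loadings of the pooled
germ-specific genes against the pooled soma-specific genes with a
two-sided Wilcoxon rank-sum test and reports group medians and the
p-value. The original analysis this mirrors does not name its test; a
rank test was chosen because |loadings| are bounded and far from normal,
and the choice is documented rather than asserted as the original. The
exact distribution is used where `stats::wilcox.test` supports it
(small, tie-free groups), the normal approximation otherwise.

## The simulator

`simulate_gonad_expression()` generates the full study design so that
every stage above can be tested by parameter recovery. Each sample's
linear-scale profile is a two-compartment mixture

$$y_{g} = \log_2\!\big(f\,G_g + (1-f)\,S_g\big) + \varepsilon_g,
  \qquad \varepsilon_g \sim N(0, \sigma^2),$$

where $G$ and $S$ are germ and soma compartment profiles, $f$ is the
germ fraction of the tissue, and noise is additive on the log2 scale
(multiplicative on intensities — the standard microarray error model). A
(sex, compartment)-specific gene sits at `baseline * spec_fold` in its
home compartment-and-sex and at `baseline` elsewhere.

Condition semantics:

* `control_het`: normal mixture for the sample's sex.
* `germ_ablated`: $f = 0$; the pure somatic profile.
* `smad4_ko` ovary: a fraction $e$ of germ cells (the recombined ones)
  silence female-germ genes without activating male-germ genes; the
  remaining $1-e$ keep the female program. Mosaicism is a linear mixture
  within the germ compartment, reflecting that recombined and
  non-recombined germ cells coexist in one tissue.
* `dko` ovary: the recombined fraction $e$ activates a planted subset of
  male-germ genes (fraction `p_up_male`) and silences a planted subset
  of female-germ genes (fraction `p_down_female`); the rest of the germ
  compartment keeps the female program.

Defaults are the study conditions the pipeline targets: class sizes
386/360/680/636 with 2000 background genes; 3 replicates per condition;
recombination efficiency $e = 0.80$ (the reported upper bound of Cre
activity); planted penetrances 0.521 and 0.711, so that at zero noise the
realized shift fractions are exactly 52.1% (201/386) and 71.1%
(256/360); `spec_fold = 4` and `noise_sd = 0.25`, typical of a
well-expressed microarray signature; and `germ_fraction = 0.3` — a
simulator convention, not a measured value, chosen as a plausible germ
share of a fetal gonad. The mutant-stage labels (E14.5 vs E13.5
controls) are carried purely as design metadata: the developmental-delay
argument only justifies *which* control timepoint is compared, so it has
no expression effect in the model. All randomness derives from the
config seed; the generator restores the caller's RNG state.

With these defaults the planted tissue-level contrasts are comfortably
detectable: an activated male-germ gene in the DKO ovary exceeds the
control ovary by a linear factor $1 + f\,e\,(\text{spec\_fold}-1)
= 1.96$, above the 1.5 cut, and the closed form is asserted exactly in
the tests at zero noise.

### What the simulator does and does not emulate

It emulates the mixture structure, the ablation contrast, KO mosaicism,
replicate noise, and planted penetrances — enough to test recovery of
every statistic the pipeline computes. It does not emulate probe-level
artifacts, correlated gene programs, variable expression magnitudes, or
selection effects, and one consequence is worth stating plainly: because
every planted gene uses one compartment-level `spec_fold` while germ and
soma signals are diluted by $f = 0.3$ and $1-f = 0.7$ respectively,
soma-specific genes have systematically larger *tissue-level* sex
contrasts (fold $1 + 0.7 \cdot 3 = 3.1$) than germ-specific genes
($1 + 0.3 \cdot 3 = 1.9$). On real data, both sets are *selected* by the
same tissue-level 1.5-fold cut, which equalizes their tissue-level
effect distributions; the simulator has no such selection. The
contribution test is powerful enough (hundreds of genes per group) to
detect this construction asymmetry in the control testis-vs-ovary
comparison, so on simulated data that comparison is *not* a null — an
honest limitation of the generator, not of the test. The simulation
properties that do transfer, and that the test suite asserts across
seeds, are the qualitative ones: germ-subset PC1 places DKO ovaries
between the control sexes and beyond the single KO toward the male side,
and extraction recovers the planted sets with high sensitivity and
precision.

## Problem sizes and numerical conventions

The test suite runs the full default design (4,062 genes, 18 samples)
for end-to-end and multi-seed property checks — 10 seeds for noisy
recovery, 20 for the PCA ordering and contribution properties — and
small matrices (at most 10 x 10) wherever an exhaustive or
eigendecomposition oracle is compared, with tolerances of 1e-8 for the
PCA oracle, 1e-12 for arithmetic identities. These sizes make the whole
suite run in seconds while keeping the Monte-Carlo assertions stable.

Degenerate inputs are errors, not silent results: empty contrast groups,
overlapping groups, germ sets that are not subsets of their sex sets,
all-zero-variance PCA subsets, and gene universes that do not match
between paired inputs all fail with the offending names in the message.

## Limitations

* Input matrices are assumed pre-normalized, gene-collapsed and
  log2-scaled; no within-pipeline normalization is performed.
* The fold-change filter is deliberately a pure threshold rule — no
  moderated variance, no multiple-testing control — because the
  procedure it reproduces is a threshold rule. It should not be read as
  a differential-expression method.
* The rank-sum contribution test is this package's choice; other
  reasonable tests (t on Fisher-transformed loadings, Kolmogorov–
  Smirnov) would differ in tail behavior.
* Real-data headline numbers that depend on the original deposited
  arrays (PC1 percentages, contribution p-values) are reproduced only
  qualitatively by simulation; the worked arithmetic (count-to-percent
  pairs, planted penetrances) is reproduced exactly.
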