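---
title: "Models and methods behind myolabour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myolabour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

myolabour implements a complete analysis pipeline for two-group bead-array
transcriptome studies of the myometrium — labouring versus non-labouring
uterine smooth muscle — together with a synthetic-data generator that makes
every stage testable without access to clinical data. This vignette explains
the models, the parameters that matter, the numerical choices, and what the
synthetic data can and cannot tell you about real studies.

## The tissue-composition ("dilution") model

The central scientific subtlety the package addresses is that bulk myometrial
tissue is a mixture of cell types. At labour, leukocytes (largely
neutrophils) infiltrate the myometrium. A gene expressed only in smooth
muscle then *appears* down-regulated in bulk labouring tissue, and a
leukocyte-specific gene appears up-regulated, even if no cell changes its
transcription. The generator makes this explicit. Each sample $s$ carries a
leukocyte fraction $f_s$; the expected signal of gene $g$ is

$$t_{gs} = \left[(1-f_s)\,\mu^{\text{muscle}}_g + f_s\,\mu^{\text{leukocyte}}_g\right]\cdot\beta_g^{[s\ \text{labouring}]},$$

where $\beta_g$ is a genuine multiplicative transcriptional labour effect
($\beta_g = 1$ for all but the `labour_induced` and `labour_repressed`
catalog classes). The observed intensity adds bead-array error structure:

$$y_{gs} = b_{gs} + c_s\, t_{gs}\, e^{\varepsilon_{gs}},$$

with additive Gaussian background $b_{gs}$ (mean 100, SD 15, truncated at a
small positive constant — negative-control probes receive background only),
a per-sample scale factor $c_s$ (log-SD 0.1), and multiplicative log-normal
measurement noise $\varepsilon_{gs}$.

Key defaults and why:

* **Leukocyte fractions**: Beta(2, 38) (mean 0.05, tight) for non-labouring
  samples, Beta(3, 7) (mean 0.30, wide) for labouring samples. The location
  shift encodes infiltration at labour; the wider labouring spread
  deliberately reproduces the observation that labouring samples are far
  more heterogeneous than non-labouring ones — some labouring samples look
  almost non-labouring, others are strongly infiltrated. No quantitative
  estimate of the true fraction at labour exists, so these are exposed as
  parameters, not asserted as biology.
* **Measurement noise** `noise_sd_log = 0.05` (~5% CV). This term models
  *technical* replicate error, which is small on bead arrays because each
  reported intensity averages dozens of beads. Biological between-sample
  variation is carried by $f_s$ and the labour effects, not by this term;
  power analyses in the test suite use a deliberately harsher 0.3.
* **Group sizes** default to 22 labouring / 26 non-labouring, the scale of a
  well-powered single-centre study; half of the labouring group is flagged
  as pharmacologically induced/augmented, with *no* effect on expression by
  default (a null covariate for the sensitivity analysis). Parity, BMI,
  maternal age, gestational age and chip assignment are likewise generated
  effect-free.
* **Catalog** (2050 probes): 200 muscle-specific, 200 leukocyte-specific,
  100 labour-induced ($\beta = 2$), 50 labour-repressed ($\beta = 0.5$),
  1400 housekeeping, 100 negative controls. Desk-scale, but preserving the
  class structure that matters: pure-dilution classes, pure-transcription
  classes, nulls, and background-only probes.

Under the defaults the mixture formula predicts muscle-specific genes at an
apparent fold change of $0.70/0.95 \approx -1.36$ and leukocyte-specific
genes near $+6$ with no transcription changing at all — both beyond the
conventional 1.2-fold threshold, which is exactly the confound the pipeline
must expose. The `truth` table of every synthetic study records these
expectations separately from the transcriptional ones.

## Preprocessing

1. **Background correction.** The normexp convolution model (observed =
   normal background + exponential signal) is the background model that
   underlies RMA. Parameters are estimated per sample from negative-control
   probes: $\mu$ and $\sigma$ are the control mean and SD, $\theta$ the mean
   excess of regular probes over $\mu$. Each intensity is replaced by the
   posterior mean $E[S \mid O = o]$, the mean of a normal truncated to the
   positive half-line, evaluated in log space by `limma::normexp.signal()`
   (strictly positive, monotone in $o$; verified against direct quadrature
   of the posterior in the test suite).
2. **Quantile normalization** forces all samples onto the common
   distribution of rank means. Tied values receive the mean of the reference
   values over their tie span, a convention that conserves the grand mean
   exactly and is idempotent on tie-free data.
3. **Detection-floor filtering.** The floor is the median negative-control
   intensity rounded to the nearest integer (half away from zero; ~100
   under the defaults). It is computed from the *raw* controls — after
   background correction control intensities shrink towards zero, while the
   conventional floor is defined on the raw scale. A probe is removed only
   if its mean is below the floor in *both* groups; controls are always
   removed from the analysis matrix.

## Rank-product differential expression

For each of up to `max_pairs = 100` labouring/non-labouring sample pairs
(all $n_L \times n_{NL}$ pairs when fewer; a seeded subsample otherwise),
probes are ranked by their between-sample expression ratio. The rank product
of a probe is the geometric mean of its ranks across comparisons — small
when a probe is consistently near the top of the ordering. Ratios are taken
on the normalized raw scale by default so that the ranking and the reported
fold changes share a scale; a log2 option exists and yields identical
rankings on positive data. Geometric means are accumulated in log space to
avoid overflow; ties receive average ranks.

Significance is attached by permutation, and two complementary nulls are
reported:

* **RP-PFP** (drives the up/down calls): the classical rank-product null —
  each probe receives an independent uniform random rank per comparison, $B$
  times. For a probe with ascending rank-product rank $\rho_g$, the expected
  number of null rank products at or below its observed value, divided by
  $\rho_g$, is the percentage of false positives. PFP values are made
  monotone non-decreasing along the rank-product ordering so threshold sets
  are nested in $\alpha$.
* **Per-probe permutation p-values**: sample group labels are permuted and
  the rank products recomputed on the real data, each probe referenced
  against its own permutation distribution. This null preserves two features
  the classical scheme ignores — comparisons share samples, and probes
  differ in ratio variance — and is therefore calibrated: under a global
  null the p-values are uniform. (A *pooled* label-permutation null was
  rejected during design: when real effects exist, other probes' signal
  contaminates the pool and destroys power; per-probe referencing avoids
  this.)

A probe is called differential when RP-PFP $\le$ 0.05 *and* |signed fold
change| $\ge$ 1.2, the conventional joint threshold. When both directions
qualify, the smaller PFP wins, then the larger magnitude; a residual exact
tie is excluded with a warning.

## Correlation networks and Markov Clustering

Sample–sample and probe–probe graphs are built from Pearson correlations of
log2 intensities (the standard co-expression scale), over the selected
differential probes. In sample mode each probe is z-scored across samples
first, fixing a definite convention for the multi-probe profile. An edge
exists only when $r$ is *strictly above* the threshold — 0.85 for samples,
0.80 for probes — so negative correlations never create edges.

MCL is implemented from scratch on dense matrices: add a self-loop (weight
1) to each node, column-normalize to a stochastic matrix, then alternate
*expansion* (matrix squaring) and *inflation* (elementwise power at the
inflation parameter, then renormalization), pruning entries below $10^{-5}$,
until the maximum change drops below $10^{-6}$ (cap 200 iterations;
non-convergence returns the current clustering with a flag). Clusters are
the connected components of the limit matrix's non-zero structure; cluster 1
is the largest, ties broken by smallest member label. Inflation 3.0 is the
default for sample graphs and 2.2 for probe graphs; 3.1 is a documented
alternative for the sample graph. Column sums are tracked at every
normalization step and deviate from 1 by less than $10^{-9}$ in practice.

Cluster–trait association cross-tabulates cluster membership against a
binary trait, using Fisher's exact test when any expected cell count is
below 5 and Pearson's chi-squared (no continuity correction) otherwise.
Singleton clusters are pooled into a single "unclustered" row by default: a
cluster of one sample carries no grouping information, and a table padded
with singleton rows makes the exact test degenerate. A treatment covariate
that only one group can receive (labour induction/augmentation) is tested
within the labouring group, since a whole-cohort test is confounded with
labour status by construction.

## Meta-analysis

Studies are harmonized to their common gene set after collapsing probes to
genes (default: keep the probe with the highest mean intensity in that
study; averaging is available). Effects are standardized mean differences of
log2 intensities — Cohen's $d$ with the pooled SD, Hedges' small-sample
correction $J = 1 - 3/(4m - 1)$ (with $m = n_L + n_{NL} - 2$), and the
standard large-sample variance. The small-sample correction is material here
because replication studies in this literature run at $n \approx 6$ per arm.

Pooling is inverse-variance weighted. Heterogeneity is summarized by
Cochran's $Q$ (chi-squared test on $k-1$ df) and the DerSimonian–Laird
between-study variance $\tau^2 = \max(0, (Q - df)/C)$. Both fixed- and
random-effects estimates are always reported — the two models coincide when
$\tau^2 = 0$, and neither is privileged in the output. Cross-study
concordance reports, over the shared genes: the percentage of study A's
significant genes replicated with the same direction in B, the percentage
with the same direction regardless of B's significance, and the percentage
of jointly significant genes with conflicting directions.

## Validation procedures

* **Subgroup sensitivity**: signed fold changes are recomputed after
  dropping a flagged subgroup (by default, induced/augmented labouring
  samples) from the same preprocessed matrix, and compared with the
  full-cohort fold changes: median absolute difference, IQR of the signed
  differences (spanning zero for a null flag), Pearson correlation, and the
  percentage of probes keeping their sign. All differences are on the
  signed-fold-change scale.
* **Delta-CT comparison**: qRT-PCR cycle thresholds are analysed as the
  target CT minus the reference-gene CT per sample, compared between groups
  with a pooled-variance Student's t-test (Welch optional). Lower delta-CT
  means higher expression, and the direction call uses that inverse mapping.
  Group means of the raw reference CT are reported so the reference-gene
  stability assumption can be inspected.
* **Cross-platform concordance**: Pearson correlation of per-gene log2
  group ratios between platforms, plus per-gene sign agreement.

## What the synthetic data do and do not show

The generator emulates the features the pipeline's statistics depend on:
positive raw intensities over an additive background floor, a two-group
design with realistic group sizes, composition-driven apparent effects with
known direction, genuine transcriptional effects of known size, partially
overlapping probe complements across studies, and null clinical covariates.
It does **not** emulate probe-level cross-hybridization, batch effects
(chips are recorded but effect-free), RNA-quality degradation, correlated
co-regulation beyond the single composition axis, or annotation ambiguity.
Passing tests therefore demonstrate that the *procedures* are implemented
correctly and behave as designed under a controlled generative model — not
that any particular biological conclusion transfers to a given real dataset.

One consequence of the deliberately simple error model is that sample–sample
correlation graphs are sparser than on real arrays, where thousands of
co-regulated genes make within-group correlations very high: at the 0.85
threshold the synthetic graph connects the strongly infiltrated labouring
samples and leaves weakly infiltrated samples unclustered, which is exactly
the heterogeneity pattern the clustering stage is designed to reveal.

## Problem sizes and determinism

Simulations in the test suite and acceptance script use desk-scale sizes
chosen to exercise every code path with stable statistics: the default 2050
x 48 study for the end-to-end runs, 1000-1500 probes at $n = 8+8$ for the
calibration and power studies, $B = 100$ permutations, and 200 replicates
for the meta-analysis recovery simulation. Every stochastic step — catalog
construction, study generation, pair subsampling, both permutation nulls —
is driven by an explicit integer seed, and identical seeds reproduce every
output bit-for-bit.
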