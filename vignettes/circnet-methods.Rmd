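---
title: "Methods and design of the circnet pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the circnet pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circnet)
```

# Scope

circnet implements the computational arm of a two-group circRNA profiling
study of the kind run on plasma samples from a small patient cohort: a
probe-by-sample microarray intensity matrix is normalized and screened
for differentially expressed circRNAs; a handful of hits are validated
by qRT-PCR and quantified with the 2^-ddCt method; the host/target genes
of the differential circRNAs are tested for gene-set over-representation;
and candidate competing-endogenous-RNA (ceRNA) relations are screened by
a shared-miRNA hypergeometric test and assembled into a tripartite
circRNA–miRNA–mRNA network.  Everything upstream of the intensity matrix
(RNase R digestion, labelling, hybridization, image analysis) and the
internals of miRNA target prediction are out of scope: target maps are
consumed as input.

# Differential expression

## Normalization

`quantile_normalize()` forces every sample onto the reference
distribution of rank means.  Ties within a column receive the *mean of
the reference values at the rank positions the tie group occupies*
(not an interpolation of the reference at the mean rank — the two rules
differ whenever the reference is locally non-linear).  On tie-free data
the procedure is idempotent, conserves the grand mean, and agrees with
other standard implementations; with ties, exact idempotence is not
guaranteed, which is a property of any tie-averaging rule rather than of
this implementation.

## Fold change and tests

Fold changes are ratios of geometric means — differences of group means
of log2 intensities — so that testing and filtering happen on the same
scale.  `fc_abs = 2^|log2fc|` matches how array studies print absolute
fold changes.

`probe_test()` offers three variants on log2 intensities:

* **moderated** (default): empirical-Bayes variance moderation.  Probe-wise
  pooled variances $s_i^2$ with $d$ residual df are shrunk toward a prior,
  $\tilde s_i^2 = (d_0 s_0^2 + d s_i^2)/(d_0 + d)$, and the t statistic is
  referred to $d_0 + d$ df (capped at the pooled residual df of all
  probes).  $(d_0, s_0^2)$ are estimated by method of moments on the log
  sample variances: the excess of the spread of $\log s_i^2$ over the
  theoretical $\psi'(d/2)$ identifies $d_0$ through the inverse trigamma
  function.  When the observed spread does not exceed sampling noise the
  prior df is infinite and the prior variance is the mean sample
  variance.  With 4 vs 3 samples per group, per-probe variances are
  almost uninformative; moderation is what makes ranking possible at
  this design, which is why it is the default.
* **welch**: Welch t with Welch–Satterthwaite df.  At 4 vs 3 its true
  size at nominal 0.05 is about 0.0405 under normal homoscedastic noise
  (measured over $10^6$ simulated null probes) — slightly conservative,
  as expected for estimated df this small.
* **pooled**: the equal-variance two-sample t; also the exact limit of
  the moderated variant when $d_0 = 0$.

Degenerate inputs follow fixed conventions: zero standard error with
equal group means gives $p = 1$; with unequal means the p-value is
clamped to the smallest positive double so the $(0, 1]$ contract holds.

## Calling and thresholds

`call_de()` applies the conventional dual filter, default
`fc_abs >= 1.5` and `p < 0.05` on raw p-values, with BH adjustment
optional.  These defaults follow the filter actually applied in the
results of the profiling study this pipeline models (its summary section
prints a stricter 0.01 in one place; the results section's 0.05 is taken
as authoritative, and both are settable).  Raw-p filtering is the field's
common, anticonservative habit; the BH option is provided and used in the
package's own recovery validation.

## Heatmap ordering

`hclust_order()` clusters probe profiles on `1 - Pearson` correlation of
log2 intensities with average (UPGMA) linkage — the usual choice for
expression heatmaps.  Neither the distance nor the linkage is uniquely
dictated by convention, so they are fixed here for determinism; probes
are pre-sorted lexicographically so tie handling does not depend on
input order, and a zero-variance profile (undefined correlation) is
placed at distance 1 from everything.

# qRT-PCR relative quantification

Technical replicates are collapsed by arithmetic mean Ct (the aggregation
rule is a modelling choice; averaging Ct rather than `2^-Ct` matches the
log-linear error structure of qPCR).  Per sample,
`dCt = Ct(target) - Ct(reference)`; `ddCt` is the case-minus-control
difference of group mean dCt, and relative expression is
`2^-ddCt`, case over control, so values below 1 denote downregulation.
The group comparison is a Welch t on per-sample dCt values — the printed
"Student's t-test" of validation figures, made robust to unequal group
variances.  Exact antisymmetry under group swap and invariance to
per-sample Ct shifts are tested properties.  Efficiency correction
(Pfaffl) and standard curves are out of scope.

# Over-representation

`enrich_terms()` computes the one-sided hypergeometric upper tail
$P(X \ge k)$ for the overlap $k$ between the differential gene list
($n$ of $N_u$ universe genes) and each term ($M$ genes), identical to
the one-sided Fisher exact test (verified exhaustively for
$N_u \le 20$).  The *enrichment factor* is $k/M$, the fraction of a
term's genes that are differential, as plotted in enrichment dot plots.
The universe is never stated in such studies; the default here is the
union of all annotated genes, with an explicit background argument
provided.  Terms are tested independently per category (BP/CC/MF/
pathway); no GO-graph propagation or elimination weighting is applied.

# ceRNA screening

For a candidate pair with MRE sets of sizes $K$ and $n$ drawn from a
prediction universe of $N$ miRNAs, the probability of sharing $c$ or
more miRNAs by chance is

$$P \;=\; \sum_{i=c}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}
{\binom{N}{n}},$$

the hypergeometric upper tail *including* the observed overlap, with
impossible terms contributing zero.  It is computed in log space via
the standard hypergeometric distribution function and matches exact
integer enumeration to below $10^{-12}$ relative error over the full
grid $N \le 25$.  The tail is exchangeable in $K$ and $n$, strictly
decreasing in $c$, and strictly decreasing in $N$ — a fixed overlap in a
larger universe is more surprising.

`screen_cerna_pairs()` retains unordered candidate pairs with at least
`min_common` shared miRNAs (default 1 — the shared-miRNA condition with
no published threshold) and $P \le 0.05$.  $N$ is the size of the
supplied miRNA universe — the total number of miRNAs used for
prediction — not the union of observed MRE sets, which would understate
it.  Gene candidates are screened through the same interface by
inverting the miRNA-to-gene map.  Of the three classical conditions for
ceRNA crosstalk — relative concentrations, sponging capacity, MRE
inequality — the first requires expression stoichiometry data that a
profiling study does not provide and is deliberately not modelled; the
second maps to `min_common`, the third to the hypergeometric test.

`build_cerna_network()` merges the shared miRNAs of retained pairs into
a tripartite network (circRNA–miRNA and miRNA–gene edges only) whose
nodes and edges are sorted deterministically; exports are edge TSV
(round-trip safe), SIF and GraphML.

# Synthetic data: what it emulates and what it does not

The generators produce every input with planted ground truth, under
defaults fixed to the modelled study design:

* `simulate_expression()`: per-probe baseline log2 intensity uniform on
  [6, 14], Gaussian log2 noise (sd 0.5 — a realistic between-subject
  spread for plasma arrays), 4 case vs 3 control samples, 5% planted
  probes with |log2FC| uniform on [1, 4] (the magnitude range of
  published top tables) and Bernoulli(1/2) sign, intensities
  exponentiated so positivity is guaranteed.
* `simulate_ct_table()`: triplicate wells, a per-sample loading shift
  that cancels in dCt, and planted effects written into the case group's
  target Ct so that zero noise recovers the planted fold change exactly.
* `simulate_target_map()`: uniform MRE sets without replacement; planted
  pairs share a forced core and fill the rest independently; every used
  miRNA gets 1–3 downstream gene targets.  Defaults: 200 candidates,
  5 MREs each, universe 10,000, 20 planted pairs with fully shared sets.
* `simulate_annotations()`: term sizes uniform on [20, 100]; enriched
  terms draw half their members from the differential list.

Each generator is a pure function of its parameters and one integer
seed, and restores the caller's RNG state.  Not emulated: array image
artifacts, probe GC/sequence bias, batch effects, heteroscedastic or
heavy-tailed intensity noise, correlated probes, qPCR efficiency
differences, and the topology of real target-prediction networks (hub
miRNAs, degree heterogeneity).  Passing recovery tests therefore shows
the pipeline's machinery is correct and calibrated under the stated
noise model — not that real plasma arrays meet that model.

# Validation sizes and numerical choices

The packaged checks use problem sizes chosen to make Monte Carlo error
small relative to the bands being checked while remaining quick: type-I
calibration of the Welch variant averages the rejection rate over 100
independent 10,000-probe null arrays (the single-array rate has sd
~0.002, comparable to the distance between the test's true size, 0.0405,
and the 0.04 band edge); ceRNA null calibration screens all 19,900
background pairs of 200 candidates; differential recovery averages 10
replicate 2,000-probe arrays with 100 planted probes each.  The
published top-20 table bundled in `extdata` is classified exactly (10
up, 10 down).  Tolerances: oracle comparisons use $10^{-12}$ relative
error; round-trip TSV comparisons use $10^{-10}$ (floats are serialized
with 12 significant digits).

# Known limitations

* The per-probe tests assume approximately normal log2 intensities;
  counts (RNA-seq) need different models and are out of scope.
* Raw-p filtering (the field's default, kept here) does not control FDR;
  use `adjust = "BH"` for error-rate guarantees.
* The hypergeometric pair test treats all MREs as exchangeable and
  ignores expression levels; it screens candidates, it does not
  establish ceRNA activity.
* Published headline counts of the modelled study (thousands of detected
  and differential circRNAs, specific term counts, network sizes) depend
  on undeposited raw arrays and dated annotation databases and are not
  reproduction targets; the worked example reproduces the printed top
  table's classification and validation fold changes instead.
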