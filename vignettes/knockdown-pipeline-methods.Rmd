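---
title: "Methods: single-replicate knockdown expression analysis with fetdeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-replicate knockdown expression analysis with fetdeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetdeg)
```

## The analysis problem

fetdeg analyses a class of experiment that is statistically awkward but
common in practice: a single-channel expression BeadChip hybridized with one
array per condition. The motivating design has six arrays — siRNA knockdowns
of the three FET-family RNA/DNA-binding proteins (FUS, EWS, TAF15), a triple
knockdown of all three, and two non-specific siRNA controls matched to the
single- and triple-knockdown siRNA concentrations. With n = 1 per condition
no variance-based test statistic exists; the pipeline instead implements the
deterministic decision rules that practitioners use in this setting, plus
resampling-based cluster support where resampling *is* possible (over genes,
not arrays).

The stages are:

1. **Quantile normalization** of the probe intensity matrix, forcing every
   array onto the common average distribution while preserving within-array
   ranks.
2. **Detection filtering**: a probe is kept iff its detection p-value (the
   probability its signal is indistinguishable from the negative-control
   probes) is below 0.05 in at least one array.
3. **Background estimation**: the pooled arithmetic mean of all
   negative-control intensities across all arrays, reported rounded to the
   nearest integer.
4. **Ratio DEG calling** per knockdown/control pair, on
   background-subtracted signals:
   `ratio = (treated - bg) / (control - bg)`. A probe is *up* iff
   ratio > 2 and the treated detection p < 0.05; *down* iff ratio < 0.5 and
   the control detection p < 0.05. All inequalities are strict.
5. **Set analysis**: exclusive Venn partitioning of the single-knockdown DEG
   sets, comparison against the triple knockdown, and a one-sided
   hypergeometric test for overlap with external gene lists.
6. **Cluster support**: SD-based gene selection, correlation-distance
   average-linkage clustering of the sample columns, and multiscale
   bootstrap giving AU (approximately unbiased) and BP (plain bootstrap)
   support per cluster.
7. **qPCR verification**: efficiency-based X0 quantification of Cq values,
   normalized to a housekeeping gene and expressed relative to a control
   sample.

## Design choices in the preprocessing order

The normalization/background order is fixed as: quantile-normalize the
regular probes, filter on detection, and estimate the background from the
**raw** negative-control intensities. Two deliberate deviations from a naive
reading deserve a note.

*Normalization covers regular probes only.* Negative controls have no
biological signal; letting their random rank interleaving perturb the
normalization of real probes adds noise with no benefit, and it breaks a
useful exactness property: in the no-effect, no-noise limit the pipeline
then yields ratios exactly 1 for every valid probe, which our tests rely on.

*Ratios are computed on normalized signals by default.* The decision rule is
stated in terms of raw intensities, but with one array per condition an
un-normalized ratio confounds chip brightness with biology. A `use_raw =
TRUE` switch in `call_degs()` preserves the literal raw-intensity reading;
both variants matter when trying to match historical DEG counts, and the
raw variant is also the sharper instrument when the treatment effect is
confined to one array (see "limits of quantile normalization" below).

## The synthetic-data generator

`simulate_experiment()` draws the six-array design with known ground truth
so that every stage is testable at desk scale. The model:

* per-probe baseline intensity: log-normal, `meanlog = 4.0`,
  `sdlog = 1.5` (intensity units; median about 55);
* per-array measurement noise: independent log-normal with
  `sdlog = 0.08`;
* negative controls: log-normal with mean 28 (`sdlog = 0.4`), drawn
  independently and identically in every array — their mean is the intended
  background;
* knockdown effects: multiplicative folds drawn uniformly from
  `fold_range = (2.5, 8)`, sign negative with probability
  `down_fraction = 0.56`;
* sharing structure: 14% of each single knockdown's effects are shared
  between siFUS and siTAF15 (7% by all three), with identical fold on the
  sharing groups; the triple knockdown inherits the union of single-group
  effects (same folds, not resampled) plus an independent triple-unique set
  sized so that 80% of its effects are unique to it;
* both controls are draws from the same null distribution: any divergence
  between them is noise, as in a well-behaved experiment;
* detection p-values are computed per array by the rank formula
  `(1 + #{controls >= x}) / (N + 1)` against that array's own negative
  controls.

The default fractions mirror the structure of the motivating six-array
study (a few hundred DEGs per single knockdown out of ~48,000 probes; about
1 in 7 shared between the FUS and TAF15 responses; most triple-knockdown
DEGs unique to it). The intensity scale parameters were calibrated once so
that the full-scale pipeline output resembles that study's reported figures
— roughly 45% of regular probes removed by detection filtering, and
single-knockdown DEG counts in the low hundreds — and are not meant to be
tuned per analysis.

Two modelling notes. First, effects are planted only on probes whose
baseline exceeds `fold_range[2] * negctrl_mean`: a down-regulation of an
already-unexpressed transcript produces a signal at or below background and
is unobservable under a ratio rule, so planting it would only make "truth"
unrecoverable by construction. Second, because the triple group inherits the
*full* union of single-knockdown effects, its planted set is much larger
than a real triple knockdown would show (real combined knockdowns reproduce
only a fraction of the single-knockdown responses); this is a deliberate
simplification — the generator's job is a known, structured truth map, not a
mechanistic model of combinatorial siRNA action.

What the generator does **not** emulate: bead-level variation, spatial/batch
effects, probe sequence biases, correlated noise between arrays, and
intensity-dependent variance beyond what the multiplicative log-normal noise
implies. Passing tests therefore demonstrate the pipeline's correctness
under a clean generative model, not robustness to artefacts of real chips.

## The multiscale bootstrap

Plain bootstrap support (BP) for a cluster — the fraction of resampled
datasets in which the cluster reappears — is biased: it is conservative for
large true clusters and the bias depends on the number of resampled rows.
The multiscale bootstrap estimates and removes this bias by resampling at
several sizes. For relative sizes `r` in 0.5 ... 1.4 (step 0.1, always
including 1) and `B = 1000` replicates per scale, each replicate draws
`ceiling(n * r)` probe rows with replacement, reclusters the samples, and
records whether each original cluster reappears. Writing `BP_r` for the
appearance fraction at scale `r`, the probit transform
`z_r = qnorm(1 - BP_r)` is fitted by weighted least squares to

    z_r = v * sqrt(r) + c / sqrt(r)

with per-scale weights `B / (BP_r (1 - BP_r))` (the inverse of the binomial
variance of `BP_r`). The two supports are then

    AU = 1 - pnorm(v - c)        BP = 1 - pnorm(v + c)

`v` is interpreted as a signed distance of the data from the cluster
boundary and `c` as the boundary's curvature; both are kept on each node for
diagnostics, together with the root-mean-square weighted fit residual.

Numerical safeguards: appearance fractions are clipped to
`[1/(B+1), 1 - 1/(B+1)]` before the probit transform so the fit is always
finite; clusters observed in every replicate at every scale are snapped to
`AU = BP = 1` (flag `at_ceiling`), clusters never observed to
`AU = BP = 0` (flag `never_observed`). A replicate whose resampled rows
leave some sample with zero variance (correlation undefined) counts as a
replicate in which no cluster reappears; with realistic data this is
vanishingly rare.

Reproducibility: one master seed deterministically derives a substream per
scale, and clusters are identified by their sorted member-label sets, so
supports are invariant to the order of the sample columns.

Distance and linkage are one minus the Pearson correlation between sample
columns and average linkage (UPGMA) — the conventional defaults for this
kind of expression clustering. The agglomeration is written with an explicit
deterministic tie-break (among equally close pairs, merge the pair whose
smallest member labels sort first) so that results are bit-reproducible even
on degenerate inputs; on tie-free data it agrees exactly with
`stats::hclust(method = "average")`.

### SD selection and the log scale

Clustering is preceded by `sd_select()`, which drops probes expressed
near-identically across all samples (either an absolute SD threshold or a
top-k selection; we default to top-k in examples because the threshold that
separates "similar" from "variable" depends on the intensity scale). Raw
BeadChip intensities are heavily right-skewed, and Pearson correlations on
the linear scale are dominated by a handful of very bright probes; analyses
in this package therefore log2-transform normalized intensities before SD
selection and clustering, which is standard practice for expression data.
The clustering functions themselves are scale-agnostic — they cluster
whatever matrix they are given.

### Limits of quantile normalization at n = 1 per condition

One property surfaced by the synthetic tests is worth knowing: when strong
effects are confined to a single array (the extreme single-replicate case),
quantile normalization must equalize that array's distribution against the
others, which compresses fold changes toward the thresholds and can slightly
inflate ratios of near-background probes whose ranks get displaced. With
effects spread over several arrays — the realistic case — the distortion is
mild, but exact planted-truth recovery in tests is asserted on the raw
scale, and sensitivity/false-positive bounds on the normalized scale.

## Set analysis

`venn_partition()` computes the exclusive membership regions of 2–4 DEG
sets; the partition invariants (regions pairwise disjoint, sizes summing to
the union) are property-tested on random sets. `compare_to_combined()`
reports, for each region of the single-knockdown partition, how many of its
members recur in the triple-knockdown DEG set, plus the count unique to the
triple. `enrichment_test()` formalizes "do our DEGs overlap this external
target list more than chance" as the one-sided hypergeometric upper tail
(Fisher's exact test in the enrichment direction); the sensible universe is
the number of probes that survived detection filtering, since only those
could have been called, and the choice of universe is the analyst's main
lever on the resulting p-value — it is an explicit argument, never a hidden
default.

## qPCR quantification

Cq values are back-transformed to linear-scale initial amounts
`X0 = E^(-Cq)` with the assay efficiency `E` in (1, 2] taken from standard
curves (default 2, i.e. perfect doubling). Technical replicates are averaged
on the X0 scale — the linear scale is the quantity of interest, and
averaging Cq instead would estimate a geometric mean. Relative expression is
the double ratio (target/reference in the sample) over (target/reference in
the control sample); with all efficiencies equal to 2 this reduces exactly
to the classic `2^(-ddCq)`, which the tests verify to 1e-12. Replicate
scatter is propagated to the result by first-order relative-variance
propagation across the four X0 means. Two structural invariants are tested:
adding a constant to every Cq cancels in the double ratio, and the result is
strictly decreasing in the sample target Cq.

## Problem sizes used in tests and the acceptance script

The packaged test suite runs entirely on synthetic data: normalization
oracles on 10 x 4 matrices, DEG recovery on 2,000–5,000-probe experiments,
1,000 random set triples, bootstrap calibration at B = 200, and the
clustering topology claim over 10 generator seeds. `scripts/acceptance.R`
re-runs the pipeline at the full design scale (48,803 probes, B = 1000
bootstrap replicates) and writes the headline quantities as JSON. These
sizes were chosen to exercise every code path at full fidelity while keeping
a complete run in the order of a minute.

## Known limitations

* The ratio rule has no error control; its false-positive behaviour depends
  entirely on the noise level and the proximity of signals to background.
  The package reports counts and recovery rates, not significance, for DEG
  calls.
* Detection p-values on real arrays come from vendor software and are used
  as-is; `compute_detection_p()` exists to equip synthetic data with
  comparable calls, not to reproduce the vendor algorithm.
* The SD cut-off for gene selection before clustering is a free parameter
  with no principled default; results should be reported together with the
  selection used.
* Probe-to-gene mapping is out of scope: the counting unit is the probe,
  with an optional `collapse_to_genes()` convenience when a mapping is
  supplied.
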