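---
title: "Sliding-window differential binding: models and methods"
author: "windowdb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window differential binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

windowdb detects genomic regions whose protein binding changes between
experimental conditions in replicated ChIP-seq experiments, without calling
peaks first. Peak-based pipelines condition the tested intervals on the data
used to test them, which breaks type I error control; here every fixed-width
window on a regular grid is a candidate, windows are tested with count-based
GLMs, and neighbouring windows are aggregated into regions in a way that
keeps the false discovery rate controlled over the regions actually
reported.

The package implements the full chain — fragment counting, background
filtering, normalization, window-level quasi-likelihood tests, region-level
aggregation — plus negative-binomial read simulators for broad
(histone-mark-like) and sharp (transcription-factor-like) binding and an
evaluation harness that scores detections against simulated truth.

# Counting model

Single-end reads are directionally extended to the average fragment length
$f$ (a parameter, default 100 bp): a forward read at 5' position $p$ becomes
the fragment $[p, p+f)$ and a reverse read with 5' end at $p$ becomes
$[p-f+1, p+1)$, in 0-based half-open coordinates throughout. Paired-end
fragments are the interval spanned by an inward-facing pair on one
chromosome spanning at most `max_span` (600 bp default). The count for
window $w$ in library $j$ is the number of library-$j$ fragments overlapping
$w$ by at least 1 bp. Windows have width 150 bp and spacing 50 bp by
default; the width is chosen on biological grounds (roughly the DNA span
protected by a nucleosome; 10–50 bp suits transcription factors) and the
grid is anchored at position 0 of each chromosome.

Because a fragment is counted whenever its 5' end lies within $f-1$ bp of
the window, a width-$W$ window effectively collects reads from a
$W + f - 1$ bp footprint. This *effective width* appears wherever window
and bin counts are compared.

# Background filtering

Non-specific enrichment is estimated from counts in large bins (2 kbp by
default). Per-region abundance is the average library-size-adjusted count
rate on a log2 counts-per-million scale,
$$A = \log_2(\mathrm{CPM} + a),$$
with a pseudocount $a = 2$ CPM. Putting the pseudocount on the CPM scale
(rather than on raw counts) makes $A$ exactly invariant to a joint
rescaling of counts and library sizes and gives the zero-count floor
$\log_2 a$.

The background estimate is the median bin abundance after downscaling the
bin *rates* by the width ratio $2000/(W+f-1)$ **before** the pseudocount is
added. The order matters: downscaling the abundance after adding the
pseudocount understates the background exactly when windows are narrow and
their counts are comparable to the pseudocount, which floods a 10–50 bp
analysis with noise windows. Scaling the rates first means the background
value is precisely the abundance that a window of pure background coverage
would show. Windows are kept when their abundance exceeds the scaled
background by `filter_fold` (two-fold, i.e. 1.0 log2 units) or more.
Filtering uses only abundances, never the design, so it does not bias the
downstream tests.

# Normalization

Three modes are available and are mutually exclusive per run:

* **none** (default): library sizes only. Appropriate for balanced designs
  with no composition bias — including the built-in simulations, where DB
  is introduced symmetrically in both groups.
* **tmm**: trimmed mean of M-values computed on 10 kbp bin counts,
  unweighted (no precision weights), trimming 30% of M-values and 5% of
  A-values from each tail, with the reference library chosen by the
  upper-quartile rule. Bin-level TMM removes composition bias from
  genome-wide shifts in bound material. Running it instead on
  high-abundance windows corrects immunoprecipitation-efficiency
  differences; that variant is available by passing window counts to
  `tmm_factors()`.
* **loess**: per-entry log2 offsets from a loess fit of M against A per
  library (against an average pseudo-reference), recentred to zero row
  means, for trended biases that a single factor cannot capture. Offsets
  subsume library-size scaling and therefore cannot be combined with TMM
  factors.

Neither mode ever modifies the counts; factors and offsets are consumed by
the GLM offsets.

# Window-level testing

Counts for window $i$, library $j$ follow a negative binomial model
$\mathrm{var}(y_{ij}) = \mu_{ij} + \phi_i \mu_{ij}^2$ with
$\log \mu_{ij} = x_j^T\beta_i + o_{ij}$, where $o_{ij}$ is the log
effective library size (plus loess offsets when used) and the design matrix
may encode arbitrarily complex experiments, provided at least one residual
degree of freedom remains.

**NB dispersion trend.** $\phi$ is modelled as a smooth function of
abundance. Windows are grouped into up to 20 abundance bins (at least ~200
windows each); within a bin the Cox–Reid adjusted profile likelihood —
NB log-likelihood at the fitted coefficients minus
$\tfrac12\log\det(X^TWX)$ — is summed over windows on a shared 15-point
dispersion grid spanning $[10^{-6}, 5]$, and maximized with quadratic
interpolation on the log grid. Per-bin estimates are smoothed with lowess
and interpolated; evaluation outside the observed abundance range clamps
to the boundary value. With fewer than 200 windows a single global
estimate is used. The recovery tests (constant $\phi = 0.05$ recovered
within [0.03, 0.07]; Poisson data driven below 0.01) establish the
adequacy of this estimator; it is not claimed to be numerically identical
to any other trend fitter.

**GLM fitting.** All windows are fitted simultaneously by vectorized
iteratively reweighted least squares sharing one design matrix, with
per-window step halving (up to 10 halvings) whenever a step would increase
the deviance, convergence at a relative deviance change below $10^{-8}$,
and a cap of 50 iterations.

**Quasi-likelihood dispersions.** The raw QL dispersion is
$s^2_i = D_i/d$, the residual deviance over the residual degrees of
freedom. A trend in $s^2$ against abundance is fitted and each estimate is
shrunk towards it,
$$\tilde s^2_i = \frac{d_0\, s^2_0(A_i) + d\, s^2_i}{d_0 + d},$$
with the prior degrees of freedom $d_0$ estimated by moment-matching the
spread of $\log s^2$ around the trend to a scaled F distribution
(limma's `squeezeVar`). The **robust** variant of this fit is the default:
it winsorizes outlier dispersions before moment matching. This matters
greatly when true dispersions are heavy-tailed across sites — exactly the
situation the simulators create by drawing $\phi_i$ from an inverse
chi-squared distribution — because a non-robust fit lets the tail inflate
the apparent spread, collapses $d_0$ to single digits, and leaves the
F-test too weak to detect anything after multiplicity correction.

**F-test.** For a contrast with $k$ constraints,
$$F = \frac{(D_{\mathrm{null}} - D_{\mathrm{full}})/k}{\tilde s^2}$$
is referred to an F distribution on $(k,\, d_0 + d)$ degrees of freedom.
The finite denominator df accounts for the uncertainty of the dispersion
estimates, which is what keeps the procedure from becoming liberal when
dispersions vary between sites; $d_0 = \infty$ recovers the
chi-squared/df reference. Contrast vectors are reparameterized into a
coefficient (via limma) so that the null model is always a nested
column-drop.

# Region-level FDR

Windows are clustered left to right: a window joins the current cluster
when its gap to the cluster's right boundary is at most `merge_tolerance`
(100 bp; gap = next start − cluster end, so abutting windows merge even at
tolerance 0) and the resulting span stays within `max_region_width`
(5 kbp). When a window would push the span beyond the cap the chain is cut
and a new cluster starts at that window — a greedy rule; other splitting
conventions exist and could shift region boundaries slightly.

Member P-values are combined with Simes' method,
$p_{\mathrm{region}} = \min_j \; n\, p_{(j)}/j$, a valid test of the
global null for the region, and the Benjamini–Hochberg step-up procedure
is applied to the combined P-values, so the FDR is controlled across
*regions*, the unit actually reported. Each region also reports its most
significant window (ties broken by larger |logFC|, then leftmost) and a
direction label derived from the logFC signs of the members at or below
the Simes-minimizing member P-value; the label is descriptive only.

# Simulators

Both designs use two groups of two libraries on one chromosome sized to
hold the requested sites at spacings drawn uniformly from 10–20 kbp, plus
margin, and layer non-specific background over the sites: 2 kbp bins with
means drawn once from Uniform(10, 50) and dispersions from
$1/\chi^2_{20}$, reused across all libraries so the background is null by
construction.

* **Complex (histone-like):** each site is three overlapping 500 bp
  subintervals offset by 250 bp (1 kbp footprint); per subinterval and
  library the read count is NB(30, $\phi_i$) with $\phi_i \sim
  1/\chi^2_{20}$ (unscaled; mean $1/18 \approx 0.056$, a realistic
  biological CV — the distribution's scaling is a modelling choice here,
  fixed once), and read positions follow a scaled Beta(2, 2) within the
  subinterval with random strands. DB removes all reads of one or two
  randomly chosen subintervals from one group at 500 sites per group
  (disjoint sets, so composition stays balanced); the truth records the
  removed subintervals.
* **Sharp (TF-like):** point sites where forward-read 5' positions fall at
  $c_i - fX$ and reverse at $c_i + fX$, $X \sim \mathrm{Beta}(2,2)$ —
  inward-facing reads whose extensions pile over the site, reproducing
  strand bimodality. Counts are NB with means 30/30 (non-DB) and 45 vs 15
  for 500 DB sites per direction. The fixed-dispersion variant sets
  $\phi = 0.05$ everywhere with means 10 and 20 vs 0, the regime where
  dispersion-estimation uncertainty should matter least.
* Scoring: a detected region is a true positive only if it overlaps a DB
  *subinterval* (not merely a site footprint); power is the fraction of DB
  sites whose subinterval is overlapped. Replicates with zero detections
  contribute zero power and are excluded from FDR averages, with the
  exclusion count reported.

The simulators emulate count overdispersion, uneven background, binding
shape, and strand structure. They do **not** emulate duplicate reads,
mappability artefacts, GC bias, chromosome structure, or input/control
libraries; passing tests on them demonstrates the statistical pipeline's
operating characteristics under the stated model, not robustness to every
real-data pathology.

# Numerical and design details

* IRLS: damped as above; means floored at $10^{-10}$, linear predictors
  clamped to $\pm 45$.
* $s^2$ floor $10^{-8}$ guards saturated zero-deviance fits; $d_0$ is
  capped at $10^6$ when finite, and an infinite $d_0$ collapses
  $\tilde s^2$ onto the trend exactly.
* Effective width $W + f - 1$ for bin-to-window rescaling, as derived in
  the counting section.
* Duplicate reads are kept by default (marking-based removal is optional),
  mapping-quality filtering defaults to off, and secondary/supplementary
  alignments are always skipped.
* Single-end reverse reads have their 5' end at the rightmost aligned
  base; extension proceeds leftward.
* Simulated BAM records use a 50 bp read length with dummy base calls;
  counting re-extends reads to $f$, so record length affects only the
  alignment files.
* All randomness is consumed through R's RNG under a caller-supplied seed;
  simulators and the pipeline are byte-reproducible.

# Problem sizes used for verification

The package's test suite and the bundled acceptance script reproduce the
simulation studies at one quarter of the published genome (5,000 sites,
125 DB sites per group, ~75 Mbp, three replicate datasets), a size chosen
so the complete verification runs comfortably on a laptop while keeping
the DB-site fraction, count depths and all distributional parameters at
the study conditions. FDR and power at this scale match the full-scale
values to within Monte-Carlo error, since the BH threshold depends on the
ratio of true to total regions rather than on their absolute number.

# Interface

The package is used from R, like the analysis packages it builds on:
`run_pipeline()` / `run_pipeline_sim()` compose the exported stage
functions (`count_windows`, `filter_windows`, `tmm_factors`,
`window_test`, `region_results`, …), configurations live in plain YAML
key-value files (`load_config`/`save_config`), and results are classed
objects with `print`, `summary`, `coef` and `plot` methods plus TSV/BED
writers. No shell entry point is shipped; scripts/acceptance.R shows the
package driven non-interactively.

# Known limitations

* Fragment-length estimation (e.g. by cross-correlation) is out of scope;
  $f$ is supplied by the user.
* One window width per run; multi-resolution consolidation across widths
  is not implemented.
* No input/IgG control handling.
* Only the QL F-test is offered (no exact or likelihood-ratio tests).
* The dispersion-trend fitter is a documented approximation validated by
  recovery tests, not an exact re-implementation of any external tool.
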