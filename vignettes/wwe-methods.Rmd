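---
title: "Calling differentially methylated regions by coverage-weighted Welch expansion"
author: "wwedmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differentially methylated regions by coverage-weighted Welch expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wwedmr)
```

## The problem

Bisulfite sequencing reports, per cytosine and per sample, a methylated
read count and a total coverage.  Differentially methylated regions
(DMRs) are contiguous stretches where methylation differs between two
groups of samples.  Two features of the data shape the method: counts at
one CpN are binomial-like with very unequal and informative coverage
across replicates, and biologically meaningful differences extend over
runs of neighbouring CpNs rather than isolated sites.

## Model and statistic

Let replicate $r$ of a group have coverage $C_r$ and methylated count
${}_mC_r$ at a site.  The group methylation level is the
coverage-weighted mean
$$\bar m = \frac{\sum_r C_r \,({}_mC_r/C_r)}{\sum_r C_r}
        = \frac{\sum_r {}_mC_r}{\sum_r C_r},$$
i.e. the pooled fraction, and the between-replicate variance weights the
squared deviations of replicate fractions $m_r={}_mC_r/C_r$ the same way:
$$s^2 = \frac{\sum_r C_r (\bar m - m_r)^2}{\left(\sum_r C_r\right) - 1}.$$
With unit coverages $s^2$ reduces to the ordinary unbiased sample
variance, which the tests exploit as an oracle case.

Groups A and B are compared with a Welch-type statistic
$$t = \frac{\bar m_B - \bar m_A}{\sqrt{s_A^2/R_A + s_B^2/R_B}},$$
two-tailed, with Welch–Satterthwaite degrees of freedom.  Two choices
here were genuinely open and are deliberate:

* **$R_A$, $R_B$ are replicate counts, not total coverages.**  Coverage
  already enters through the weighting of $\bar m$ and $s^2$; using
  total reads as the sample size would count the same information twice
  and inflate the degrees of freedom to absurdity at deep coverage.
* **Degrees of freedom** follow Welch–Satterthwaite with per-group terms
  $s^2/R$, the standard companion to the unequal-variance statistic.

A Welch test needs at least two replicates per group.  With a single
replicate on either side, `site_p_value()` falls back to a two-tailed
Fisher's exact test on the pooled per-group 2×2 table
(methylated/unmethylated × group).  The two-tailed p sums hypergeometric
point probabilities not exceeding the observed one; ties are compared
with a $1+10^{-7}$ relative tolerance, the convention of
`stats::fisher.test`, so the two implementations agree to machine
precision (the suite checks this by exhaustive enumeration on all tables
with total ≤ 40).

Degenerate sites (both weighted variances zero) would produce 0/0; the
caller instead assigns $p = 1$ when the means are equal and $p = 0$
otherwise, with a warning.  This keeps perfectly separated
deep-coverage sites callable rather than propagating `NaN` into region
assembly.  Sites with zero total coverage in a group, or an undefined
variance, get `NA` statistics and are simply never qualifying.

## The expansion scan

A site **qualifies** when three site criteria hold: every replicate in
both groups reaches `min_coverage` (default 10 reads); the absolute
difference of weighted means reaches `min_diff` (default 10 percentage
points); and the two-tailed p is at most `max_p` (default 0.05).  Per
chromosome, a single left-to-right pass then:

1. opens a candidate at a qualifying site, whose sign of difference
   fixes the region's direction;
2. expands over subsequent sites while qualifying sites keep that sign,
   tolerating up to `max_similar` (default 5) consecutive non-qualifying
   sites in the interior;
3. terminates when the tolerated run is exceeded, when a qualifying site
   of the *opposite* sign appears (that site immediately seeds the next
   candidate), when the distance to the previous site exceeds `max_gap`
   (default 20 000 nt, measured between consecutive sites included in
   the candidate; a site exactly at the limit is still included), or at
   the chromosome end;
4. shrinks back to the last qualifying site, so both boundaries qualify;
5. emits the region if it has at least `min_cpn` qualifying CpNs
   (default 5) and spans at least `min_span` nucleotides (default 0).

Three edge rules are worth stating because any choice was defensible:

* **Direction consistency.**  A region never mixes hyper- and
  hypomethylated qualifying sites; a sign flip closes one region and
  opens the next.  Mixed-sign "regions" are biologically incoherent.
  As a corollary, a site with a difference of exactly zero (possible
  only when `min_diff = 0`) is treated as non-qualifying.
* **Coverage failures count as "similar" sites** — one uniform
  non-qualifying category keeps the automaton simple and predictable.
* **No re-scanning.**  A candidate rejected at emission (too few CpNs or
  too short) is not revisited; any sub-run would be a subset and fail
  the same thresholds.

The production scan is a vectorised-statistics + single-loop automaton;
the test suite pins it, on a thousand random instances with randomised
criteria, against an independently written brute-force walker, and
checks determinism, non-overlap, qualifying boundaries and criterion
monotonicity as properties.

Each emitted region is then summarised by `region_test()`: per
replicate, counts are summed over the region's aligned sites, and the
same dispatch (Welch or Fisher) runs on the aggregated counts — a
single-site region reproduces the site test exactly.  Aggregation to
region level, rather than combining site p-values, keeps the region
statistic on the same coverage-weighted footing as the site statistic.
Benjamini–Hochberg adjustment is applied across all regions of one run
(all chromosomes jointly): one analysis, one multiple-testing family.

## Input handling

Five count-table dialects are registered (Bismark coverage, Bismark
cytosine report, methylKit-style, ENCODE bedMethyl-style, generic TSV);
the registry is extensible via `register_dialect()`.  Detection uses the
column count and a column-type signature of the first recognisable data
line; a tie between dialects is an error, never a silent guess.
Internally all coordinates are 1-based inclusive; BED input/output
converts at the boundary, which confines off-by-one risk to the readers
and writers (all of which are round-trip tested).  Percent-based
dialects convert with `round(percent/100 × coverage)`, half away from
zero, which makes the conversion deterministic and exactly invertible
for files the package wrote itself.  Zero-coverage records are kept at
read time — filtering is the caller's job, through the coverage
criterion.  Groups are aligned on the intersection of sites present in
*every* sample; partially observed sites are a known source of spurious
calls, so no union or imputation mode is offered.  CpG strand merging
(`merge_cpg_strands()`, summing a +-strand C with the −-strand C one
position downstream) is exposed as an explicit, optional step since
upstream pipelines differ in whether they pre-merge.

## The simulator: what it emulates and what it does not

`simulate_methylation()` generates the canonical overdispersed model for
methylation counts: a latent site mean, Beta-distributed replicate
fractions around it with dispersion `rho`
($\alpha=\mu(1-\rho)/\rho$, $\beta=(1-\mu)(1-\rho)/\rho$), negative
binomial coverage, binomial methylated counts.  Defaults were fixed
once, on realism grounds, before any benchmarking:

* **Background methylation Beta(0.3, 0.3).**  Genome-wide CpG
  methylation is strongly bimodal — most sites are nearly fully
  methylated or nearly unmethylated — and a symmetric Beta with shape
  well below 1 is the simplest distribution with that character.
* **`rho` = 0.01**: isogenic biological replicates are tightly
  concentrated around the group mean.
* **Coverage NB(mean 30, size 20)**: the narrow spread typical of
  artificial benchmark data; `coverage_size = 2` gives the much wider
  spread of real WGBS, useful for exercising the coverage-weighting
  rationale.
* **Planted regions** replace the background mean with a base level
  drawn from U(0.1, 0.35) and shift group B by `delta`; the base range
  keeps a shift of up to +0.65 away from the clipping boundary, so the
  realised effect equals the nominal one.

All draws are quantile transforms of one seed-fixed uniform stream whose
length depends only on structural parameters.  Two consequences matter:
byte-identical reproducibility from `(config, seed)`, and *comonotone
coupling* across `difficulty_series()` levels — datasets at different
`delta` share coordinates, truth placement and coverages, and their
methylation counts are ordered in `delta` site by site, so
recall-versus-difficulty curves are monotone by construction rather than
up to simulation noise.

The simulator does **not** emulate reads or mapping (no bisulfite
conversion error, no mapping bias), non-CpG contexts, correlated
neighbouring sites, or mixtures of cell types.  Passing the recovery
tests therefore demonstrates that the caller finds what its model class
plants at the stated effect sizes and coverages — not performance on any
particular real methylome.

## Benchmarking conventions

Intervals are 1-based inclusive, lengths `end − start + 1`.  A predicted
region overlapping any truth region by ≥ 1 nucleotide is one true
positive (and every truth region it touches counts as found); precision,
recall and F1 follow, with 0/0 reported as `NA` and F1 = 0 when either
component is 0.  The directional *overlay* of a query interval is the
percentage of its nucleotides covered by the reference set — asymmetric
by design, and more informative than a Jaccard index because the two
directions separate boundary over-extension from under-coverage.  Gene
annotation uses the edge-to-edge coordinate difference (0 when
overlapping, default radius 15 000 nt), reporting *all* genes in range
sorted by distance.

## Problem sizes and numerical tolerances in the test suite

The suite runs the recovery benchmark at 50 000 sites × 5 seeds
(Δ = 0.6, 3 vs 3, coverage 30, 20 planted DMRs), the null calibration at
50 000 sites × 10 seeds, the graded series at Δ ∈ {0.6, 0.4, 0.2, 0.1}
on shared coordinates, and the scan-versus-oracle comparison on 1 000
random instances of up to 200 sites — sizes chosen so the full suite
completes in a couple of minutes on one core while leaving each estimate
well-determined.  Oracle comparisons use 1e-12 (enumeration, BH) or
1e-10 (Welch vs. the classical implementation) absolute tolerances;
region equality checks are exact.

## Known limitations

* The region p-value treats the region as if it had been pre-specified;
  because boundaries are data-chosen, region p and q are ranking scores
  with an optimistic bias, best used comparatively.
* The Welch test's type-I control is approximate at very small replicate
  counts and extreme methylation levels (fractions are bounded and
  skewed there); the null-calibration property test bounds the practical
  consequence at the region level.
* Single-replicate designs lose the variance component entirely: the
  Fisher fallback tests pooled counts and cannot distinguish biological
  from sampling variability.
* The caller is context-agnostic (CpG/CHG/CHH are treated alike); any
  context filtering happens at read time via the reader's `context`
  flag.
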