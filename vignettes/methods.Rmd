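---
title: "Models and methods behind selfmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind selfmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

selfmix analyses whole-genome haploid panels from a species pair in
which a highly selfing taxon recently derived from an outcrossing
progenitor and the two still hybridize. This vignette explains the
models each stage implements, the parameters that matter, the design
choices made where the field's practice is genuinely open, and what the
synthetic-data tests do and do not establish about real data.

## Data model and filtering

Samples are fully inbred lines, so diploid genotype calls collapse to
haploid alleles; residual heterozygous calls (typically ~1–2% of SNPs)
are resolved by choosing one allele uniformly at random under an
explicit seed (`resolve_heterozygotes`). Coordinates are 0-based
half-open internally; VCF I/O converts to and from the 1-based VCF
convention.

The filter cascade (`apply_site_filters`) guards against collapsed
paralogs and mismapping: calls below 10 reads are set missing; calls
whose depth is more than 2 SD from the sample's mean depth are censored
(mean and SD taken over calls passing the minimum-depth cutoff — the
order is fixed so the cascade is idempotent; whether censoring should be
per sample or pooled across samples is not settled practice, and the
per-sample two-sided form is implemented); sites with more than two
alleles among the retained calls are dropped. Invariant callable sites
stay in the panel: they carry the denominators of every π estimate.

Degeneracy classes (`classify_degeneracy`) follow the standard genetic
code, strand-aware; a site whose class depends on another polymorphic
position in the same codon is classified against the reference codon.

## Diversity, windows, uncertainty

π between two samples is mismatches over co-called sites of the
requested degeneracy class. Windows default to 5 kb with a 1 kb slide;
windows with fewer than `min_sites` informative sites (default 100 per
window — a configurable knob, since no canonical cutoff exists for
"insufficient density") are flagged and excluded from summaries.
Windows anchor at position 0, and a final partial window is kept when at
least half a window remains. Linked variants violate i.i.d. standard
errors, so intervals come from a 100 kb block bootstrap; each resampled
block becomes its own pseudo-chromosome so window arithmetic and
callable lengths stay coherent under resampling.

## Closed-form timescales

With mutation rate μ per bp per generation (default 1.5e-8, generation
time 1 year):

* split time `τ = (π_between − π_anc) / 2μ` generations, ancestral
  diversity proxied by a present-day population;
* `π / 2μ` is an effective number of chromosomes (within-population π)
  or a divergence time (between sequences);
* a lineage pair avoids coalescence past generation `t` with probability
  `e^{−t/Ne}`, inverted by `solve_N`;
* the selfing rate follows Nordborg's argument that selfing divides the
  population-scaled recombination/mutation ratio by `1 − F`: comparing
  the selfer's fold-reduction in Ne with its fold-expansion in the
  physical scale of LD decay gives `1 − F`, and `s = 2F/(1 + F)`.

LD decay (`ld_profile`) bins pairwise `r²` by physical distance. "Half
decay" has no canonical formula; it is operationalized as the first bin
at or below the midpoint between the shortest-distance bin and the
asymptotic floor (mean of the last 10% of bins). With n samples the
floor sits near the 1/(n−1) estimation bias, not at zero.

## The ancestry HMM

The observation for a focal (potentially admixed) genome is, per
non-overlapping 1 kb window, the pair (k, n): mismatches to the
*closest* donor-panel sample and the number of informative sites.
Minimum divergence to a panel is what distinguishes a recently
introgressed tract (near the selfer's low within-taxon diversity) from
the deep interspecific background.

Emissions: the genome-wide distribution of per-site mismatch rates is
estimated separately for the two states — donor-vs-closest-donor
windows for the donor state, recipient-vs-closest-donor windows for the
recipient state — as a 50-bin weighted histogram with a 0.5 pseudo-count
per bin; the likelihood of (k, n) under a state is the binomial mixture
`Σ_b w_b Binom(k; n, p_b)`. The histogram absorbs genome-wide
heterogeneity in informative-site density; the binomial absorbs each
window's own n. When the focal minima run over m donors but a reference
distribution was built from minima over fewer (the donor panel compared
to itself loses one comparison), the reference is resampled toward
min-of-m with 10,000 seeded draws; the adjustment randomizes the number
of draws so the *expected* number of comparisons matches m — an
approximation chosen because the underlying single-comparison
distribution is not identified from minima alone.

Transitions depend on the admixture proportion α and r, the per-window
recombination probability times generations since admixture:
`t[rec,rec] = (1−r) + r(1−α)`, `t[rec,don] = rα`, `t[don,rec] = r(1−α)`,
`t[don,don] = (1−r) + rα`. r is constant across windows — recombination-
rate variation is deliberately ignored in the transition model. The
initial distribution is the stationary `(1−α, α)`. Missing windows emit
likelihood 1 in both states while the chain still advances one window,
preserving genome geometry.

Decoding uses scaled forward–backward recursions (compiled); per-window
scaling keeps chains of 10⁵+ windows in range, and the scaled posteriors
match exact arithmetic to ~1e-12 on enumerable chains. `(α, r)` are fit
by Nelder–Mead on logit-transformed parameters (unconstrained search),
with 5 spread restarts and a 1e-8 relative tolerance; the fit never
returns a likelihood below its starting point.

## Admixture blocks and dating

Blocks are maximal runs of windows with donor posterior above 0.95;
healing optionally bridges gaps of 0/20/50/100 kb (transitively), with
the healed length spanning the merged extent by default (a
sum-of-parts option exists). Physical lengths convert to map lengths
linearly (default 1,470 cM over 260 Mb) or through a supplied map.

Under a single admixture pulse v generations ago, tract lengths are
exponential with mean 1/v Morgans, so `T = 1/mean(Morgans)` dates the
pulse. Two systematic effects matter when tracts are short relative to
the window grid. First, a window-grid caller reports the union of
windows overlapping a tract, overshooting true length by about one
window; `block_mean_length` subtracts one window (floored at half a
window), a correction that is negligible for ~132 kb tracts over 1 kb
windows but material in scaled-down simulations. Second, independently
labelled adjacent segments merge into runs, so observed runs have mean
`1/(v(1−α))` rather than `1/v` — a ~15% compression at α = 0.15 that the
single-pulse reading inherits; the truth generator records
breakpoint-level segments so both views are testable.

The dispersion test bootstraps blocks (1,000 resamples) and reports the
proportion of resamples in which the squared mean exceeds the variance;
exponential lengths give ~uniform p-values (≈5% rejection), while
mixtures of pulse ages are overdispersed and reject. The chunk
arithmetic `X = vL + C` (map length L Morgans, C chromosomes) and the
per-ancestor expectation `X / 2^v` are computed in log2 space — `2^150`
is far beyond double-precision integers.

## Introgression tests

The four-population D uses sample allele frequencies on a common
biallelic site set, `D = Σ(y−z)(w−x) / Σ(y+z−2yz)(w+x−2wx)`, signed so
that excess sharing between the sympatric recipient (Y) and the donor
taxon (W) is positive; the statistic is antisymmetric under Y↔Z and
W↔X and invariant to allele relabelling. Significance comes from a
delete-one-chromosome jackknife in the weighted (Busing) form, since
chromosomes contribute unequal site counts. Note the denominator
requires polymorphism shared across the species split: D is informative
in the regime where diversity predates the split.

The outlier scan exploits the selfer's near-identity across most of the
genome: windows where exactly one sample exceeds 1% divergence to all
others, while the others stay mutually similar, merge into regions kept
at ≥20 kb. For each region the outlier's divergence to a candidate
source is compared against the non-outliers' mean divergence (a strict
all-must-be-farther variant exists; the mean is the default because the
non-outlier summary is not pinned down by practice); ties drop out of n,
and k of n successes go to an exact one-sided binomial tail at 1/2 —
under incomplete lineage sorting alone the outlier is closer half the
time.

## Recombination–divergence correlation

Local recombination rates are interpolated cM differences across 100 kb
windows (piecewise-linear, clamped at terminal markers to avoid negative
extrapolated rates), smoothed by the mean over the centred five-window
span with edge windows using the neighbours that exist. Divergence is
joined by window coordinates; windows with fewer than 100 informative
comparisons or no map coverage are excluded, and Spearman's ρ is
reported. Covariate controls (outgroup divergence as a mutation-rate
proxy; mean depth) recompute the correlation on rank-regression
residuals and within covariate quartiles — a documented stand-in, since
the canonical control procedure is not fully specified in the
literature this design follows.

## The synthetic-data generator

`simulate_unlinked_loci` is a per-locus Kingman coalescent for a
two-population split (sizes default to `π/2μ` chromosomes and
`τ = Δπ/2μ`), with optional stepwise bottleneck and migration pulse;
infinite-sites mutations fall on branches at `μ` per bp. It reproduces
`E[π] = θ` and `E[π_between] = π_anc + 2μτ` and underlies the D-test
null calibration.

`simulate_admixed_genome` builds mosaics Markovianly: Poisson
breakpoints at v per Morgan along a uniform map (chromosome ends always
break), each segment independently donor with probability α, no
back-coalescence of segments — deliberately matching the block-length
arithmetic rather than a full ancestral recombination graph. Donor
segments carry a shared donor-consensus divergence (rate `π_between`
from the recipient consensus); every genome adds private variation at
rate `π_within`. All randomness flows from explicit config seeds through
derived substreams; global RNG state is never touched.

Default conditions are the study system's: a 260 Mb, 14-chromosome
genome, 14.7 Morgans, μ = 1.5e-8, conspecific diversity 0.003,
heterospecific divergence 0.04, pulse α = 0.15 at v = 150. Test and
acceptance simulations keep every rate, the map length and the pulse but
run a 30 Mb genome (mean donor tract ≈ 16 kb ≈ 16 windows) — chosen once
so a 50-replicate recovery study stays tractable; D-null replicates use
280 independent 10 kb loci across 14 chromosomes with diversity at the
outcrosser's level (4.45%) and divergence 4.94%, the regime in which D's
denominator is populated.

What passing these tests shows: the estimators are consistent under
their own generative assumptions at realistic parameter values, the HMM
decodes mosaics with >95% per-window accuracy when divergence exceeds
diversity ten-fold and blocks span ≥10 windows, and the test statistics
are calibrated under their nulls. What they do not show: robustness to
alignment artefacts, depth-correlated error, gene conversion,
recombination-rate heterogeneity inside the transition model, selection
on tract survival, or back-coalescence of tracts — all absent from the
generator by design.

## Numerical notes and degenerate inputs

Zero informative sites yield flagged `NA`s, never silent zeros (π,
emission windows, D's denominator). Emission pseudo-counts keep
likelihoods positive; forward scaling aborts loudly on impossible data.
`logit`-scale optimization keeps `(α, r)` interior; fits at the boundary
report α ≤ 0.01 when no window looks donor-like. The dispersion test
needs ≥2 blocks, the jackknife ≥3 chromosomes, the rank correlation ≥10
joined windows; each errors informatively below its minimum. Bootstrap
resamples on which a statistic is undefined are redrawn and counted, and
a guard aborts if the statistic is undefined on most resamples.
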