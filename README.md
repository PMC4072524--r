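# selfmix

Population-genomic analysis of a predominantly selfing species and its
outcrossing progenitor, from multi-sample haploid (inbred-line) genotype
panels. The package targets the classic question set around a recent
origin of selfing with ongoing hybridization — as in the yellow
monkeyflowers, where a selfer (*Mimulus nasutus*-like) budded from a
structured outcrossing population (*M. guttatus*-like) a few hundred
thousand generations ago and the two still exchange genes in sympatry —
and makes every stage runnable on synthetic data with known truth.

## What it computes

* **Filtering and annotation** — the inbred-line filter cascade (minimum
  depth 10, per-sample ±2 SD depth censoring, multiallelic-site removal,
  random resolution of residual heterozygotes) and codon-degeneracy
  classes (0/2/3/4-fold) from gene models and a reference sequence.
* **Diversity and divergence** — pairwise π per degeneracy class with
  co-called-site denominators, sliding windows (5 kb / 1 kb slide),
  100 kb block-bootstrap confidence intervals, polarized allele-frequency
  spectra, and shared/private/fixed variant partitioning.
* **Closed-form timescales** — split time `τ = Δπ / 2μ`; the coalescent
  scale `π / 2μ` read as effective chromosomes or divergence time;
  `e^{-t/Ne}` non-coalescence with its inverse; the Nordborg selfing-rate
  estimate `1 − F = (Ne ratio)/(LD ratio)`, `s = 2F/(1+F)`; LD decay
  profiles with a half-decay distance.
* **Ancestry HMM** — two-state (recipient/donor) hidden Markov model on
  windowed minimum divergence to a donor panel (1 kb windows), emissions
  as binomial mixtures over genome-wide reference histograms, transitions
  `t = f(α, r)`, scaled forward–backward posterior decoding (Rcpp), and
  Nelder–Mead fitting of `(α, r)` on the logit scale.
* **Admixture blocks** — >95%-posterior block extraction, gap healing
  (0/20/50/100 kb), bp→cM conversion, tract-length dating
  `T = 1/mean(Morgans)`, a bootstrap dispersion test of the single-pulse
  model, and the `X = vL + C` genome-chunk arithmetic.
* **Introgression tests** — the four-population D statistic
  `D = Σ(y−z)(w−x) / Σ(y+z−2yz)(w+x−2wx)` with a delete-one-chromosome
  weighted jackknife, and the single-outlier scan (>20 kb regions where
  one selfer sample exceeds 1% divergence to all others) with an exact
  one-sided binomial test against the 50% incomplete-lineage-sorting
  expectation.
* **Recombination scan** — 100 kb windowed map rates smoothed over
  500 kb, Spearman correlation with windowed divergence, and
  rank-residual / stratified covariate controls.
* **Synthetic data** — a Kingman coalescent for unlinked loci (two
  populations, bottleneck, migration pulse) and a Markovian mosaic
  simulator for admixed genomes (Poisson breakpoints at `v` per Morgan,
  donor labelling with probability `α`), with truth segments, gene
  models, plantable premature stops, and a genetic map.

## Worked example

```r
library(selfmix)

# a 30 Mb, 14-chromosome genome; admixture pulse alpha = 0.15, v = 150
cfg <- sim_config(genome_bp = 3e7, n_chromosomes = 14, seed = 5)
ds  <- simulate_dataset(cfg)

ew   <- compute_emission_windows(ds$panel, "ADM1", ds$roles$donor)
dref <- do.call(rbind, lapply(ds$roles$donor, function(d)
          compute_emission_windows(ds$panel, d, setdiff(ds$roles$donor, d))))
rref <- do.call(rbind, lapply(ds$roles$recipient, function(s)
          compute_emission_windows(ds$panel, s, ds$roles$donor)))
attr(dref, "window_bp") <- 1000; attr(rref, "window_bp") <- 1000
model <- build_emission_model(dref, rref, m = 4, m_ref_donor = 3,
                              m_ref_recipient = 4)
fit <- fit_hmm(ew, model)
fit$params$alpha
#> [1] 0.1305456
bl <- call_blocks(fit$track)
generations_since_pulse(block_mean_length(bl, 14.7 / 3e7))
#> [1] 135.4709
```

The fitted admixture proportion (13.1%) matches this replicate's planted
donor fraction (13.4%; the nominal α of 0.15 fluctuates across seeds with
only ~2,200 ancestry segments per genome), and the tract-length clock
dates the pulse at ~135 generations against a 150-generation truth —
recombination has broken donor haplotypes into ~240 blocks whose mean
length in Morgans is the reciprocal of the pulse age, compressed slightly
by same-ancestry run merging.

Closed-form estimators work directly on published summary numbers:

```r
split_time(0.0445 + 0.005875, 0.0445, rate_params())$tau_years
#> [1] 195833.3            # a ~196 ky species split from delta-pi = 0.5875%
selfing_rate_from_ratios(10, 1000)$s
#> [1] 0.9949749           # ~99% selfing from a 100-fold ratio of ratios
genome_chunks(150)$X
#> [1] 2219                # 150 generations x 14.7 M + 14 chromosomes
```

`run_pipeline()` chains the stages end to end from a single seeded
config and writes TSV/BED tables, a run log and a `summary.json`.

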