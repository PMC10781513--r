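---
title: "Analysing LD-based recombination landscapes with recland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing LD-based recombination landscapes with recland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recland)
library(dplyr)
```

## The model

Linkage-disequilibrium-based estimators infer a historical recombination
landscape as a piecewise-constant function: sorted, non-overlapping,
half-open intervals each carrying a per-base-pair, per-generation rate
$r$. recland treats this object — the *rate map* — as its core data
structure and derives everything else from three pieces of calculus:

* **Unit conversion.** $1\,\mathrm{cM/Mb} = 10^{-8}$ crossovers per bp per
  generation, so cM/Mb $= 10^8 r$. Cumulative genetic distance at a
  position $b$ is $100 \sum_{i : e_i \le b} r_i (e_i - s_i)$ cM.
* **Length-weighted averaging.** The mean rate of any region is
  $\sum_i r_i \,\omega_i / \sum_i \omega_i$ with $\omega_i$ the physical
  overlap of interval $i$ with the region. Gaps in the map are *missing
  data*, never rate zero: LD estimators only emit rates between
  informative SNP pairs, and zero-filling would bias window means
  downward. A consequence worth knowing: windowed means conserve total
  map distance exactly ($\sum_w \bar r_w c_w = \sum_i r_i \ell_i$, with
  $c_w$ the covered bp), which the test suite verifies to $10^{-12}$
  relative tolerance.
* **Population scaling.** $\rho = 4 N_e r$, with
  $N_e = \theta / (4\mu)$ by default ($\theta = 4 N_e \mu$ under the
  standard coalescent). Because the literature sometimes reports
  $N_e = \theta/\mu$ with a pre-scaled $\theta$, `ne_factor = 1` is
  available; the default follows the standard definition. The default
  mutation rate is the collared flycatcher's $4.6 \times 10^{-9}$ per bp
  per generation, the usual proxy for songbirds.

Chromosomes below 20 Mb are classed as microchromosomes (configurable),
following avian convention.

## Statistical kernel

All associations are rank-based. `kendall_tau_b()` implements the
tie-corrected statistic
$\tau_b = S / \sqrt{(n_0 - n_1)(n_0 - n_2)}$ with a two-sided p-value
from the normal approximation of $S$ with tie-corrected variance; ties
are counted by exact value, not by printed representation. Because
$\tau$ is invariant under strictly increasing transforms, the customary
square-root or log transforms of rates change nothing — they are kept
only for presentation.

`partial_kendall()` follows the inverse-correlation-matrix route
($\mathrm{partial}_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$,
$\Omega = T^{-1}$), conditioning each pair on *all* remaining variables,
with listwise deletion (matrix inversion needs one common sample;
pairwise deletion is used for simple correlations). For $k = 3$ this
reproduces the classical recursion exactly, which the tests exploit as
an independent oracle.

`wilcoxon_rank_sum()` uses midranks, and enumerates the full permutation
distribution when $n_a + n_b \le 12$ (valid under ties) — above that, a
normal approximation with tie-corrected variance and continuity
correction, which at $n_a = n_b = 6$ stays within 0.02 of the exact
answer. Group-level contrasts are Holm-adjusted by default
(Benjamini–Hochberg optional); Holm is the conservative default because
the category contrasts involve a handful of non-independent groups.

## CpG islands

`detect_islands()` is a distance-based detector: candidate islands are
maximal runs of $\ge 2$ CpGs whose consecutive spacings all stay at or
below the chromosome's median spacing (floored to an integer, so the
threshold is deterministic). Significance treats spacings as geometric
with success probability equal to the chromosome-wide CpG density
$\hat p = n_\mathrm{CpG}/L$; the total intra-island distance $D$ is then
negative-binomial and the island p-value is $P(X \le D)$. We use the
density form of $\hat p$ rather than the reciprocal mean *intra-map*
spacing because the two coincide for dispersed CpGs but the latter
degenerates when most CpGs sit inside clusters (every island would then
look typical under its own spacing). Retention requires span
$\ge 50$ bp and $p \le 10^{-5}$; both filters are monotone, which the
tests check directly. Observed/expected-ratio island definitions are out
of scope.

## Sequence uniqueness

Genome complexity is summarised as a unique-$k$-mer fraction
(`unique_kmer_index()` + `complexity_windows()`, $k = 16$): the share of
positions in a window whose forward 16-mer occurs exactly once in the
genome. The statistic lives in $[0, 1]$, equals 1 on fully unique
sequence and 0 inside perfect repeats, and is exactly testable against a
hash-table count. It is a deliberate simplification of match-length
complexity statistics: it preserves their orientation and range, not
their values.

## Windowed nucleotide diversity

`pi_windows()` sums the unbiased per-site heterozygosity
$2\hat p(1-\hat p)\,n/(n-1)$ over biallelic SNPs and divides by the
*callable* bases of the window, so invariant sites count in the
denominator only. Windows are dropped when callable span falls below
20 kb or when fewer than 70% of individuals have that much support
(per-individual support is approximated as callable span times the
individual's genotype call rate at the window's variant sites, since a
plain VCF carries no per-individual callability track — an all-sites
VCF would remove that approximation). Without a mask the full window is
assumed callable, with a warning; that default is only appropriate for
synthetic data.

## The synthetic genome

`sim_config()` defines the generator's study conditions; they are fixed
defaults, not tuning knobs:

* eight chromosomes of 2–40 Mb (four macro $\ge$ 20 Mb, four micro),
  desk-scale stand-ins for an avian karyotype;
* baseline rate $r_0 (L/20\,\mathrm{Mb})^{-\beta}$ with
  $r_0 = 3\times10^{-8}$ and $\beta = 0.5$, giving micro rates a few
  cM/Mb above macro ones before any local structure;
* telomeric elevation ($\times 4$ over the outer 1 Mb) with a sharp
  terminal drop ($\times 0.2$ over the outer 100 kb), and central
  deserts ($\times 0.15$ over the middle quarter) on macrochromosomes
  only;
* CpG-island and promoter boosts ($\times 2$ and $\times 1.5$), plus a
  planted $\times 2$ boost on promoters overlapping LINEs — the
  RT-coupling the recovery suite must find. Retrotransposons are placed
  uniformly at 60 (LINE), 15 (LTR) and 20 (SINE) copies/Mb, densities
  in line with a CR1-dominated avian repeat landscape;
* gene and CpG-island *placement* intensity proportional to the shape
  field (exponent `feature_rate_coupling = 1`), which is what gives
  window-level CpGi/gene density its positive rank correlation with
  rate;
* segment-level log-normal noise (sd 0.4 on the log scale), reflecting
  the positive, heavy-tailed character of LD-based rate estimates;
* a diversity track $\pi = 10^{-3} + 4\times10^{4}\, r + \varepsilon$
  realised as an actual VCF whose allele counts follow a neutral-like
  $1/i$ spectrum across 20 haplotypes, so that `pi_windows()` recovers
  the target within a few percent;
* per-window GC targets $0.42 + 0.03\,z(\log \text{shape})$ realised in
  the emitted sequence, and CpG islands planted as dense CG runs with
  CpG-scrubbed 150 bp flanks so their boundaries stay crisp for
  recovery checks;
* a sister-species map built per chromosome as
  $\log r_B = \rho_c z(\log r_A) + \sqrt{1-\rho_c^2}\,\varepsilon$ on
  the standardised log scale (default $\rho_c = 0.8$), preserving the
  interval structure.

What the generator does *not* emulate: sequence-evolution realism
(mutation spectra, codon structure), coalescent linkage between sites,
read-level error, assembly gaps, or structural variation. Passing
recovery tests therefore demonstrate that the analysis stack measures
what the generator planted — not that real data will be as clean.

One structural caveat surfaced by the tests: because the sister map is
rescaled per chromosome, chromosome-level baselines survive even at
$\rho_c = 0$, so genome-wide cross-species correlations never go to
zero; independence checks at $\rho_c = 0$ are therefore per-chromosome.

## Problem sizes

The shipped tests and the acceptance script run the full default genome
for everything map-level (summaries, window correlations, RT contrasts,
conservation), and restrict the expensive sequence-backed tracks (GC,
$\pi$, island recovery) to the two smallest chromosomes (7 Mb of
sequence, ~35 windows of 200 kb) — enough support for sign and
recovery checks while keeping a ten-seed recovery suite within a few
minutes. Null calibration of the Kendall p-values uses $n = 200$ with
2000 replicates.

## Worked sketch

```{r example, eval = FALSE}
cfg <- sim_config()
ann <- simulate_annotations(cfg, seed = 1)
map <- simulate_rate_map(cfg, ann, seed = 1)$map

cs <- chromosome_summary(map, ann$chrom_lengths, theta = 0.0092)
size_rate_correlation(cs)
micro_macro_contrast(cs)

w <- window_rates(map, 200e3, chrom_lengths = ann$chrom_lengths,
                  units = "cm_mb") |>
  window_density_coverage(ann$cpgi, windows = _, mode = "density")
kendall_tau_b(w$rate, w$density)

tss <- derive_tss(ann$genes)
prof <- distance_profile(map, tss)
autoplot(prof)
profile_flank_trend(prof)
```

## Known limitations

* The complexity proxy is not a match-length statistic; only its
  orientation and range are comparable to such measures.
* `pi_windows()`'s individual-support rule is an approximation when no
  all-sites callability information exists.
* Partial correlations condition on all remaining variables; per-panel
  conditioning subsets are not implemented.
* The intergenic category is the complement of gene spans (introns are
  genic); a non-exonic category can be built by complementing exons
  instead if needed.
* Cross-species comparison assumes both maps live on one reference
  coordinate system; no lift-over is provided.
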