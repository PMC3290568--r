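---
title: "Methods: neutrality tests, haplotype scans and allele ages in standscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neutrality tests, haplotype scans and allele ages in standscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standscan)
```

standscan characterises the selective signature of a resequenced candidate
locus — the motivating case is a polymorphic gene/pseudogene segregating a
full-length, putatively re-functionalised variant — from phased haplotypes.
This vignette documents the models and estimators, the numerical choices,
and what the synthetic-data tests do and do not establish.

## Data model

The carrier object is `hap_matrix`: an `n × m` 0/1 matrix of phased
haplotypes over biallelic SNPs, polarised so 0 is the ancestral allele
(inferred from outgroup bases during loading; sites whose ancestral state
matches neither observed allele are dropped and counted rather than
guessed). Positions are 1-based chromosomal coordinates; regions are
half-open `[start, end)` everywhere, so complementary regions partition
sites exactly once. Missing genotypes are dropped (not imputed): the
resequencing-style analyses downstream assume complete data, and the
dropped-site report keeps the filter auditable. Monomorphic sites are kept
on load and excluded per-statistic.

## Summary statistics

For a region with `n` chromosomes, surveyed length `L` and `S` segregating
sites, the package computes nucleotide diversity
$\pi = \frac{n}{n-1}\sum_j 2p_j(1-p_j) / L$ (identical to averaging
pairwise differences over all $\binom{n}{2}$ pairs), Watterson's
$\hat\theta_W = S/(a_1 L)$ with $a_1 = \sum_{i=1}^{n-1} 1/i$, and Tajima's
$D = (\pi_{tot} - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with the standard
variance constants. Two conventions matter and are fixed package-wide:

* `L` is the *surveyed* length, supplied by the region specification —
  never inferred from the positions span.
* `D` at `S = 0` is undefined and returns a flagged `NA`, never 0.

Per-bp quantities are reported ×10⁴ in outputs, matching the convention of
resequencing survey tables; internal computation is unscaled. The unbiased
$n/(n-1)$ form of π is used: it reproduces the published per-region D
values from the published (n, L, S, π) inputs to the printed precision.

## The coalescent null

`simulate_sample()`/`simulate_stats()` implement a Hudson-style backward
simulator: an ancestral recombination graph with crossover rate
$\rho = 4N_0 r$ per locus, gene conversion initiating at $f\rho$ with
geometric tract lengths (defaults $f = 2$, mean tract 500 bp, the
Frisse–Hudson parameterisation), and piecewise-constant coalescence
intensity encoding the demographic models. Time is scaled in units of
$4N_0$ generations; carrier sets are 64-bit masks, so $n \le 64$ (the
study design is $n = 40$). Mutations are laid down afterwards on recorded
(duration × ancestral-material) pieces, either as Poisson(θ) or as an
exact count (below). The engine is validated against closed forms
(E[S] = θa₁, E[π] = θ, Watterson's Var(S) at ρ = 0, the 1/i frequency
spectrum) and was cross-checked during development against an independent
coalescent simulator at matched parameters.

**Conditioning on S.** Null distributions for the 97.5th-percentile
neutrality test are generated *conditional on the observed number of
segregating sites* (each replicate receives exactly S mutations placed
proportionally to branch length), the classical convention for empirical
Tajima's-D p-values in resequencing surveys. The choice is empirical as
well as conventional: at the locus parameters (θ_total ≈ 14.6,
ρ_total ≈ 0.87), Poisson-θ mutation dropping inflates the π percentile by
roughly 45% relative to the published constant-size value, while
conditioning on S = 62 reproduces both the π×10⁴ and D percentiles to
within ~3%. Poisson-θ mode remains available (`mutation_model =
"poisson_theta"`) and is what the calibration checks use.

**Demographic encodings.** The table-driven scenarios are encoded as:
instantaneous ancestral→present size change at `t` generations for the
recent expansion (reference size anchors θ and ρ to the ancestral
population); exponential two-fold growth over the last `t` generations
(discretised into 32 piecewise-constant steps; an instantaneous switch is
available since the source calibration does not state the functional
form); a piecewise bottleneck of intensity `b` between `t1` and `t0`; and
a symmetric island model with even sample splits. The published
descriptions of the non-constant scenarios give only two or three
parameters of models calibrated elsewhere, so these encodings are the
package's own documented readings; the `best_fit` preset (growth from
12,500 to 25,000 at 17,000 generations) is likewise a simplified stand-in
for a multi-parameter calibrated model and is labelled as such. Under
these encodings the constant-size percentiles reproduce the published
values, while the recent-expansion percentiles do not (the package
reports ≈20.2 and ≈1.00 against published 15.64 and 1.27); no
two-or-three-parameter expansion encoding we examined reproduces that
pair, which suggests the source model had additional structure. The
numbers the package reports are the ones its stated encoding computes.

The empirical test is one-sided: `p = (1 + #{sim ≥ obs}) / (reps + 1)`,
flagged significant when the observation exceeds the 97.5th percentile
(linear-interpolation quantile, R type 7).

## LD and complete-LD grouping

`ld_matrix()` computes signed D, |D′| and r² from exact 2×2 haplotype
counts for all pairs passing a minor-allele-frequency floor (default 0.05,
the Haploview-style convention; the source analyses do not state one).
|D′| is reported as an absolute value. `complete_ld_groups()` takes the
transitive closure of pairs with |D′| ≥ 1 (within numerical tolerance) and
r² above a threshold defaulting to 0.90 — the criterion used to bundle
tightly linked functional alleles on either side of a recombination
hotspot. Confidence-interval block calling is deliberately out of scope;
the grouping is the package's surrogate for "configurations of tightly
linked alleles".

## EHH and iHS

`ehh()` computes extended haplotype homozygosity among the carriers of one
core allele as the probability that two random carriers are identical at
every site from the core to the query site. `ihh()` integrates the curve
by trapezoids over physical distance on each side, truncating at the
interpolated crossing of EHH = 0.05; a side that reaches the data edge
first carries an edge flag, and flagged sites are excluded from
standardisation by default. `ihs_scan()` takes
$\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$ per site and standardises within 20
equal-width derived-allele-frequency bins spanning [0.05, 0.95];
|iHS| > 2 is the significance flag, mirroring the genome-wide top-5%
convention of the statistic's authors. Distance is physical bp by default
(a genetic map can be supplied through positions pre-mapped by the user);
the original genome-wide scans used genetic distance, a documented
divergence that matters little at resequencing scale. Clustering of
significant sites uses a maximal-run rule with a configurable gap.

Calibration (in the test suite) simulates HapMap-density neutral data
(1 Mb, θ = ρ = 1.5×10⁻⁴/bp, n = 40, ≈2,000 usable scores): standardised
scores have per-bin mean ≈ 0 and SD ≈ 1 and ≈2–8% of sites exceed |iHS| = 2;
partial sweeps planted at frequency 0.4–0.8 are detected at ≥80% power
against the neutral 95th percentile. Synthetic sweeps are injected by
haplotype copying with exponential recombination scars — sufficient to
create the EHH/DHS structure these statistics detect, but not a
forward-time selection model; power against real sweeps with allele-age
and frequency trajectories is not established here.

## Allele age from haplotype-sharing decay

For the carriers of a candidate haplotype, recombination breaks down
sharing with the ancestral (core) haplotype at a per-meiosis rate equal to
the genetic distance; after `g` generations the distance from the core to
the first departure is approximately Exponential(g) per Morgan, with an
additional mutation hazard of μ per marker scanned (default
2.5×10⁻⁸). `dhs_tau()` uses the censored-exponential MLE
$\hat g = k_{\mathrm{uncensored}} / \sum_i (d_i + \mu m_i)$, reports
τ = 1/ĝ with the age 1/τ = ĝ, converts generations to years (default 25
y/generation, the calibration also used for the divergence-based mutation
rate μ = Dxy/(2·T/g)), and attaches a nonparametric bootstrap CI over
carriers. This estimator is a transparent reimplementation of the
haplotype-sharing-decay idea, *not* a port of the fine-mapping likelihood
software used in the original analysis; it is validated by parameter
recovery on synthetic sweeps of known age (median relative error ≤30%
across ages 100–1600 generations at 40 chromosomes, 8 Mb, 1 cM/Mb). The
ancestral haplotype defaults to the carrier-majority allele at each
marker with ties broken toward the ancestral allele, and can be supplied.

## Environmental correlation

`pathogen_richness()` counts pathogens present per country, optionally
restricted to classes (virus/bacteria/protozoa — the intracellular set).
`kendall_tau()` implements τ-b with the tie-corrected variance; the
tie-corrected form matters because country-level richness induces heavy
ties when several populations share a country (the package's default is to
keep populations as separate observations with tied richness;
`average_by_country` collapses them instead — the source analysis does not
state which was used). p-values are exact by full permutation enumeration
for n ≤ 10, a continuity-corrected normal approximation otherwise, with a
random-permutation option as the robustness layer. Note that with ties
only in richness, a perfect monotone relationship yields τ-b < 1 by
construction. Type-I error at the 21-country design is verified ≤0.06 at
nominal 0.05.

## Counting-based dN/dS and lineage assignment

`pairwise_dnds()` implements the NG86 counting estimator: per-codon
expected synonymous sites from single-base-change enumeration (changes to
stops excluded from the denominator, so sites sum to 3), observed
differences averaged over minimal mutational pathways that avoid stop
codons (unweighted; pathways through stops discarded, and codons whose
every pathway passes a stop are flagged out), Jukes–Cantor correction, and
ω = dN/dS with explicit undefined-flags when dS = 0 or a proportion
reaches the correction's 3/4 boundary. Codons containing a stop in either
sequence are excluded and reported separately — in the motivating locus
the premature stop *is* the pseudogenisation signal, not a rate.
`lineage_changes()` assigns substitutions to a focal lineage by
strict-consensus parsimony over ≥2 outgroups, which is exactly what is
needed to exhibit a stop-codon resurrection path (e.g. Leu TTA → stop
TAA → Glu GAA) codon by codon. Maximum-likelihood codon models are out of
scope; the counting estimator is not expected to reproduce ML estimates
numerically. ω recovery on alignments evolved at known ω (equal-rate
mutation, stops forbidden — the regime where NG86 is consistent) is
within ±25% median at 300 codons.

## Synthetic data and what the tests show

Every generator emits a machine-readable truth record, and recovery tests
read truth only through it. The generators emulate: neutral samples at
stated θ/ρ (the coalescent engine itself), partial-sweep haplotype
structure (copying with exponential scars and optional mutation noise),
multi-population frequency tables with a planted rank effect (calibrated
through τ = 2·asin(ρ)/π on a latent Gaussian scale), and codon alignments
at known ω on a 3-taxon star. They do not emulate: genotyping error,
phasing error, ascertainment bias, realistic recombination maps, or
selection with frequency trajectories. Passing tests therefore establish
internal correctness and calibration under the stated models, not
robustness to those real-data complications.

## Problem sizes and reproducibility

Default analysis problem sizes were chosen to match the study design
(n = 40 chromosomes, 9,209 surveyed bp, S = 62) with 10,000 null
replicates for percentile reproduction; calibration checks use 4,000–
10,000 replicates and the scan calibration uses ≈2,000 scores, sizes at
which the Monte-Carlo error is comfortably inside the stated tolerances.
All randomness flows through R's RNG (the C++ engine draws from the R
generator), so a single `set.seed()` makes every pipeline stage — and the
whole `run_pipeline()` demo — bitwise reproducible; replicate streams are
consumed sequentially, which keeps results identical across runs of the
same build.

## Known limitations

* n ≤ 64 chromosomes per simulated sample (bitmask carrier sets).
* Gene-conversion tract starts are drawn within the breakable span, which
  slightly under-represents tracts overlapping only the span's left edge;
  at 500 bp tracts on multi-kb loci the effect is negligible.
* The DHS age estimator ignores haplotype-sharing correlation induced by
  the carriers' shared genealogy; the bootstrap CI is over carriers and
  should be read as approximate.
* The island-model migration rate is interpreted as the scaled
  per-lineage rate in 4N₀ units; published two-parameter "structure"
  rows are reproduced only up to that reading.
* iHS uses physical distance; supply genetically mapped positions when a
  map is available.
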