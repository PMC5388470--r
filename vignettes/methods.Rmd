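---
title: "Detecting selective sweeps at light-environment loci: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps at light-environment loci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Threespine stickleback on the Haida Gwaii archipelago have repeatedly
colonized two extreme visual environments: oligotrophic clearwater lakes
with a blue-shifted light spectrum, and tannin-stained blackwater lakes in
which almost only red-shifted downwelling light survives. Adaptation of
color vision to these habitats is mediated by the linked cone-opsin genes
*SWS2* (blue-sensitive) and *LWS* (red-sensitive): a haplotype carrying
red-shifting *SWS2* key-site residues has swept in blackwater populations,
and a transplant experiment — 100 fish moved from a blackwater lake into a
clearwater pond and resampled after 19 years (about 13 generations) —
shows the alternate, blue-shifted haplotype rising again, a "reverse
sweep".

`sweeplight` implements the analysis machinery this kind of study needs,
end to end: genotype filtering and dataset partitioning, haplotype-based
sweep scans, windowed diversity statistics, recombination-aware outlier
calling, codon-level divergence, genotype–environment association, and
selection-experiment inference, plus a synthetic-data generator that
emulates the study's structure so every stage can be exercised and
validated without any sequencing data.

# Data model and filters

Inputs are standard formats: VCF 4.x for genotypes, a 3-column text file
for the recombination map (chrom, position, cumulative cM), a CSV of
per-population habitat covariates, and aligned in-frame FASTA for coding
sequences.

Site filters retain biallelic SNPs with quality ≥ 45, mean depth at or
below a ceiling (either fixed or the dataset mean plus 1.5 times the
interquartile range of per-site mean depth, type-7 quantiles), and at
least four reads supporting each allele; indels and multi-allelic records
are removed. Genotypes supported by fewer than four reads are masked, and
sites with strictly more than 50% missing genotypes are then dropped. The
order matters — masking precedes the missingness rule — and the test suite
pins it with a fixture whose output changes under permutation. Missing
genotypes are excluded pairwise from every frequency computation and never
imputed.

Coordinates follow the two conventions of the formats involved: VCF
positions are 1-based inclusive; all genomic windows are half-open
`[start, end)` in 0-based bp, so a 1-based position *p* is inside iff
`start < p <= end`.

# Haplotype statistics

**EHH.** For the carriers of one allele at a core SNP, the extended
haplotype homozygosity at extension *d* is the probability that two
randomly drawn carriers are identical at every SNP from the core to *d*:
$\mathrm{EHH}(d) = \sum_k \binom{n_k}{2} / \binom{n}{2}$ over groups of
identical carrier haplotypes. It equals 1 at the core and is
nonincreasing outward.

**iHS.** For every SNP with minor allele frequency above 5%, the EHH
curves of the reference-state and alternate-state carriers are integrated
over genetic distance (trapezoid rule), truncated where EHH drops below
0.05. The unstandardized score is $\ln(\mathrm{iHH}_{ref} /
\mathrm{iHH}_{alt})$; scores are z-standardized within 5%-wide
alternate-allele-frequency bins so that extreme values are comparable
across frequencies. Sites whose curves run off the chromosome before
decaying are flagged `edge`, and physical gaps larger than 200 kb flag
`gap`; both are excluded from standardization. All three controls (cutoff
0.05, gap 200 kb, trapezoid integration over cM) are arguments. Alleles
are polarized against the reference genome state, not an inferred
ancestral allele, so binning uses the alternate-allele frequency; this
choice is recorded in the output.

**Window-iHS.** Per non-overlapping 10 kb window with strictly more than
10 standardized scores, the fraction with |iHS| > 2.

**H12.** Haplotypes are compared as exact strings over consecutive 81-SNP
windows (non-overlapping by default; a sliding step is available). With
sorted haplotype frequencies $p_1 \ge p_2 \ge \dots$,
$H12 = (p_1 + p_2)^2 + \sum_{i \ge 3} p_i^2$, which responds to both hard
and soft sweeps.

# Diversity and differentiation

Per-site nucleotide diversity uses the unbiased estimator $2 p q\, n /
(n - 1)$ with *n* the genotyped chromosomes at the site; windows report
both the sum and the per-bp density. Tajima's D uses the original
normalizing constants; windows with no segregating site are undefined
(`NA`), never zero, and with missing data the window uses the rounded mean
chromosome count over its segregating sites. F~ST~ is the Hudson
ratio-of-sums estimator, $\sum_s \hat N_s / \sum_s \hat D_s$, which is the
recommended way to combine sites and is invariant to population labeling.
LD is composite r² from genotype dosage correlation (pairwise-complete)
behind MAF ≥ 5% and ≤ 20% missingness gates. These statistics are computed
from called genotypes; a genotype-likelihood route would differ for very
low-coverage data but not in the definitions.

# Outlier calling

Haplotype statistics are sensitive to local recombination rate, so items
(SNPs or windows) are assigned to rate bins (<0.5, 0.5–2, 2–3.5, 3.5–5,
>5 cM/Mb, left-closed at the printed edges) using finite-difference rates
from the map, and the empirical 0.1%/99.9% type-7 quantile thresholds are
computed per bin. Items strictly beyond a threshold are flagged.

Two degenerate-input policies matter in practice:

* *Under-occupied bins* (fewer than 1/q items) flag nothing and warn — an
  empirical 99.9% quantile from 300 values is not a 99.9% statement.
* *Ties at the extreme*: bounded statistics such as the window-iHS
  fraction can saturate (value 1.0) across more windows than the nominal
  tail holds, making the threshold equal the maximum. The tied maximal
  items are then flagged — they are indistinguishably the most extreme
  set — while a fully degenerate bin (all values equal) still flags
  nothing.

Allele-frequency change between the source and transplant populations is
computed per site as $\Delta p = p_{transplant} - p_{source}$ (alternate
allele in both), binned by source minor allele frequency in 0.05-wide
bins, with per-bin empirical 50/95/99% quantiles of $|\Delta p|$ attached
as the genome-wide context against which candidate sites are judged.

# Codon-level divergence

Pairwise dN/dS uses the counting (NG86-style) estimator: fractional
synonymous site counts per codon (changes to stop codons excluded from
the per-position denominator, so S + N = 3 per codon), observed
differences attributed by equal-weight averaging over all shortest
mutational pathways through multi-hit codons (pathways through stops
excluded; if every pathway is blocked, all are used), and Jukes–Cantor
correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$. A maximum-likelihood
codon model would weight pathways by rates instead of equally; the
counting estimator was chosen because the study uses mean pairwise dN/dS
as a rank statistic across thousands of genes, and the counting form is
exactly checkable against a pathway-enumeration oracle. Pairs with
dS = 0 are undefined and excluded from gene means (a pseudocount would
bias the genome-wide distribution); raw counts are always reported so the
ratio can be re-estimated differently.

The gene-conversion scan computes dS between one sequence pair in 30 bp
windows with 1 bp step: per-codon synonymous site counts are spread over
the codon's three nucleotides, while synonymous differences sit on the
exact differing nucleotides, so a single synonymous change lights up
exactly the windows that cover it.

Spectral classification reads two key residues in bovine-rhodopsin
numbering from a user-supplied position map: S97 with A109 is red-shifted,
C97 with G109 blue-shifted, anything else (including gaps or ambiguities,
with a warning) intermediate. The haplotype network is a minimum-spanning
network over nucleotide Hamming distances — the union of all minimum
spanning trees, so tied alternative links are retained — which captures
the two-major-haplotype topology this system shows without median-vector
inference.

# Genotype–environment association

Each gene's SNPs are collapsed into one axis per individual by classical
metric MDS (principal coordinates) on mean absolute dosage difference,
pairwise-complete; the first coordinate's sign is fixed by positive
correlation with total alternate dosage, since an MDS axis sign is
otherwise arbitrary. Coordinates are averaged per population (the
population is the sampling unit for habitat covariates; an
individual-level fit is available) and modeled by ordinary least squares
against three predictors: light transmission at 400 nm (T400, in percent)
either continuous or as the categorical blackwater contrast (blackwater
iff T400 ≤ 74%), lake depth (m), and log-transformed lake area.
Significance is Bonferroni-adjusted across the whole gene-by-predictor
family at α = 0.05. Single-SNP association uses Pearson's χ² without
continuity correction on 2×2 allele-count-by-habitat tables, again
Bonferroni-corrected.

# Selection-experiment inference

**Evolutionary rate (haldanes).** The haldane is change in pooled
standard deviations per generation, $h = ((x_2 - x_1)/s_p)/g$. Here the
trait is an allele frequency, taken on the natural-log scale by default.
The study system's printed rate for the shift 0.13 → 0.40 over 12.7
generations equals the total ln-frequency change ($\ln(0.40/0.13) =
1.124$), i.e. a standardization in which $s_p\,g$ collapses to unity; that
reproducible form is frozen as the default (`sd_pooled = 1/g`), because no
raw-scale or binomial-sampling standard deviation we examined reproduces
the printed value from the printed inputs. Supplying an explicit
`sd_pooled` gives the textbook estimator, and the convention in use is
recorded in the output.

**Selection coefficient.** The observed total frequency change is divided
by the generation count and the single-generation viability-selection
response is inverted at a reference frequency. The parameterization is
fitnesses $1 : 1 - hs : 1 - s$ against the declining allele, with the
exact mean-fitness denominator:
$$\Delta p = \frac{s p q\,[h p + (1-h) q]}{1 - s q\,(2 p h + q)}
\quad\Longrightarrow\quad
s = \frac{\Delta p}{p q [h p + (1-h) q] + \Delta p\, q (2 p h + q)}.$$
With the study inputs ($\Delta p_{total} = 0.27$, g = 12.7, h = 0.5,
reference = source frequency 0.13) this yields s = 0.283. The
approximation $\bar w \approx 1$ is available (`normalize = FALSE`) and
changes s by O(s²); the reference frequency defaults to the source
population's, with the midpoint as the recommended choice for
self-consistency checks, since the source-frequency form carries a known
upward bias when the response grows along the trajectory.

**Wright–Fisher validation.** `wf_simulate()` runs a diploid
Wright–Fisher population with viability fitnesses (1, 1+hs, 1+s) for the
focal allele, binomial drift at the census size (default 100 founders, the
experiment's design), and final binomial sampling of 12 source and 11
transplant diploids. Under the study parameterization (s = 0.28,
p₀ = 0.13, 13 generations) the observed shift of 0.27 lies inside the
central 90% of replicate outcomes, and with s = 0 the simulator is a
martingale — both are pinned by tests.

# The synthetic-data generator

The generator emulates three layers of the study design:

* **Neutral panels** come from a mosaic-copying model: 80 founder
  haplotypes carry alleles with founder-copy counts drawn proportional to
  1/i (the neutral frequency spectrum), and each sample haplotype copies
  from founders with switch points at exponential spacings along the
  genetic map (2 switches/cM by default, an effective ancestry depth),
  plus rare private mutations. These defaults were calibrated so the
  panel behaves neutrally under the package's own statistics —
  genome-mean Tajima's D within ±0.5 of zero — before any
  detection experiment was run; with too few founders the frequency floor
  of 1/(2K) starves the rare tail and pushes D positive.
* **Sweeps** are injected by copying one donor haplotype over a target
  interval into a chosen fraction of rows, with exponential shoulders
  beyond the edges so EHH decays realistically rather than cliff-like.
  The radiation simulator plants the sweep at high frequency in
  blackwater populations (0.95 at full association strength) and low in
  clearwater ones, and places 7 nonsynonymous plus 4 synonymous coding
  variants on the swept segment with 5% recombinant leakage, mirroring
  the study system's *SWS2* variant set.
* **The transplant** wraps the Wright–Fisher simulator for the focal
  allele, lets linked SNPs ride the focal haplotype with leakage, and
  drifts 2,000 unlinked SNPs through the same 100-founder bottleneck, so
  the allele-frequency-change quantile analysis can be run against its
  own truth tables.

What the generator does *not* emulate: coalescent genealogies and
realistic demography, sequencing error and depth heterogeneity, physical
linkage between the "unlinked" backdrop SNPs, and phasing error (panels
are phased by construction). Passing tests therefore demonstrate that the
statistics and the detection logic are implemented correctly and are
calibrated under a neutral-like null — not that the pipeline's power on
any particular real dataset matches the synthetic numbers.

# Problem sizes and validation design

The validation suite runs at desk scale, with sizes chosen so every
empirical-quantile precondition (at least 1/q items per bin at q = 0.001)
is met:

* Oracle equivalence: 200 seeded random cases per statistic (EHH, iHH
  integration, H12, π, Tajima's D, Hudson F~ST~, NG86 counts) on panels up
  to 32 haplotypes × 64 SNPs, each compared against an independent
  brute-force enumeration written separately from the production code
  (the NG86 oracle even takes its genetic code from a different source).
* Calibration: a neutral genome of 100 haplotypes × 60,000 SNPs over
  25 Mb with two recombination regimes; per-bin flagged fractions stay
  within the binomial band around 0.1%, and standardized iHS has per-bin
  mean 0 and sd 1 to 1e-9.
* Sweep power: 50 replicates of a 0.8-frequency sweep over 200 kb in an
  11 Mb, 81,000-SNP genome of 40 haplotypes (81,000 SNPs keeps ≥ 1,000
  non-overlapping H12 windows) — the interval must be recovered by both
  H12 and window-iHS outlier calls in ≥ 90% of replicates, and in ≤ 5% of
  50 matched null genomes.
* Reverse-sweep logic: 100 transplant replicates at s = 0.28 (the focal
  site's |Δp| exceeds its source-MAF bin's 95% quantile of unlinked SNPs
  in the majority) versus 100 at s = 0 (it does not).

# Known limitations

* The iHS implementation mirrors one specific, documented convention set
  (reference-allele polarization, alternate-frequency bins, EHH cutoff
  0.05, 200 kb gap rule); other tools' defaults (ancestral polarization,
  derived-frequency bins) will shift individual scores though not the
  outlier geography.
* Tajima's D with missing data uses a single effective chromosome count
  per window; heavily uneven missingness within a window is better
  handled upstream by the missingness filter.
* The counting dN/dS estimator ignores transition/transversion bias and
  codon frequencies; its values are comparable across genes computed the
  same way, which is how they are used here.
* The haldanes default is a frozen reproduction of the study system's
  operational convention, not a general-purpose rate estimator; for real
  trait data supply the pooled standard deviation explicitly.
* The selection-coefficient inversion is a single-point deterministic
  approximation; it ignores drift, so on strongly drifting trajectories
  it estimates the realized, not the causal, selection intensity.
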