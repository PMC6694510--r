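---
title: "Founder mosaic reconstruction from skim sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder mosaic reconstruction from skim sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An F2 intercross between two divergently selected, *outbred* lines is a
classical design for mapping quantitative trait loci: every F2 genome is a
mosaic of segments inherited from high-line (H) and low-line (L) founders,
and the mosaic -- HH, HL or LL at every position -- is the genotype needed
for linkage and QTL analysis. Whole-genome sequencing makes it affordable to
genotype such crosses by sequencing founders deeply (~30x) and offspring
very shallowly (well under 0.5x). At skim coverage almost no site has
enough reads for a per-site genotype call, but a *chromosome-scale* mosaic
can still be inferred, because F2 haplotype blocks are tens of megabases
long and thousands of sparse reads fall on each block.

The complication relative to crosses of inbred lines is founder
heterozygosity: the F0 linkage phases are unknown, so a read carries
line-origin information only at sites where the founders of the family are
*fixed for alternative alleles* between the lines. `mosaicimpute`
implements the full path from founder genotypes to analysis-ready binned
genotypes around that idea:

1. filter founder variants (MAF > 0.043, AC > 5, QUAL > 30 by default);
2. select, per nuclear family (one F2, two F1s, four line-labelled F0s),
   the markers at which both H grandparents are homozygous for one allele
   and both L grandparents for the other;
3. polarize the offspring's ref/alt read depths at those markers into
   (n~H~, n~L~) line counts;
4. decode each chromosome with a three-state hidden Markov model;
5. apply biological QC, bin the mosaic at 1 Mb, and export R/qtl input.

The F1 generation is never sequenced: it is heterozygous at every selected
marker by construction.

## Site-level states

Each scored marker is first translated into one of six observation states
(HH, HU, HL, LU, LL, UU): reads from both lines give HL, at least
`min_hom_reads` (default 2) one-sided reads give a homozygous state, a
single one-sided read gives the ambiguous HU/LU, and no reads give UU.
These six states describe *read evidence*; in the decoder they are carried
as binomial likelihood statements (HU is simply "compatible with HH or
HL"), and the hidden state space is the three true genotypes {HH, HL, LL}.
U-bearing states therefore never appear in final segmentations, except for
the degenerate whole-chromosome UU segment returned when a chromosome has
no read-covered marker at all.

## The chromosome-specific HMM

**Transitions.** Between adjacent markers at physical distance $d$ bp, the
recombination fraction per meiosis is Haldane's
$r = \tfrac12\left(1 - e^{-2dm}\right)$, with $m$ the map distance from a
configurable genome-average rate (default 3.0 cM/Mb, a chicken-like
value). An F2 carries two independent meioses, so single line-origin
changes (HH&harr;HL, HL&harr;LL) occur with probability $r$, the double
change HH&harr;LL with $r^2$, and the remaining mass stays put. The
initial distribution is the F2 expectation (1/4, 1/2, 1/4).

**Emissions.** At a site with $n_H + n_L$ reads, the H-read count is
binomial with per-read probability $1-\varepsilon'$, $0.5$, $\varepsilon'$
under HH, HL, LL. $\varepsilon'$ is the configured per-read line error
(default 0.01) inflated by the magnitude of a chromosome-level
*allele-ratio bias* estimated from the data (below).

**Window averaging.** Read counts are averaged in non-overlapping windows
of 200 consecutive markers on large chromosomes and 50 on small ones (a
chromosome is "small" when it carries fewer than 2000 informative markers;
the trailing partial window merges into its predecessor). Windows whose
H-read fraction lies in [0.25, 0.75] are predominantly heterozygous
territory; their mean deviation from 0.5 estimates a systematic line-read
bias (reference bias, mapping asymmetry) which is folded into
$\varepsilon'$. Because window statistics are computed per chromosome, the
HMM is chromosome-specific, accommodating uneven chromosome lengths and
marker densities. Windows also flag extreme-depth regions for diagnostics.

**Decoding.** Viterbi decoding is the default (per-marker max-posterior is
available as `decode_mode = "posterior"`). Dynamic-programming ties are
broken toward the state of the preceding marker, which favours fewer
crossovers; residual ties take the lower state index, making decoding
fully deterministic. Consecutive identical states merge into segments.

**Breakpoint intervals.** Each state change is localised between the last
read-covered marker supporting the left state and the first supporting the
right state. The segment boundary is placed at the interval midpoint
(unbiased under a uniform prior on the crossover position within the
interval); chromosome ends are extended to [1, length]. Interval lengths
are the package's measure of breakpoint resolution.

## Quality control

* **Density filter**: individuals whose genome-wide density of
  read-covered markers is below 5 SNPs/Mb are dropped -- "called SNPs" is
  defined here as marker sites with at least one mapped read, over the
  assayed genome only, since that is the quantity that guarantees HMM
  input density.
* **Close double crossovers**: crossover interference makes double
  crossovers within short distances biologically implausible, so every
  internal decided segment shorter than 3 Mb that is flanked by two
  crossovers is removed, iteratively: agreeing flanks merge (removing two
  crossovers); disagreeing flanks mask the segment to UU (a
  `merge_left` option is exposed). Masking is the default for the
  disagreeing case because it explains how the genome-wide call rate can
  *drop* after this filter -- the signal used by the next step. The
  operation is idempotent and never increases the crossover count.
* **Individual filter**: individuals whose post-filter call rate falls
  below 0.90 are removed (default), or alternatively individuals whose
  genome-wide crossover count exceeds the cohort median plus three robust
  standard deviations; the two modes select very similar sets, and the
  report always lists both statistics.
* **Binning**: genotypes are extracted in 1-Mb bins; a bin takes the state
  of the single decided segment covering it entirely, and bins containing
  a crossover or any UU overlap are set to missing. Terminal partial bins
  keep their true span. R/qtl export codes HH/HL/LL/missing as A/H/B/-
  with cM positions approximated as physical Mb times the configured rate
  (no linkage map is estimated here).

Coordinates are 1-based inclusive throughout (VCF convention); only the
BED export converts to 0-based half-open.

## The simulator

Every stage is testable without external data through a generator that
emulates the target study design and provides full ground truth.

* **Founder genomes.** Two lines drift independently from a common base:
  each non-fixed site draws per-line allele frequencies from a symmetric
  Beta whose parameter is set so the expected within-line heterozygosity
  is `within_line_het` (default 0.30); a `fixed_fraction` of sites
  (default 0.034) is strictly fixed for alternative alleles between the
  lines. Founder genotypes are Hardy-Weinberg draws from the line
  frequencies. Under these defaults roughly 13% of segregating sites end
  up informative within a family -- most of them family-specific rather
  than line-fixed, the hallmark of outbred founders. Because line drift is
  independent, small founder pools can also be alternate-fixed by chance,
  so pooled line-level selection remains meaningful in simulation.
* **Density calibration.** The headline condition is the density of
  informative markers (default 791/Mb, after the default founder filter).
  The per-site probability of being family-informative *and* surviving
  the filter depends on the drift model and pool size, so it is estimated
  once per run by a seeded Monte Carlo draw of 200,000 sites, and the
  total site density is set to target/rate. Realized densities land
  within ~1% of the target.
* **Meiosis.** Crossover counts are Poisson with mean equal to the map
  length in Morgans; positions are uniform subject to a *hard* minimum
  gap of 5 Mb between crossovers of one meiosis (rejection sampling,
  infeasible counts resampled with a warning). A hard gap is the simplest
  model consistent with cytological evidence of essentially absolute
  interference over short distances; a gamma renewal process would be the
  natural refinement. Only the two F1 meioses matter for line origin (the
  F1's haplotypes are line-pure), which is also why F1s are generated but
  never "sequenced".
* **Reads.** Depth per marker site is Poisson(`coverage`), each read
  reports the wrong line with probability `seq_error` (default 0.005,
  standing in for sequencing error plus residual mapping error after
  MAPQ filtering). Reads are simulated at informative marker sites only,
  since the pipeline consumes nothing else; `coverage` is therefore the
  expected reads per site. Coverage titrations use binomial read
  *thinning*, so lower coverages are coupled subsamples of higher ones --
  the clean way to study the coverage/accuracy relationship without
  confounding by independent randomness.

What the simulator does **not** emulate: reference/mapping bias varying
along the genome, uneven marker spacing driven by selection history,
structural variation, pedigree errors and sample mix-ups, and
library-failure dropouts. Passing tests on simulated data therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to every artefact of real sequencing data; the QC layer exists
precisely because real data contain such artefacts.

## Numerical and design choices

* All likelihood computation is in log space; forward, backward and
  Viterbi recursions agree with exhaustive path enumeration to 1e-9
  relative tolerance on small instances (enforced by tests).
* Sites with any missing founder call are excluded from that family's
  marker set: a single missing call breaks the fixation guarantee.
* MAF for founder filtering is computed jointly across all founders from
  the genotypes; AC is taken from VCF INFO when present. Multi-allelic
  records are dropped at ingestion with a counter (the model is
  biallelic). Markers fixed in one line's pair but segregating in the
  other's (~20% more markers in practice) are deliberately not used.
* The founder filter's AC > 5 default presumes a realistically sized
  founder cohort; with fewer than three founders per line, line-fixed
  sites cannot exceed AC 5 and the threshold should be lowered to match.
* Window averages feed the emission model only through the bias estimate;
  transition probabilities come from physical distance and the configured
  map rate. This is the minimal standard HMM consistent with estimating
  transmission and emission probabilities from windowed read ratios; the
  exact window-to-parameter mapping of ancestral implementations for
  inbred crosses is not recoverable and was not copied.
* Whether disagreeing-flank double crossovers should be masked or merged
  is genuinely open; masking is the default because it is conservative
  (it never invents a decided genotype) and makes the call-rate filter
  informative. Both actions are logged.
* F1 parents may be reused across families (many-to-many F1 matings), so
  families may share founders; each F2 still defines its own family.

## Problem sizes used in the shipped checks

The package's cohort-level checks simulate 10 families on a five
chromosome, 200-Mb genome at 791 informative markers/Mb and 0.33x
coverage -- a deliberately scaled-down cross that keeps a full run in
minutes while preserving the per-chromosome marker densities, coverage
and interference of the motivating design. On that cohort the
reconstruction agrees with truth on well over 95% of decided 1-Mb bins
per individual and localises inferred crossovers to a median interval
under 10 kb; the exact values are recomputed, not stored, by
`scripts/acceptance.R` and the test suite. The coverage titration
(0.4x thinned to 0.2x, 0.1x, 0.05x) shows genotype error flat to within
a percentage point down to 0.05x, the practical argument for sequencing
intercross offspring as shallowly as multiplexing allows.

## Known limitations

* Two founder lines only; multi-parental designs (MAGIC, AILs beyond F2)
  are out of scope.
* No X/Z-chromosome dosage model: sex chromosomes are carried in the
  genome specification but excluded from imputation by default.
* Individuals are decoded independently; no joint pedigree likelihood.
* Founders are not phased, and partially informative markers are unused,
  which bounds breakpoint resolution below what a phasing-aware method
  could achieve.
* cM positions in the R/qtl export are proportional to physical position;
  build a proper linkage map downstream if map distances matter.
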