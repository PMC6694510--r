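# mosaicimpute

Founder-line mosaic genotype reconstruction for F2 intercrosses bred from
**outbred** (heterozygous) founders of two divergent lines, using
high-coverage founder sequence genotypes and very low coverage (< 0.5x)
offspring sequencing.

## Who this is for

Groups running experimental intercrosses (e.g. divergently selected
poultry, rodent or fish lines) who want genome-wide QTL-mapping genotypes
for hundreds of F2 offspring at skim-sequencing cost. Per-site genotype
calling is hopeless below ~1x coverage, but the F2 genome is a mosaic of
long founder-line blocks (HH, HL, LL), and those blocks -- plus the
recombination breakpoints between them -- can be reconstructed accurately
from sparse reads.

## The method in brief

Because outbred founders have unknown phase, information about line origin
exists only at markers **fixed for alternative alleles** between the
founders of a nuclear family (one F2, its two F1 parents, its four
line-labelled F0 grandparents). The pipeline:

1. **Founder variant filter** -- keep sites with MAF > 0.043, AC > 5,
   QUAL > 30 (all configurable).
2. **Within-family informative markers** -- both H grandparents homozygous
   for one allele, both L grandparents for the other; the H-line allele is
   recorded for polarization. A pooled line-level mode
   (`select_pooled_informative()`) supports pooled founder sequencing.
3. **Read calling** -- offspring allele depths (VCF `AD` fields or a depth
   TSV) are polarized to line counts (n_H, n_L); individuals with fewer
   than 5 read-covered markers per Mb genome-wide are dropped.
4. **HMM decoding** -- per chromosome, hidden states {HH, HL, LL};
   transitions from Haldane's map function,
   `r = 0.5 (1 - exp(-2 d m))` over inter-marker distance `d`, with
   HH<->LL as a double crossover (`r^2`); binomial emissions with per-read
   line error `eps'`, where `eps'` folds in an allele-ratio bias estimated
   from 200-marker (large chromosomes) or 50-marker (small chromosomes)
   windows. Viterbi decoding yields segments; each boundary carries a
   breakpoint interval spanning the flanking read-covered markers.
5. **QC + export** -- close double crossovers (< 3 Mb) merged or masked,
   individuals below 90% call rate (or crossover-count outliers) removed,
   genotypes binned at 1 Mb and exported in R/qtl csv format (A/H/B/-).

A simulator (`simulate_cross()`) generates the whole design -- drifting
founder lines, nuclear families, meioses with hard 5-Mb crossover
interference, Poisson skim reads -- with full ground truth, and
`truth_agreement()` / `breakpoint_resolution()` quantify accuracy.
See `vignette("mosaicimpute-methods")` for models, assumptions and
parameter choices.

## Worked example

Simulate a small cohort (4 families, 40 + 20 Mb genome, 791 informative
markers/Mb, 0.33x coverage), then run the full pipeline in memory:

```r
library(mosaicimpute)

genome <- genome_spec(c("1", "2"), c(40e6, 20e6))
sim <- simulate_cross(sim_config(genome, n_families = 4, seed = 11))

founders <- filter_founder_variants(sim$founders)
markers  <- lapply(sim$families, function(fam)
  select_family_informative(founders, fam))
sapply(markers, nrow)
#> F2_01 F2_02 F2_03 F2_04
#> 47736 47974 47803 47746        # ~795 informative markers per Mb

res <- impute_cohort(sim$depths, markers, genome)
subset(res$seg$segments, individual == "F2_01")
#>   individual chrom    start      end state
#> 1      F2_01     1        1 33656417    HL
#> 2      F2_01     1 33656418 40000000    LL
#> 3      F2_01     2        1 20000000    HH

head(res$qc[, c("individual", "density", "call_rate", "crossovers")])
#>   individual  density call_rate crossovers
#> 1      F2_01 226.2500         1          1
#> 2      F2_02 222.8333         1          4
```

F2_01 is heterozygous along chromosome 1 until a crossover near 33.66 Mb
switches it to LL, and carries two H-line haplotypes across chromosome 2;
all four individuals pass the density (>= 5 covered SNPs/Mb) and
call-rate (>= 0.90) filters. Comparing with the simulated truth:

```r
truth_agreement(res$seg, sim, genome)$overall
#> [1] 0.9956          # mean per-individual 1-Mb bin agreement
breakpoint_resolution(res$seg)$summary
#>    n median  q25  q75     q90
#> 1 13   6318 5250 8313 11809.4   # interval lengths in bp
```

`bin_genotypes()` + `export_rqtl()` write the 1-Mb genotype matrix for
R/qtl; `run_simulate()` / `run_select()` / `run_impute()` /
`run_evaluate()` are file-based stage wrappers, also reachable from a
shell via `inst/cli/mosaicimpute.R {simulate|select|impute|evaluate}`.

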