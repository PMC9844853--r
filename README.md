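# cistromics

Regulatory-genomics inference for transcription-factor studies: does a TF
pair co-occupy the genome more than chance allows, which genes do the
shared sites drive, and do disease-risk variants inside those sites act
through allele-specific regulatory activity?

The package was built for the analysis pattern of a two-TF ChIP-seq study
in a differentiated cell type (e.g. LHX2/OTX2 in retinal pigmented
epithelium): integrate two peak sets with a knockdown RNA-seq table, test
their co-occupancy against a covariate-matched null, scan GWAS variants
through the bound regions, and quantify allelic imbalance at a candidate
regulatory SNP. It is aimed at computational biologists who have peak
calls, a DE table, open-chromatin intervals, genotypes and allele-level
read counts, and want the downstream statistics to be explicit, seeded and
testable.

## The statistics at the core

**Matched permutation null for co-occupancy.** For query cistrome *A* and
reference cistrome *B*, the observed statistic is the query-side count
`#{a ∈ A : a overlaps some b ∈ B by ≥ 1 bp}`. Null sets replace *A* with
random regions that (1) lie in open chromatin, (2) match *A*'s joint
GC-content × distance-to-TSS profile exactly at bin resolution, and (3)
draw lengths from *A*'s length distribution. The empirical p-value is

    p = (#{null ≥ observed} + 1) / (n_perm + 1)

**Allelic imbalance.** At a heterozygous SNP, per-donor ref/alt read
counts (after proper-pair, duplicate and MAPQ ≥ 10 filtering) are tested
with an exact two-sided binomial against 1:1 and combined across donors by
Fisher's method, X² = −2 Σ ln pᵢ ~ χ²(2k).

**Variant scan.** Tag SNPs are expanded by dosage r² > 0.7 within 1 Mbp,
intersected with the cistromes, and each candidate's alleles are scored
against a PWM as log2-odds bits; the allele delta on the
reference-maximising window measures motif disruption.

All standard plumbing (intervals, FASTA, overlap algebra) runs on
GenomicRanges/IRanges/Biostrings; the statistics above are implemented in
the package and validated against brute-force oracles, `binom.test()`, and
planted-truth simulations.

## Worked example

Allelic imbalance from two heterozygous donors' ATAC-seq read counts at a
promoter SNP (15 C : 5 T and 12 C : 4 T):

```r
library(cistromics)
counts <- data.frame(donor = c("donor1", "donor2"),
                     n_ref = c(15L, 12L), n_alt = c(5L, 4L))
ai_test(counts)
#> Allelic-imbalance test (per-donor exact binomial + Fisher)
#>   donor1: 15 ref : 5 alt, p = 0.0414
#>   donor2: 12 ref : 4 alt, p = 0.0768
#>   combined: chi-square = 11.50, df = 4, p = 0.02146
```

Neither donor alone is conclusive at the usual threshold, but the combined
evidence (p ≈ 0.021) supports a genuine ~3:1 imbalance favouring the
reference-fitting allele.

Co-occupancy of two synthetic cistromes with 65% planted overlap, tested
against the matched null:

```r
cfg <- sim_config(7, genome = list(contig_length = 3e5, n_tss = 60),
                  peaks = list(n_a = 60, n_b = 180, overlap_fraction = 0.65))
w  <- gen_genome(cfg)
pk <- gen_peaksets(cfg, w)
permutation_overlap_test(pk$setA, pk$setB, w$open, w$genome, w$tss,
                         n_perm = 999, seed = 42)
#> Matched-null permutation overlap test
#>   observed overlap: 41
#>   null mean:        11.8 (999 permutations)
#>   empirical p:      0.001 (floor at 999 permutations)
```

41 of 60 query peaks touch the reference set; matched random sets average
11.8, so the planted co-occupancy is detected at the permutation floor.
The methods vignette (`vignettes/cistromics-methods.Rmd`) documents every
model, default and limitation.

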