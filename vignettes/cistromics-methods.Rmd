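---
title: "Methods: matched-null co-occupancy testing, variant scanning and allelic imbalance"
author: "cistromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-null co-occupancy testing, variant scanning and allelic imbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistromics)
```

# Scope and model

`cistromics` implements the inference chain that connects a transcription
factor's genome-wide binding map (its *cistrome*, from ChIP-seq peak
calling) to its transcriptional program and to regulatory disease variants.
Four statistical components sit at the core:

1. **Co-occupancy testing.** Two cistromes overlapping more than expected is
   the basic evidence for TF cooperation. Raw overlap counts are
   meaningless without a null that respects where peaks *can* occur:
   accessible chromatin, sequence composition, and the tendency of peaks to
   cluster near genes. The package therefore samples random region sets
   constrained to open chromatin and matched on the query set's joint GC ×
   distance-to-TSS profile, and reports an empirical permutation p-value.
2. **Peak–expression integration.** Peaks are assigned to the gene with the
   nearest TSS; knockdown response is summarised by thresholding a
   differential-expression table (|FC| > 1.5, FDR < 5% by default) and by a
   Wilcoxon rank-sum shift test of target vs non-target log2 fold changes.
3. **Variant scanning.** GWAS tag SNPs are expanded into candidate causal
   sets via dosage r² (> 0.7 by default), intersected with cistromes, and
   scored for allele effects on a PWM match in log2-odds bits.
4. **Allelic imbalance.** At a heterozygous regulatory SNP, reads are
   filtered (proper pair, not duplicate, MAPQ ≥ 10), alleles counted, each
   donor tested with an exact two-sided binomial against 1:1, and donors
   combined by Fisher's method (−2Σln p ~ χ², df = 2k).

# Coordinate conventions

Internally everything is a `GRanges`/`DNAStringSet`, i.e. 1-based closed
coordinates — the native convention of the GenomicRanges stack this package
is built on. File formats are converted at the boundary exactly as
`rtracklayer` does: BED input is 0-based half-open and becomes
`(start + 1, end)` on read; headered TSV interval input is taken as 1-based
inclusive. The BED membership rule "a SNP at `pos == end` is outside the
interval" holds identically after conversion. An optional `summit` column
carries the peak summit as a 0-based offset from the interval start
(peak-caller convention); the summit, when present, is the anchor for all
TSS distances, with the interval midpoint as fallback.

Peak widths are used as-is by default. ChIP fragment sizes argue that ~200
bp around the summit is the physically meaningful unit, so
`resize_to_summit()` offers width standardisation, but no analysis applies
it implicitly.

# The matched permutation null

`permutation_overlap_test()` randomises the **query** set (conventionally
the smaller cistrome) and holds the reference set fixed. Each null draw:

* has the query set's cardinality;
* lies entirely within open chromatin (checked per interval);
* resamples interval lengths with replacement from the query length
  distribution;
* reproduces the query set's **joint** (GC bin, distance-to-TSS bin) counts
  *exactly*.

Matching is joint rather than marginal because both constraints apply to
the same random sets; joint matching is the more conservative reading.
Default bins are GC width 0.05 on [0, 1] and log10-spaced distance decades
from 1 bp to 10 Mbp plus an overflow bin (`default_gc_breaks()`,
`default_distance_breaks()`). Matching exact at bin resolution is the
strongest construction consistent with "a matched profile"; the bins are
user-configurable, and coarser bins trade matching fidelity for sampling
feasibility in small open-chromatin universes.

Sampling is by rejection: positions uniform over open-chromatin bases,
accepted while the joint bin has unfilled quota. A draw whose bin cannot be
filled within `max_rejections × n` attempts aborts with an error naming the
bin — the remedy is coarser bins or a larger universe, never silent
relaxation. Sampled intervals may overlap one another (the null is a
marked point process, not a packing); containment and conservation are
asserted per draw in the test suite.

The empirical p-value uses the add-one (permutation-inclusive) convention
`(#{null ≥ observed} + 1) / (n_perm + 1)`, so at 1,000 permutations the
smallest reportable value is ~9.99 × 10⁻⁴: a *floor*, printed as such.
Claims like p < 10⁻⁵ require ≥ 10⁵ permutations by construction.

Two properties define correctness here and are what the acceptance tests
measure, since a published genome-scale overlap (which requires the
original genome, ATAC atlas and peak files) cannot be recomputed offline:
**calibration** — for independent cistromes placed uniformly in shared open
chromatin the empirical p is uniform (KS test over 200 replicate tests at
199 permutations each) — and **power** — a 60% planted co-occupancy drives
p to its floor in ≥ 99/100 runs. Calibration holds because conditional on
its joint bin counts a uniformly-placed query set is exchangeable with the
matched draws; to keep that exchangeability exact in the calibration study
the generator uses a degenerate length distribution (`len_sd = 0`), since
length *resampling* (rather than permutation) is only approximately
exchangeable.

# Statistical choices

**DEG thresholds.** Down-regulated: signed linear FC ≤ −1.5 and adjusted
p < 0.05; up symmetric. The DE table carries both `log2fc` and the signed
linear `fc` (display scale: an 18-fold knockdown reduction is −18), related
by `fc = sign(log2fc)·2^|log2fc|`. Genes with missing FC/adjusted p are
excluded from threshold filtering (with a count reported) but retained in
shift tests, which use only fold changes — this mirrors how
independent-filtering NAs arise in DE pipelines.

**Shift test.** Two-sample Wilcoxon rank-sum of target vs non-target log2FC
is the default; a one-sample signed-rank mode (targets vs 0) is available.
Exact p-values up to n = 25 per group, normal approximation with continuity
correction beyond. Rank invariance to monotone transforms of the FC column
is property-tested.

**Exact binomial, two-sided.** The two-sided p is the minimum-likelihood
convention: the sum of P(X = k) over all outcomes no more probable than the
observed one (the `binom.test()` convention, cross-checked against it and
against full enumeration). The two-sided choice is not arbitrary: on the
published two-donor counts (15:5 and 12:4) it gives per-donor p ≈ 0.0414
and 0.0768 and a Fisher-combined p ≈ 0.0215 — reproducing the printed
0.021, whereas one-sided tests give ≈ 0.006. The pipeline's agreement with
the printed value is itself the validation of this reading.

**Fisher combination.** −2Σln p referred to the upper χ² tail with 2k df.
Combining k copies of the same p is *not* monotone in k for weak evidence
(p > 1/e ≈ 0.37 adds less than the df increment's expectation); the
monotonicity property is asserted only in the informative regime.

**LD r².** Squared Pearson correlation of unphased alt-dosage vectors over
shared non-missing samples (the genotypic estimator). PLINK's default
composite/EM haplotype estimator differs slightly on unphased data; at the
tight LD relevant to tag expansion (r² near 0.7–1) the two agree closely.
The threshold is strict (r² > 0.7), and monomorphic-column errors are kept
distinct from missing-data errors. The search window defaults to 1 Mbp.

**Allele-effect scoring.** Log2-odds `Σ log2(P_pwm(b)/P_bg(b))` over every
PWM window covering the SNP, both strands. The default delta convention
evaluates both alleles on the window/strand maximising the *reference*
score — "how much does the alternate allele disrupt the existing site" —
because that is the question asked of a regulatory variant inside a known
binding footprint. A `max`-vs-`max` mode compares each allele's best window
instead; only that mode is exactly antisymmetric under allele swap (the
best-ref mode is antisymmetric only when both alleles share the maximising
window), which is why the antisymmetry property is asserted for `max`.
PWM probabilities come from counts via a background-split pseudocount,
`(c_b + 4·pc·bg_b)/(Σc + 4·pc)`, default `pc = 0.8`, uniform background;
scores are reported as raw bits, not calibrated to motif-hit p-values.

**Read filtering.** Retained reads are properly paired, non-duplicate, and
MAPQ ≥ 10 (a read at exactly 10 is kept, matching a "< 10 is low quality"
rule). Reads carrying a third base or N at the SNP are tallied separately
and excluded from the test rather than erroring — alignments against an
N-masked reference (the standard guard against reference bias, supported
via `mask_base()`) legitimately carry such mismatches. Read alignment
itself is out of scope; the module consumes aligned-read tables or bare
counts.

# The synthetic-data generator

All pipeline inputs can be generated with planted ground truth
(`sim_config()` + `gen_*()`, orchestrated by `simulate_study()`). Every
generator is a pure function of the configuration: one master seed,
stream-split by stage name (`substream_seed()`), so outputs are
byte-identical per seed and adding a stage never perturbs earlier streams.

What it emulates, and the defaults:

* **Genome** — 2 contigs × 2 Mbp composed of equal-length GC strata
  (defaults 0.35/0.55, spanning the GC range of typical regulatory
  regions); open chromatin as randomly sampled 2 kb tiles covering 60% of
  the genome; 300 uniformly placed TSSs.
* **Peak sets** — 150 query / 450 reference peaks, lengths ~N(200, 25²) bp
  (ChIP-seq scale), all inside open chromatin; a planted fraction (default
  0.65, the published co-occupancy regime) of query peaks placed to overlap
  a reference peak by ≥ 1 bp. The default density puts *chance* query-side
  co-occupancy near 8% — deliberately matching the regime where a sparse
  reference cistrome occupies a small share of open chromatin, as in real
  data, so that planted overlap is clearly separated from chance.
* **DE table** — null genes with log2FC ~ N(0, 0.3) and non-significant
  adjusted p; planted targets (default 30 down / 10 up) shifted by ±3 log2
  with adjusted p < 10⁻⁴. A 3-log2 shift at 0.3 noise is a strong direct-
  target response, sized so threshold recovery is exact and failures
  indicate real defects.
* **Genotypes** — LD blocks in which each SNP copies a latent block
  genotype with probability q per sample (default q = 0.975), giving
  expected within-block r² ≈ q⁴ ≈ 0.9 — tight-LD haplotype blocks — plus
  unlinked filler SNPs; 200 samples.
* **Allele reads** — per donor, `depth` (default 20, ATAC-scale at a single
  SNP) filter-passing reads, ref with probability r/(1+r) (default ratio
  3, the published imbalance magnitude); additional flagged reads
  (duplicates, low MAPQ, improper pairs; 10% of depth) and third-base reads
  (2%) exercise the filters. The truth record stores realised post-filter
  counts.

What it does **not** emulate: sequencing error and fragment-length models,
mappability structure, coalescent LD decay, peak-width/signal covariation,
or correlated gene expression. Passing tests therefore demonstrate the
*statistical machinery* — calibration, exact matching, planted-truth
recovery — not performance on the full complexity of real data.

# Problem sizes in the validation suite

The validation studies use toy scales chosen to make the statistical
properties measurable with comfortable margins: calibration runs 200
replicate tests (40 query / 120 reference peaks on a 2 × 200 kb genome,
199 permutations each); power runs 100 tests at 150/400 peaks on a
2 × 500 kb genome; oracle-equivalence checks use 100 random instances of
size ≤ 50 against brute-force implementations; parameter-recovery studies
use 100 seeds (LD, allelic imbalance) and 20 seeds (DE). At the allelic-
imbalance study's conditions (two donors, depth 20, ratio 3) the exact
detection probability of the two-sided pipeline, computed by enumerating
Binomial(20, 0.75) donor counts, is 0.752 — worth knowing when judging
observed detection rates at these depths.

# Known limitations

* The matched sampler's rejection scheme can stall when a template bin is
  rare in the open-chromatin universe; it fails loudly rather than
  approximately. Coarser bins are the intended fallback.
* Length matching is by resampling, not permutation, of template lengths;
  for heterogeneous length distributions the null is exchangeable only
  approximately (exactly, conditional on lengths).
* The LD estimator is genotypic (dosage) r²; no EM phasing is attempted.
* Motif scores are raw log-odds without a p-value calibration, so deltas
  are comparable within a PWM but not across PWMs of different widths.
* The allelic-imbalance model is binomial; overdispersion across donors or
  fragments (beta-binomial) is out of scope.
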