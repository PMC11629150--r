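---
title: "Methods: SNP panel selection, ED-based BSA-seq, and recombinant fine mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP panel selection, ED-based BSA-seq, and recombinant fine mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbtskit)
```

This vignette documents the models, rules and numerical choices behind
`gbtskit`, in the spirit of a methods section: what each stage assumes, which
parameters matter and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and where the design was
genuinely open.

## 1. The panel-selection cascade

A targeted genotyping (liquid-phase capture) array needs SNPs whose 201-bp
probe context behaves well during hybridisation. The cascade applies five
pure per-site predicates, in a fixed order that only affects the audit
bookkeeping, never the final set:

1. **Biallelic SNP restriction.** Multiallelic records and indels are dropped
   at parse time and tallied, not split: the downstream filters and the ED
   statistic are defined on biallelic sites, and splitting would manufacture
   sites the filters were never meant to see.
2. **MAF and missingness.** Minor-allele frequency is computed over called
   diploid genotypes only, so `maf <= 0.5` by construction. The MAF bound is
   *inclusive* (`maf >= 0.05` kept) while the missingness bound is *strict*
   (`missing_rate < 0.50` kept); half-called genotypes count as fully
   missing. A site rejected here is tallied under the first failing rule
   (MAF before missingness).
3. **Flank completeness, N and GC.** The 100-bp windows ending at `pos - 1`
   and starting at `pos + 1` must both lie fully inside the chromosome
   (probes need complete context, so incomplete flanks fail), contain no N,
   and each have GC strictly inside (0.40, 0.60). The GC rule is applied per
   flank — both windows are tested independently — with strict inequalities
   at both bounds. N bases are excluded from the GC denominator; this is moot
   after the no-N rule but keeps `gc_fraction()` well defined on arbitrary
   input.
4. **Single-copy probe context.** The 201-bp probe (flank + SNP + flank) is
   searched against the whole genome; any second locus with an ungapped exact
   match of at least 120 bp (60% of the probe) disqualifies the site. The
   built-in search is seed-and-verify: seeds of length `floor(120/2) = 60`
   tile the probe without gaps, so *every* exact match of length >= 120
   necessarily contains a full seed and is found; candidates are then
   verified by their longest exact run, which is how matches of 119 bp and
   120 bp are told apart exactly. Diverged copies are found only when they
   retain one intact seed — aligner-grade best effort. For production
   genomes, `select_panel(external_hits = ...)` accepts a hit table from a
   dedicated aligner instead.
5. **Functional classification.** Using the longest annotated mRNA per gene
   (the annotation rarely says which isoform an array should care about, so
   the longest CDS chain is a deterministic, conventional choice), a site is
   `intergenic`, `noncoding_genic`, or — inside a CDS — classified by
   translating the reference and alternate codons with the standard genetic
   code, strand-aware: `start_codon_change` (first CDS codon ATG disrupted),
   `stop_codon_change` (stop gained or lost), `synonymous` or
   `nonsynonymous`. Classification annotates; it does not filter.

Every rejected site lands in exactly one tally, so
`sum(rejections) + survivors == inputs` is an invariant the tests enforce.
`density_report()` bins the surviving panel (1-Mb bins by default — the usual
resolution of chromosome-density plots, configurable), and `thin_panel()`
offers greedy minimum-spacing down-sampling for the case where more sites
survive than an array can carry; no claim is made that this is how any
particular published array chose its final complement, because the survivor-
to-panel selection rule is generally not published.

## 2. The BSA-seq Euclidean-distance statistic

Two bulks of phenotypically extreme F2 individuals are sequenced as pools.
At each informative site (pool genotype calls differ), each pool's reads are
reduced to a base-frequency vector `p = (p_A, p_C, p_G, p_T)` and compared by

$$ED = \sqrt{\sum_{b \in \{A,C,G,T\}} (p_{1,b} - p_{2,b})^2},$$

which is 0 for identical pools and at most sqrt(2) for biallelic sites. The
working signal is `ED^k` with **k = 2 by default**: squaring shrinks the
many small background values (sampling noise is O(1/sqrt(depth))) much more
than the large linked values. `k` is configurable because values up to 5 are
in circulation in ED-based pipelines.

**SNPNUM window fitting.** The per-site signal is smoothed with a median over
windows of a fixed *number of SNPs* (not a fixed bp width), 101 SNPs by
default, stepping one site at a time. SNP-count windows adapt to marker
density — exactly the behaviour wanted on an array whose spacing varies —
and the median is robust to single-site artefacts. Windows shrink
symmetrically at chromosome ends, never span chromosomes, and degrade to the
whole-chromosome median when a chromosome holds fewer sites than the window.
The window must be >= 3 sites.

**Depth floor.** Sites where either pool has total depth below 10 reads are
excluded from the profile: with fewer reads the frequency vectors are too
noisy to be worth smoothing. Configurable (`min_depth`).

**Thresholding and interval calling.** No universal threshold rule exists
for fitted ED profiles, so the package documents an explicit default —
`median(fitted) + 3 * sd(fitted)` genome-wide — with an empirical-quantile
alternative. Candidate intervals are maximal runs of at least `min_sites`
(default 10) consecutive sites strictly above the threshold; runs separated
by fewer than `gap_sites` below-threshold sites can be merged (default 1,
i.e. no merging). Intervals are reported with their physical span, length in
bp and Mb, and ranked by peak fitted value.

**Depth-axis projection.** Pooled VCFs carry ref/alt allele depths, while the
statistic is defined on four base depths; AD values are projected onto the
A/C/G/T axes at the ref and alt bases, other bases getting zero. This is
exact for biallelic sites.

## 3. F2 segregation and descriptive statistics

`chi_square_3to1()` is the uncorrected Pearson statistic against expected
counts `(3/4 n, 1/4 n)` with 1 df and critical value 3.841; on 1084:351 the
statistic is 0.22. **No Yates continuity correction** is applied: the
corrected statistic on those counts would be ~0.20, and the convention in
segregation testing (and the arithmetic this package is checked against) is
the uncorrected form. The calibration of the critical value is itself tested:
on 10,000 binomial draws from a true 3:1 ratio the rejection rate is ~5%.

`describe_fsi()` uses divisor-n central moments: skewness
`g1 = m3 / m2^{3/2}` and *excess* kurtosis `g2 = m4 / m2^2 - 3` (an excess
convention is required for the negative kurtosis values typical of flat-ish
F2 index distributions), sample sd with divisor n−1, and `CV% = 100 sd/mean`.
Small-sample bias-corrected G1/G2 are available behind `bias_correct = TRUE`.
Constant input yields sd 0, CV 0 and undefined (NA) shape moments.

`classify_shape()` puts the boundary in the round class (`fsi <= 1` round,
`fsi > 1` oval). The separate pool-construction cutoffs (<= 0.9 and > 1.2)
are deliberately *not* the classification rule: they select extreme tails
for pooling and live in `make_pools(use_thresholds = TRUE)`.

## 4. Recombinant fine mapping

Model: one causal locus, maternal allele dominant (oval). Then every round
individual is paternal-homozygous (`B`) at the locus and every oval
individual is not `B` there. The marker map partitions the chromosome into
candidate regions — marker points and open inter-marker gaps. For each
individual the implied genotype of a region is its own call at a marker, and
at a gap (or missing marker) the shared value of the nearest non-missing
flanking markers when they agree; when they disagree the region is
uninformative for that individual, because a crossover somewhere in between
makes any genotype possible. A region is excluded when any individual's
implied genotype contradicts its phenotype; note that dominant-class (oval)
individuals only ever exclude where they are `B` — heterozygous or
maternal-homozygous stretches cannot distinguish `AA` from `Aa`. The
consistent zone is reported as the physical interval between its boundary
markers; with no recombinants the zone is the whole map, i.e. no narrowing.

Interval lengths are reported as `end - start + 1` bp (1-based inclusive
coordinates throughout) and as kb rounded to one decimal; at that rounding
the inclusive and exclusive conventions agree (e.g. markers at 81,539,936
and 82,252,537 give 712.6 kb either way).

Individuals with two or more breakpoints (double recombinants) are flagged
and excluded by default — in a dense interval map a genuine double crossover
is far less likely than a genotyping error — with `include_double = TRUE` as
the override. An empty consistent zone raises an error naming conflicting
individuals rather than returning something quietly wrong; phenotype
misclassification (e.g. classification noise near the FSI boundary) is the
usual cause.

`genes_in_interval()` uses an any-overlap rule by default (`mode = "within"`
for full containment). `scan_wbox()` reports the exact literal `TTGACC`
separately from the degenerate consensus `[CT]TGAC[TC]` and the invariant
core `TGAC`, on the forward sequence and its reverse complement (reverse
hits in reverse-complement coordinates, which makes the forward+reverse hit
multiset invariant under reverse complementing the input — a tested
property). `diff_alleles()` globally aligns two alleles with unit
match/mismatch scores and affine gaps (opening 4, extension 0.5; the high
opening-to-extension ratio makes one long indel preferable to scattered
short ones, which is the right prior for promoter indels) and reports each
substitution and contiguous indel with positions and lengths.

## 5. The synthetic-data generator

The generator exists so that every stage has a fixture with *recorded ground
truth*; all generators are bit-reproducible given a seed.

* `make_genome()` draws uniform-composition chromosomes (GC 0.5, so clean
  flanks pass the GC window with high probability and planted GC extremes
  stand out) and plants, verbatim and non-overlapping: duplicated segments,
  N runs and GC-extreme regions. Overlapping plantings are an error, not a
  warning, because overlapping features would make truth ambiguous.
* `make_population_vcf()` has two modes. In **construction** mode genotype
  counts are set deterministically so each site's MAF and missingness are
  hit exactly — used for filter truth tables where the test must predict
  every decision. In **sampling** mode genotypes are Hardy–Weinberg draws —
  used for statistical properties. Violating sites are placed inside the
  planted genome features (and re-checked against the actual flank sequence
  at generation time, resampling the position if a random flank would
  contradict the intended truth), so `select_panel()`'s decision is exactly
  predictable for all 100% of sites.
* `make_f2_cross()` simulates two gametes per individual over the marker map
  with the Haldane map function (no crossover interference) at 1 cM/Mb, a
  defensible desk-scale default for a solanaceous genome. The phenotype
  model is a two-component Gaussian: FSI ~ N(1.2, σ) with >= 1 dominant
  allele, N(0.9, σ) otherwise, σ = 0.04 (the parental replicate sd), class
  threshold 1.0. The F2-wide sd that emerges from the genotype mixture plus
  noise is ~0.13, larger than the ~0.09 observed in real F2 data — the
  real trait has polygenic background and measurement structure the
  two-Gaussian model does not attempt; the simulation is built to test
  *mapping machinery*, not to reproduce a phenotype distribution. With
  σ = 0.04 roughly 0.6% of recessives cross the 1.0 boundary, so segregation
  counts wobble realistically; fine-mapping fixtures use σ = 0 because a
  single misclassified non-recombinant contradicts every region under the
  single-locus model (and the package then raises its inconsistency error,
  which is the correct behaviour on such data).
* `make_pools()` takes the `n_extreme` lowest- and highest-FSI individuals
  (or fixed cutoffs <= 0.9 / > 1.2 via `use_thresholds`), then draws
  per-site pool depths Poisson(`depth_mean`) and maternal-allele reads
  binomially at the pool allele frequency — read-level error and mapping
  bias are not modelled.

**Study conditions used by the end-to-end tests and the acceptance script**
(chosen once, before measuring): 4 chromosomes x 90 Mb, 500 evenly spaced
markers each (2000 total), causal locus at chr3:81,900,000, cross n = 1435,
pools 30 + 30, mean depth 30x, ED power 2, window 101 SNPs, depth floor 10,
threshold median + 3 SD, `min_sites` 10. Under these conditions the
top-ranked interval contains the planted locus in >= 95 of 100 seeded
replicates (the test suite runs 100; the acceptance script reports 50 to
keep its runtime near a minute).

What passing these tests shows — and what it does not: the pipeline
correctly recovers a strong single dominant locus from idealised pooled
depths on a recombination-realistic cross. It does not show robustness to
polygenic traits, segregation distortion, reference bias, depth
heterogeneity along the genome, or LD structure of a real diversity panel,
none of which the generator emulates.

## 6. Degenerate inputs and tie-breaks

* Zero-depth pool sites are flagged unusable and excluded before fitting.
* All-missing sites have undefined MAF and `missing_rate = 1`; they fail the
  missingness rule.
* `call_threshold()` on a flat profile returns the constant, and strict
  `>` comparison then calls nothing — a flat genome has no candidate region.
* Ties in peak ranking keep the first site of the run (deterministic order).
* `fit_snpnum()` with an even window uses the asymmetric floor split; odd
  windows are recommended and the default.
* Coordinates are 1-based inclusive everywhere in memory; the only 0-based
  conversion happens in `write_bed()` at the file boundary.

## 7. Known limitations

* The built-in copy search guarantees completeness only for exact
  duplicates; production panel design should feed an external aligner's hit
  table through `external_hits`.
* The survivor-to-array final selection rule (how a cascade's survivors are
  cut down to a round array size) is intentionally left as the generic
  `thin_panel()`; published arrays rarely document this step.
* `informative_sites()` trusts the pools' genotype calls; no
  parental-polarisation step is implemented because parent genotypes are
  optional inputs that real pipelines handle upstream.
* The qPCR helper implements 2^−ΔΔCt only — no amplification-efficiency
  correction.
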