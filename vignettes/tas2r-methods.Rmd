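---
title: "Methods: population genetics of TAS2R haplotype diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics of TAS2R haplotype diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tas2rdiv` analyses phased, aligned coding-sequence haplotypes of the
chimpanzee bitter taste receptor family sampled from multiple subspecies.
This vignette records the statistical model behind each stage, the
parameters that matter, the numerical conventions, and the design decisions
taken where the methodology left genuine freedom.  It is the package's own
account of its methods; all empirical numbers quoted elsewhere are produced
by the test suite, the analysis scripts or `scripts/acceptance.R` at run
time.

## Data model and coordinates

The unit of observation is a phased chromosome: one FASTA record per
sampled chromosome per gene, aligned over the coding sequence.  Coding
positions are 1-based with the A of the annotated ATG start codon as
position 1; the alphabet is `A/C/G/T/N/-`.  A population manifest maps
chromosomes to subjects and populations and carries per-gene
whole-gene-deletion flags; a chromosome flagged deleted for a gene must be
absent from that gene's alignment (this invariant is enforced and tested).
The manifest is plain TSV rather than VCF because the observation is a
phased haplotype, not a genotype call.  FASTA output is wrapped at 60
columns; any input wrapping is accepted.  `N` is accepted on input and is
treated exactly like a gap for statistics (complete deletion of the
column): the upstream base-calling pipeline this emulates emitted
quality-filtered consensus bases, and no finer convention is defensible.

One denominator convention deserves note.  SNV allele frequencies are
reported over the chromosomes actually carrying the gene, i.e. excluding
whole-gene-deletion chromosomes (a chromosome without the gene cannot carry
an allele of it); whole-gene-deletion frequencies themselves are reported
over all sampled chromosomes.  Published catalogs sometimes print both over
the full sample; the combined non-functional frequency of a gene (pseudogene
carriers plus deleted chromosomes over all sampled chromosomes) is identical
under both conventions.

## Variant classification and functional status

Variants are called per alignment column against a designated reference
haplotype (for synthetic data, the ancestral sequence).  Substitutions are
classified by mutating the affected reference codon in isolation and
translating: loss_of_start (codon 1 ATG destroyed, taking precedence over
nonsynonymous), gain_of_stop (internal stop created), loss_of_stop
(terminal stop destroyed; a stop-to-stop change is synonymous), else
synonymous/nonsynonymous by the standard code.  Indels are maximal gap runs
against the reference, reported left-aligned at the first affected CDS
position, frameshifting when length ≢ 0 mod 3.

A haplotype is a segregating pseudogene when it has no ATG at positions 1–3
*and* none at 4–6 (the alternative-start rescue), or an internal stop
before the terminal codon, or a length not divisible by 3.  Whole-gene
deletions are non-functional by definition and form their own class with an
empty sequence key.  Protein-level haplotype classes key on the predicted
translation for functional alleles and on the lesion signature plus the
translation for pseudogenes, so two different inactivating mutations are
distinct classes even when their truncated products coincide — the
published per-haplotype pseudogene marking implies class-level resolution,
and collapsing them would silently merge independent mutation events.

## Diversity statistics

All diversity statistics are uncorrected proportions (no Jukes–Cantor
correction): intraspecific distances here are ≪ 1 and the correction is
far below reporting precision.  Internally everything is a raw proportion;
report tables multiply by 100 and say so.

* π: mean pairwise Hamming distance per site over all unordered pairs,
  after removing every column containing a gap or N (per analysis unit:
  per gene for within-population statistics, over the union of both
  populations for d<sub>XY</sub>).
* π<sub>S</sub>, π<sub>N</sub>: Nei–Gojobori.  Start and stop codons are
  removed, then every codon containing a gap or N in any haplotype.  Site
  counts per codon are the expected fractions of the 9 single-base changes
  that are synonymous; substitutions to stop codons count as
  nonsynonymous.  Pairwise differences average over all orderings of the
  differing positions, excluding pathways through stop codons whenever a
  stop-free pathway exists.  Site counts are averaged over all haplotypes
  in the sample.
* d<sub>XY</sub>: mean per-site difference over all n₁ × n₂
  between-population pairs.
* Per-site F<sub>ST</sub> = 1 − H<sub>W</sub>/H<sub>B</sub> with the
  unbiased within-population heterozygosity 2k(n−k)/(n(n−1)), H<sub>W</sub>
  the sample-size-weighted mean of the two populations, and H<sub>B</sub>
  the mean between-population difference probability.  This is the
  estimator family used by the standard DNA-polymorphism toolchain; the
  fixed-difference case (F<sub>ST</sub> = 1) is estimator-independent, and
  sites with zero between-population diversity are NA, never 0.
  Whole-gene-deletion chromosomes are excluded before computing counts.

Concatenated class statistics ("old" vs "human cluster" genes) drop
chromosomes deletion-flagged for *any* member gene, keeping the alignment
rectangular; π of a concatenation is then exactly the length-weighted mean
of per-gene π over gap-free sites, which the tests verify.

## Tajima's D and its coalescent null

D follows the standard 1989 normalisation from (n, S, k̄).  D is NA when
S = 0 and also when n < 4: the variance constants e₁ and e₂ vanish exactly
for n = 2, 3, so the statistic is undefined there rather than zero.

The null distribution is simulated under the standard neutral coalescent
without recombination: exponential waiting times with rate j(j−1)/2,
random pair merges, and mutations as a Poisson process along branches with
rate θ̂/2, where θ̂ = S/a₁ (Watterson) conditions the simulation on the
observed number of segregating sites.  Conditioning on θ̂ (rather than
fixing S) follows the stated simulation design of Poisson-distributed
mutations; a fixed-S mode is provided for sensitivity analysis.  Replicates
with S = 0 have undefined D and are retained in the tail denominators as
non-exceedances, which is conservative and deterministic.  Two-sided
p = 2·min(lower tail, upper tail), capped at 1 and floored at
1/replicates with a below-resolution flag.  The simulator is compiled
(Rcpp) and consumes R's RNG, so `set.seed()` reproduces it; 10,000
replicates per locus is the default.  Calibration is tested end to end: on
neutral synthetic loci (n = 20) the test's type-I error at α = 0.05 must
fall in [0.03, 0.07] over 500 loci.

## Selection tests on classes

π<sub>N</sub>/π<sub>S</sub> is tested against 1 by a two-sided Fisher exact
test on the 2×2 table of rounded mean pairwise nonsynonymous and synonymous
differences versus the remaining (invariant) nonsynonymous and synonymous
sites.  The exact table construction behind the published ratio test is not
printed anywhere; rounding mean pairwise counts to integers is this
package's interpretation, is recorded in the output, and should be
revisited if the original tables ever become reconstructable.  D
distributions are compared with non-coding reference loci by a two-sided
Wilcoxon rank-sum test, exact for combined sizes ≤ 20 and tie-corrected
normal otherwise, with NA (monomorphic) loci removed listwise.

## The sharing null

For two focal populations the per-gene metapopulation haplotype frequency
vector is, by default, the unweighted mean of the two populations'
frequency vectors (`mean_of_frequencies`); pooled counts over pooled
chromosomes (`pooled_counts`) are offered because the phrase "mean
frequencies for the total metapopulation" admits both readings, and the
analysis scripts report both.  Per replicate and per gene, two independent
multinomial samples of n₁ and n₂ chromosomes are drawn from that vector —
multinomial, not hypergeometric, because the null is defined by
frequencies, not a finite urn — and a class counts as shared when present
in both draws.  Whole-gene-deletion classes participate as ordinary
classes, and singleton classes stay in the frequency vector (they are
observed haplotypes).  The replicate totals are summarised by their mean
and SD; the probability of observing the actual shared total *or less* is
read off a fitted Gaussian, mirroring below-resolution reporting
(P < 0.0001), with the empirical replicate fraction also emitted.

## Gene-conversion tracts

For each distinct recipient haplotype, an informative site is a position
where the donor consensus differs from the recipient consensus, the
candidate carries the donor state, and the donor state is carried by fewer
than half of the other recipient chromosomes.  The strict form of the last
condition — donor state absent from *all* other recipients — breaks down
as soon as a tract segregates on more than one chromosome or background, so
the minority criterion is used instead; the tract frequencies this targets
(≲ 15%) sit far from the 50% boundary.  Tracts are maximal runs of
informative sites uninterrupted by discordant sites (donor/recipient-
divergent positions where the candidate sides with the recipient), require
at least `min_support = 2` informative sites to suppress single-site
homoplasy, and are reported at the outermost informative sites: true
endpoints between diagnostic sites are unidentifiable, so reported
intervals are minimal and always contained in the true tract extended to
the nearest diagnostic sites.  Paralogs are assumed to share a coordinate
frame (equal-length CDSs, true for the tandem receptor cluster genes);
pairs of unequal length are skipped by the pipeline rather than aligned
internally.

## Synthetic data generator

The generator is first-class, tested code that defines the study
conditions: 28 coding loci of 876–1002 bp (multiples of 3), populations of
92 and 20 chromosomes (a 19:9 split of "old" vs "human cluster" genes),
and θ = 0.001 per site, chosen to match the observed magnitude of
nucleotide diversity in this gene family (π of order 0.1%).  Per gene, an
ancestral ORF is drawn (ATG, random sense codons, terminal stop; internal
stops are excluded so gain-of-stop lesions are unambiguous), a shared
haplotype pool is sampled from the neutral coalescent under the infinite-
sites approximation (mutation positions drawn without replacement;
positions inside the start and terminal codons are reserved for lesions),
and population-private mutations — fixed and polymorphic, each at Poisson
rate `divergence_scale · θL` — create between-population differentiation;
`divergence_scale = 0` is exact panmixia.  Lesions (loss of start, gain of
stop, frameshift indel, whole-gene deletion, conversion tract) are
materialised at exact chromosome counts, `round(f·n)`, so the truth record
is exact; a frequency that rounds to zero carriers is a configuration
error, not a silent no-op.  A single master seed drives named substreams
(one per gene and per lesion stage), so adding genes or toggling stages
never perturbs earlier genes' data.

What the generator does *not* emulate: recombination within genes, within-
population substructure, sequencing error, back-mutation (infinite sites),
and realistic linkage between paralogs.  Green tests therefore demonstrate
correctness of the statistics and recovery of planted signals under this
model, not robustness to those real-data complications.

The analysis scripts also use the generator for the non-coding reference
panel (26 loci, 10 + 10 chromosomes).  Its divergence parameter (0.05) is
calibrated so the panel reproduces the defining property of the empirical
reference distribution — F<sub>ST</sub> above 0.6 with less than 5%
probability — which is what the outlier screen consumes.

## Numerical conventions and degenerate inputs

* π, d<sub>XY</sub> are NA when n < 2 or no columns survive complete
  deletion; π<sub>S</sub> is NA when no synonymous sites remain.
* F<sub>ST</sub> requires n ≥ 2 in both populations and is NA at zero
  between-population diversity.
* Empirical tail probabilities count ties in the tail
  (P(ref ≥ value)).
* Donor consensus ties break toward the donor reference haplotype.
* Report floats: diversity values at 3 decimals (on the ×100 scale),
  simulation means and SDs at 1 decimal; identical inputs produce
  byte-identical reports.
* All Monte Carlo stages take explicit seeds; the pipeline derives
  per-stage substreams from one master seed.

## Problem sizes used in the checks

The test suite exercises oracle equivalence at n ≤ 6, L ≤ 30 (where brute
force is exact and instant), classifier enumeration over all 64 codons × 9
mutations, type-I calibration of the coalescent D test over 500 neutral
loci at 2,000 null replicates each, sharing-null coverage over 20 full-size
(28-gene, 112-chromosome) panmictic datasets at 2,000 replicates, and tract
recall over 12–15 replicate datasets.  The analysis scripts run the
full-size design at 10,000 null replicates.  These sizes were chosen so the
whole suite completes in about a minute and a half on one CPU while keeping
every Monte Carlo acceptance band several standard errors wide.

## Known limitations

* The per-site F<sub>ST</sub> estimator is one member of a family; printed
  values from other toolchains can differ by a few percent at intermediate
  frequencies (the fixed-difference value 1 is estimator-independent).
* The Fisher-table construction for the π<sub>N</sub>/π<sub>S</sub> test is
  an interpretation (see above).
* The conversion scan's informative-site criterion is deliberately simple;
  it recovers planted tracts with ≥ 2 diagnostic sites but is not
  guaranteed identical to legacy implementations, and tracts carried by a
  majority of recipients are outside its design envelope.
* Haplotype phasing, alignment, and network construction are out of scope:
  the package consumes phased, aligned input.
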