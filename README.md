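# tas2rdiv

Population-genetic analysis of bitter taste receptor (*TAS2R*) haplotype
diversification among chimpanzee subspecies.

Chimpanzee subspecies differ in their dietary repertoires, and the ~28
intact bitter taste receptor genes (c*TAS2R*s) are an obvious genetic
substrate for such differences: they are short (~876–1002 bp) single-exon
G-protein-coupled receptor genes that segregate not only amino-acid variants
but also *inactivating* alleles — loss of the ATG start codon, premature
stop codons, frameshift indels, and whole-gene deletions (CNVs) — as well as
alleles created by ectopic gene conversion between tandem paralogs.
`tas2rdiv` implements the complete analysis for phased, aligned
coding-sequence haplotypes sampled from two (or more) populations:

* **Variant catalog** — call substitutions and indels against a reference
  haplotype and classify them into the six coding classes (synonymous,
  nonsynonymous, loss of start, gain of stop, loss of stop, indel); classify
  whole haplotypes as functional or segregating pseudogenes, honouring the
  alternative-ATG rescue at positions 4–6; collapse haplotypes at the
  nucleotide and protein level and summarise how many classes are unique to
  one subspecies.
* **Diversity and divergence** — nucleotide diversity
  π (mean pairwise differences per site, Nei–Li), synonymous/nonsynonymous
  diversity π<sub>S</sub>, π<sub>N</sub> by Nei–Gojobori site counting with
  pathway averaging, between-population divergence d<sub>XY</sub>, and
  per-SNV F<sub>ST</sub> (Hudson-style 1 − H<sub>W</sub>/H<sub>B</sub>)
  screened against an empirical non-coding reference distribution.
* **Neutrality tests** — Tajima's D with a two-sided p-value from neutral
  coalescent simulation (Watterson-conditioned Poisson mutations, no
  recombination; compiled in C++), a Fisher exact test of
  π<sub>N</sub>/π<sub>S</sub> against neutrality on concatenated gene
  classes, and Wilcoxon comparison of D distributions with non-coding loci.
* **Sharing null** — a Monte Carlo null for the total number of haplotype
  classes two populations are *expected* to share under no differentiation,
  given the sampling depths and the observed metapopulation haplotype
  frequencies, with a Gaussian lower-tail probability for the observed
  total.
* **Gene-conversion scan** — Betrán-style detection of conversion tracts
  between paralogs from runs of donor-diagnostic informative sites, with
  minimal (outermost-informative-site) tract intervals.
* **Synthetic data** — a coalescent-based generator that emulates the whole
  study design (28 loci, 92 + 20 chromosomes, subspecies-skewed frequencies,
  segregating pseudogenes, whole-gene deletions, conversion tracts) with an
  exact truth record, so every stage is testable without external data.

## Worked example

Simulate a small two-subspecies dataset in which one gene segregates a
premature-stop pseudogene (15%) and a whole-gene deletion (15%) in the
eastern population, then run the full pipeline:

```r
library(tas2rdiv)

cfg <- synthetic_config(
  n_genes = 4, cds_length_range = c(900, 930),
  populations = c(western = 92, eastern = 20),
  theta_per_site = 0.001, divergence_scale = 0.3,
  lesion_specs = list(
    list(gene = 2, type = "gain_of_stop",        population = "eastern", frequency = 0.15),
    list(gene = 2, type = "whole_gene_deletion", population = "eastern", frequency = 0.15)),
  seed = 42)
ds  <- generate_dataset(cfg)
res <- run_pipeline(run_config(ds$alignments, ds$manifest,
                               replicates = 10000, seed = 42))

res$catalog$catalog_report
#  gene_id mutation     functional western    eastern
#   gene02      GTC Non-functional       0 3/17 (18%)
#   gene02      WGD Non-functional       0 3/20 (15%)
```

Both injected lesions are recovered: the gain-of-stop allele on 3 of the 17
eastern chromosomes still carrying the gene, and the whole-gene deletion on
3 of all 20 (deletion-flagged chromosomes are excluded from SNV
denominators).  The diversity table reports, per gene × population, π,
π<sub>S</sub>, π<sub>N</sub> (×100, i.e. percent), Tajima's D and
d<sub>XY</sub>:

```r
res$diversity$summary[res$diversity$summary$gene_id == "gene02", ]
#  gene_id population  n S    pi  pi_s  pi_n tajima_d  d_xy
#   gene02    western 92 6 0.129 0.213 0.101    0.011 0.138
#   gene02    eastern 17 5 0.125 0.163 0.113   -0.724 0.138
```

and the sharing null quantifies how far observed haplotype sharing falls
below the no-differentiation expectation:

```r
sh <- res$sharing$protein
# observed 5 shared protein haplotypes; null mean 16.3 (sd 1.6); P = 1.4e-12
```

## Analysis workflow

`analysis/01_simulate.R` … `analysis/06_gene_conversion.R` are thin
narrative drivers over the package functions: simulate the full 28-gene
study design, catalogue variation, compute diversity/F<sub>ST</sub> with an
outlier screen against a calibrated neutral reference panel, run the
selection tests, the sharing null (10,000 replicates) and the
gene-conversion scan.  Each writes its tables under `results/`.  Run them in
order from the repository root:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

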