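#!/usr/bin/env Rscript
# Step 2: catalogue variation.  Calls variants against the ancestral
# reference, classifies coding effects, collapses nucleotide- and
# protein-level haplotypes, and summarises how many haplotype classes are
# unique to one subspecies (with and without the high-frequency filter).

suppressPackageStartupMessages(library(tas2rdiv))

data_dir <- "results/data"
out <- "results"
gc <- read_gene_config(file.path(data_dir, "gene_config.tsv"))
man <- read_manifest(file.path(data_dir, "manifest.tsv"),
                     genes = gc$genes$gene_id)
rc <- run_config(data_dir, man, gene_config = gc, seed = 1,
                 stages = "catalog")
res <- run_pipeline(rc)

write_report(list(variant_catalog_report = res$catalog$catalog_report,
                  variants = res$catalog$variants), out)

for (lv in c("nucleotide", "protein")) {
  for (hf in c(FALSE, TRUE)) {
    cls <- res$catalog[[paste0("classes_", lv)]]
    s <- sharing_summary(cls, c("western", "eastern"),
                         high_frequency_only = hf)
    cat(sprintf("%s level%s: %d classes, %d unique to one subspecies, %d shared\n",
                lv, if (hf) " (high-frequency)" else "",
                s$total_classes, s$unique_to_one_population, s$shared))
  }
}
nf <- res$catalog$classes_protein
nf <- nf[nf$status == "nonfunctional", ]
cat(sprintf("non-functional protein classes: %d (%d pseudogene, %d whole-gene deletion)\n",
            nrow(nf), sum(nf$mechanism == "pseudogene"),
            sum(nf$mechanism == "whole_gene_deletion")))
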