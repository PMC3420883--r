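#!/usr/bin/env Rscript
# Step 1: simulate a dataset with the structure of the chimpanzee TAS2R
# study: 28 coding loci (~876-1002 bp), 92 western + 20 eastern phased
# chromosomes, moderate between-subspecies divergence, and the classes of
# inactivating variation seen in the real gene family - segregating
# pseudogenes (loss of start, premature stop, frameshift), whole-gene
# deletions shared across tandem paralogs, and an ectopic conversion tract.
# Writes per-gene FASTA alignments, the population manifest, the gene
# config and the truth record under results/data/.

suppressPackageStartupMessages(library(tas2rdiv))

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

lesions <- list(
  # western-specific pseudogenes
  list(gene = 1,  type = "frameshift_indel", population = "western",
       frequency = 0.24),
  list(gene = 6,  type = "loss_of_start",    population = "western",
       frequency = 0.76),
  list(gene = 5,  type = "gain_of_stop",     population = "western",
       frequency = 0.10),
  # eastern-specific: pseudogene + whole-gene deletion on the same gene
  # (the 15% + 15% configuration) and deletions on two tandem neighbours
  list(gene = 25, type = "gain_of_stop",       population = "eastern",
       frequency = 0.15),
  list(gene = 25, type = "whole_gene_deletion", population = "eastern",
       frequency = 0.15),
  list(gene = 23, type = "whole_gene_deletion", population = "eastern",
       frequency = 0.15),
  list(gene = 28, type = "whole_gene_deletion", population = "eastern",
       frequency = 0.15),
  # ectopic gene conversion between human-cluster paralogs
  list(gene = 25, type = "conversion_tract", donor = 22,
       interval = c(514, 586), population = "eastern", frequency = 0.10),
  list(gene = 28, type = "conversion_tract", donor = 20,
       interval = c(141, 273), population = "eastern", frequency = 0.10))

cfg <- synthetic_config(divergence_scale = 0.4, lesion_specs = lesions,
                        seed = seed)
ds <- generate_dataset(cfg)

for (g in names(ds$alignments)) {
  write_alignment(ds$alignments[[g]], file.path(out, paste0(g, ".fasta")))
}
write_manifest(ds$manifest, file.path(out, "manifest.tsv"))
gc_df <- ds$gene_config
gc_df$paralog_group <- ifelse(gc_df$gene_id %in%
                                c("gene20", "gene22", "gene25", "gene28"),
                              "cluster12", "")
write.table(gc_df, file.path(out, "gene_config.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ds$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genes, %d chromosomes (%d deletion flags)\n",
            length(ds$alignments), nrow(ds$manifest$entries),
            nrow(ds$manifest$deletions)))
cat(sprintf("injected %d non-SNV lesions; %d coalescent SNVs\n",
            sum(ds$truth$type != "snv"), sum(ds$truth$type == "snv")))
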