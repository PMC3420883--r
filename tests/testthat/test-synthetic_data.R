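small_cfg <- function(lesions = list(), seed = 1, d = 0, genes = 2,
                      pops = c(western = 10, eastern = 6)) {
  synthetic_config(n_genes = genes, cds_length_range = c(90, 120),
                   populations = pops, theta_per_site = 0.01,
                   divergence_scale = d, lesion_specs = lesions, seed = seed)
}

test_that("same seed reproduces the dataset, different seeds differ", {
  d1 <- generate_dataset(small_cfg(seed = 5))
  d2 <- generate_dataset(small_cfg(seed = 5))
  d3 <- generate_dataset(small_cfg(seed = 6))
  expect_identical(lapply(d1$alignments, `[[`, "sequences"),
                   lapply(d2$alignments, `[[`, "sequences"))
  expect_identical(d1$truth, d2$truth)
  expect_false(identical(lapply(d1$alignments, `[[`, "sequences"),
                         lapply(d3$alignments, `[[`, "sequences")))
})

test_that("per-gene substreams: adding genes does not perturb earlier genes", {
  d2 <- generate_dataset(small_cfg(genes = 2, seed = 9))
  d4 <- generate_dataset(small_cfg(genes = 4, seed = 9))
  expect_identical(d2$alignments$gene01$sequences,
                   d4$alignments$gene01$sequences)
  expect_identical(d2$alignments$gene02$sequences,
                   d4$alignments$gene02$sequences)
})

test_that("degenerate pool: no mutations, no divergence -> monomorphic twins", {
  cfg <- synthetic_config(n_genes = 2, cds_length_range = c(90, 99),
                          populations = c(western = 6, eastern = 4),
                          theta_per_site = 0, divergence_scale = 0, seed = 2)
  ds <- generate_dataset(cfg)
  for (g in names(ds$alignments)) {
    seqs <- ds$alignments[[g]]$sequences
    expect_equal(length(unique(seqs)), 1L)
  }
  expect_equal(nrow(ds$truth), 0L)
})

test_that("lesion frequencies are materialized as exact counts", {
  lesions <- list(
    list(gene = 1, type = "whole_gene_deletion", population = "eastern",
         frequency = 3 / 20),
    list(gene = 2, type = "loss_of_start", population = "western",
         frequency = 0.25))
  ds <- generate_dataset(small_cfg(lesions, seed = 4,
                                   pops = c(western = 12, eastern = 20)))
  wgd <- ds$manifest$deletions
  expect_equal(nrow(wgd), 3L)
  expect_true(all(wgd$gene == "gene01"))
  expect_true(all(grepl("^eastern", wgd$chromosome)))
  # flagged chromosomes left the alignment
  expect_false(any(wgd$chromosome %in% names(ds$alignments$gene01$sequences)))
  lic <- ds$truth[ds$truth$type == "loss_of_start", ]
  expect_equal(lic$count_western, 3)  # round(0.25 * 12)
  expect_equal(lic$count_eastern, 0)
})

test_that("infeasible lesion frequencies are rejected", {
  bad <- list(list(gene = 1, type = "loss_of_start", population = "eastern",
                   frequency = 0.01))   # round(0.01 * 6) = 0
  expect_error(generate_dataset(small_cfg(bad)), "infeasible")
  expect_error(synthetic_config(lesion_specs = list(
    list(gene = 1, type = "loss_of_start", frequency = 1.2))), "frequency")
})

test_that("conversion tract injection rewrites exactly the interval", {
  set.seed(11)
  rec <- make_aln(random_seqs(5, 900), "rec")
  don <- make_aln(random_seqs(4, 900), "don")
  out <- inject_conversion_tract(rec, don, c(514, 586), c("chr01", "chr03"))
  m0 <- do.call(rbind, strsplit(rec$sequences, ""))
  m1 <- do.call(rbind, strsplit(out$sequences, ""))
  changed <- which(m0 != m1, arr.ind = TRUE)
  expect_true(all(changed[, "col"] >= 514 & changed[, "col"] <= 586))
  expect_true(all(rownames(m1)[changed[, "row"]] %in% c("chr01", "chr03")))
  # the full 73 bp span now carries the donor consensus on the carriers
  expect_equal(586 - 514 + 1, 73)
  expect_identical(substr(out$sequences[["chr01"]], 514, 586),
                   substr(out$sequences[["chr03"]], 514, 586))

  out2 <- inject_conversion_tract(rec, don, c(141, 273), "chr02")
  diffcols <- which(do.call(rbind, strsplit(out2$sequences, "")) !=
                      m0, arr.ind = TRUE)[, "col"]
  expect_true(all(diffcols >= 141 & diffcols <= 273))
  expect_equal(273 - 141 + 1, 133)

  expect_identical(inject_conversion_tract(rec, don, c(514, 586),
                                           character(0))$sequences,
                   rec$sequences)
  expect_error(inject_conversion_tract(rec, don, c(0, 50), "chr01"), "interval")
  expect_error(inject_conversion_tract(rec, don, c(890, 905), "chr01"),
               "interval")
})

test_that("every injected lesion is recovered by the variant catalog", {
  set.seed(77)
  types <- c("loss_of_start", "gain_of_stop", "frameshift_indel")
  for (rep in 1:100) {
    type <- sample(types, 1)
    pop <- sample(c("western", "eastern"), 1)
    freq <- sample(c(0.2, 0.3, 0.5), 1)
    cfg <- small_cfg(list(list(gene = 1, type = type, population = pop,
                               frequency = freq)),
                     seed = 1000 + rep, genes = 1)
    ds <- generate_dataset(cfg)
    tr <- ds$truth[ds$truth$type == type, ]
    expect_equal(nrow(tr), 1L)
    v <- call_variants(ds$alignments$gene01, ds$manifest)
    expected_effect <- switch(type, loss_of_start = "loss_of_start",
                              gain_of_stop = "gain_of_stop",
                              frameshift_indel = "indel")
    hit <- v[v$position == tr$position & v$effect == expected_effect, ]
    expect_equal(nrow(hit), 1L,
                 info = sprintf("rep %d type %s", rep, type))
    expect_equal(hit$count_western, tr$count_western)
    expect_equal(hit$count_eastern, tr$count_eastern)
    if (type == "frameshift_indel") expect_true(hit$frameshift)
  }
})
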