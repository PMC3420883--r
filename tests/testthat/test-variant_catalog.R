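# Reference ORF used across classifier tests: ATG + internal codon + TGG +
# TAA, so codon 2 is strictly internal.
frame_for <- function(codon) paste0("ATG", codon, "TGGTAA")

call_one <- function(ref, sample) {
  aln <- make_aln(c(ref, sample), ids = c("ref", "smp"))
  man <- make_manifest(c("ref", "smp"), 1)
  call_variants(aln, man, reference_id = "ref")
}

test_that("substitution effects agree with codon-table enumeration for all
           64 codons x 9 single-base mutations", {
  for (codon in names(GC_TABLE)) {
    if (codon %in% c("TAA", "TAG", "TGA")) next  # no internal stops in an ORF
    for (p in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
        mut <- codon; substr(mut, p, p) <- b
        v <- call_one(frame_for(codon), frame_for(mut))
        expect_equal(nrow(v), 1L)
        expected <- if (aa_of(mut) == "*") "gain_of_stop"
        else if (aa_of(mut) == aa_of(codon)) "synonymous"
        else "nonsynonymous"
        expect_equal(v$effect, expected,
                     info = sprintf("%s->%s", codon, mut))
        expect_equal(v$position, 3 + p)
      }
    }
  }
})

test_that("start/stop codon changes get their dedicated effect classes", {
  # loss of start takes precedence over nonsynonymous
  v <- call_one("ATGAAATGGTAA", "GTGAAATGGTAA")
  expect_equal(v$effect, "loss_of_start")
  expect_equal(v$position, 1)
  # destroying the terminal stop
  v <- call_one("ATGAAATGGTAA", "ATGAAATGGTAC")
  expect_equal(v$effect, "loss_of_stop")
  # stop-to-stop change at the terminal codon is synonymous
  v <- call_one("ATGAAATGGTAA", "ATGAAATGGTAG")
  expect_equal(v$effect, "synonymous")
  # identical sequences: no variants
  v <- call_one("ATGAAATGGTAA", "ATGAAATGGTAA")
  expect_equal(nrow(v), 0L)
})

test_that("indels are called as gap runs with frameshift annotation", {
  ref <- paste0("ATG", strrep("AAC", 6), "TAA")
  # 5-base deletion -> frameshift
  smp <- ref
  substr(smp, 7, 11) <- "-----"
  v <- call_one(ref, smp)
  expect_equal(v$effect, "indel")
  expect_true(v$frameshift)
  expect_equal(v$position, 7)
  expect_equal(nchar(v$ref_state), 5)
  # 3-base deletion -> in frame
  smp2 <- ref
  substr(smp2, 7, 9) <- "---"
  v2 <- call_one(ref, smp2)
  expect_false(v2$frameshift)
  # insertion: gap in the reference
  refg <- paste0("ATGAAC", "--", strrep("AAC", 5), "TAA")
  smpg <- paste0("ATGAAC", "GT", strrep("AAC", 5), "TAA")
  v3 <- call_one(refg, smpg)
  expect_equal(v3$effect, "indel")
  expect_equal(v3$alt_state, "GT")
  expect_true(v3$frameshift)
  expect_equal(v3$position, 7)  # first affected CDS position
})

test_that("functional status implements the pseudogene rules", {
  orf <- paste0("ATG", strrep("GCT", 8), "TAA")
  expect_equal(functional_status(orf)$status, "functional")
  # loss of start rescued by alternative ATG at 4-6
  rescued <- paste0("GTGATG", strrep("GCT", 7), "TAA")
  expect_equal(functional_status(rescued)$status, "functional")
  # loss of start, no rescue
  broken <- paste0("GTGGCT", strrep("GCT", 7), "TAA")
  fs <- functional_status(broken)
  expect_equal(fs$status, "nonfunctional")
  expect_equal(fs$mechanism, "pseudogene")
  # internal premature stop
  gtc <- paste0("ATG", strrep("GCT", 3), "TAA", strrep("GCT", 4), "TAA")
  expect_equal(functional_status(gtc)$status, "nonfunctional")
  # frameshift length
  fshift <- paste0("ATG", strrep("GCT", 8), "TA")
  expect_equal(functional_status(fshift)$status, "nonfunctional")
  # whole-gene deletion marker
  wgd <- functional_status(deletion_marker())
  expect_equal(wgd$mechanism, "whole_gene_deletion")
  expect_error(functional_status(""), "empty")
})

test_that("haplotype collapsing separates levels and conserves counts", {
  # two nucleotide haplotypes differing synonymously -> one protein class
  s1 <- paste0("ATG", "TTT", strrep("GCT", 5), "TAA")
  s2 <- paste0("ATG", "TTC", strrep("GCT", 5), "TAA")
  aln <- make_aln(c(s1, s1, s2, s2), "g1")
  man <- make_manifest(sprintf("chr%02d", 1:4), 2)
  nuc <- collapse_haplotypes(aln, man, "nucleotide")
  pro <- collapse_haplotypes(aln, man, "protein")
  expect_equal(nrow(nuc), 2L)
  expect_equal(nrow(pro), 1L)
  expect_equal(sum(nuc$count_western + nuc$count_eastern), 4)

  # whole-gene deletions form one class counted from the manifest
  ids <- sprintf("chr%02d", 1:8)
  man2 <- make_manifest(ids, 4,
                        deletions = data.frame(chromosome = ids[6:8],
                                               gene = "g1"))
  aln2 <- make_aln(rep(s1, 5), "g1", ids = ids[1:5])
  cls <- collapse_haplotypes(aln2, man2, "protein")
  del <- cls[cls$mechanism == "whole_gene_deletion", ]
  expect_equal(nrow(del), 1L)
  expect_equal(del$count_eastern, 3)
  expect_equal(del$key, "")
  # conservation: classes + deletions account for every chromosome
  expect_equal(sum(cls$count_western + cls$count_eastern), 8)

  # distinct pseudogene lesions stay distinct protein classes
  gtc1 <- paste0("ATG", "TAA", strrep("GCT", 5), "TAA")
  gtc2 <- paste0("ATG", "GCT", "TAA", strrep("GCT", 4), "TAA")
  aln3 <- make_aln(c(gtc1, gtc2), "g1", ids = c("a", "b"))
  man3 <- make_manifest(c("a", "b"), 1)
  expect_equal(nrow(collapse_haplotypes(aln3, man3, "protein")), 2L)
})

test_that("collapse -> sharing conserves counts on random synthetic data", {
  for (seed in c(3, 17)) {
    ds <- generate_dataset(synthetic_config(
      n_genes = 3, cds_length_range = c(90, 120),
      populations = c(western = 10, eastern = 6), theta_per_site = 0.01,
      lesion_specs = list(list(gene = 2, type = "whole_gene_deletion",
                               population = "eastern", frequency = 0.5)),
      seed = seed))
    for (g in names(ds$alignments)) {
      cls <- collapse_haplotypes(ds$alignments[[g]], ds$manifest, "protein")
      expect_equal(sum(cls$count_western), 10)
      expect_equal(sum(cls$count_eastern), 6)
    }
  }
})

test_that("sharing summary counts unique vs shared classes with the
           high-frequency filter", {
  cls <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2"), level = "protein",
    key = c("A", "B", "C", "D"), status = "functional", mechanism = "none",
    count_western = c(5, 1, 3, 0), count_eastern = c(2, 0, 1, 4))
  s <- sharing_summary(cls, c("western", "eastern"))
  expect_equal(s$total_classes, 4)
  expect_equal(s$shared, 2)
  expect_equal(s$unique_to_one_population, 2)
  expect_equal(s$unique_to_one_population + s$shared, s$total_classes)

  # singletons removed first under the high-frequency filter
  sh <- sharing_summary(cls, c("western", "eastern"),
                        high_frequency_only = TRUE)
  expect_equal(sh$total_classes, 3)
  expect_equal(sh$unique_to_one_population, 1)

  # all classes present in both populations -> unique = 0
  both <- cls; both$count_eastern <- c(2, 1, 1, 4); both$count_western <- 1
  expect_equal(sharing_summary(both,
                               c("western", "eastern"))$unique_to_one_population,
               0)
  expect_error(sharing_summary(cls, c("western", "north")), "unknown")
})

test_that("deletion spans use 1-based inclusive arithmetic", {
  expect_equal(deletion_span(11257350, 11324679), 67330)
  expect_equal(deletion_span(11256872, 11324827), 67956)
  expect_equal(deletion_span(5, 5), 1)
  expect_error(deletion_span(10, 9), "start > end")
})

test_that("catalog table reports inactivating variants with frequencies", {
  # eastern population of 20: 3 chromosomes with a premature stop, 3 whole-
  # gene deletions (the cTAS2R46-style configuration)
  orf <- paste0("ATG", strrep("CAA", 8), "TGG", "TAA")
  gtc <- orf
  substr(gtc, 7, 7) <- "T"   # CAA -> TAA internal stop
  ids <- sprintf("e%03d", 1:20)
  man <- make_manifest(ids, 0, pops = c("western", "eastern"),
                       deletions = data.frame(chromosome = ids[18:20],
                                              gene = "g46"))
  # 17 sampled haplotypes (ids 18:20 are deletion-flagged), plus reference
  aln <- make_aln(c(orf, rep(orf, 14), rep(gtc, 3)), "g46",
                  ids = c("ref", ids[1:17]))
  v <- call_variants(aln, man, reference_id = "ref")
  tab <- catalog_table(v, aln, man)
  expect_setequal(tab$mutation, c("GTC", "WGD"))
  expect_true(all(tab$functional == "Non-functional"))
  expect_equal(tab$eastern[tab$mutation == "GTC"], "3/17 (18%)")
  expect_equal(tab$eastern[tab$mutation == "WGD"], "3/20 (15%)")
  # combined non-functional frequency over all sampled chromosomes: 30%
  carriers <- v$count_eastern[v$effect == "gain_of_stop"]
  expect_equal((carriers + 3) / 20, 0.30)
})
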