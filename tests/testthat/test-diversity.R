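test_that("pi matches definition on simple cases", {
  aln <- make_aln(rep(strrep("ACGT", 25), 4))
  expect_equal(nucleotide_diversity(aln)$pi, 0)

  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("A", 99), "C")
  r <- nucleotide_diversity(make_aln(c(s1, s2)))
  expect_equal(r$pi, 0.01)
  expect_equal(r$S, 1L)
  expect_equal(r$L, 100L)

  # n < 2 and all-gap columns give NA
  expect_true(is.na(nucleotide_diversity(make_aln(s1))$pi))
  expect_true(is.na(nucleotide_diversity(make_aln(c("--", "--")))$pi))
})

test_that("pi, dxy and Tajima's D match brute-force oracles on random
           alignments with gap and N columns", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:6, 1); L <- sample(10:30, 1)
    seqs <- random_seqs(n, L, alphabet = c("A", "C", "G", "T", "A", "C",
                                           "G", "T", "-", "N"))
    # ensure at least one clean column so L > 0
    seqs <- paste0(seqs, "A")
    aln <- make_aln(seqs)
    r <- nucleotide_diversity(aln)
    expect_equal(r$pi, oracle_pi(seqs), tolerance = 1e-12)
    td <- tajimas_d(aln)
    expect_equal(td$D, oracle_tajima_d(seqs), tolerance = 1e-12)

    nb <- sample(2:5, 1)
    seqs_b <- paste0(random_seqs(nb, L), "A")
    d <- dxy(aln, make_aln(seqs_b))
    expect_equal(d$d_xy, oracle_dxy(seqs, seqs_b), tolerance = 1e-12)
  }
})

test_that("statistics are invariant under chromosome relabeling", {
  set.seed(7)
  seqs <- random_seqs(5, 24)
  a <- make_aln(seqs)
  b <- make_aln(sample(seqs))
  expect_equal(nucleotide_diversity(a)$pi, nucleotide_diversity(b)$pi)
  expect_equal(tajimas_d(a)$D, tajimas_d(b)$D)
})

test_that("Nei-Gojobori site counts match enumeration for all 64 codons", {
  for (codon in names(GC_TABLE)) {
    if (aa_of(codon) == "*") next
    got <- nei_gojobori_sites(codon)
    want <- oracle_ng_sites_codon(codon)
    expect_equal(unname(got), want, tolerance = 1e-12, info = codon)
    expect_equal(sum(got), 3)
  }
  expect_equal(unname(nei_gojobori_sites("TTT")),
               c(1 / 3, 8 / 3), tolerance = 1e-12)
  expect_error(nei_gojobori_sites("ACGT"), "multiple of 3")
})

test_that("pathway-averaged codon differences match exhaustive enumeration
           for all two-position codon pairs", {
  expect_equal(unname(nei_gojobori_differences("TTT", "GTA")),
               c(0.5, 1.5), tolerance = 1e-12)
  codons <- names(GC_TABLE)
  sense <- codons[GC_TABLE != "*"]
  set.seed(5)
  # all two-position pairs among a deterministic codon subset, plus random
  # three-position pairs
  for (c1 in sense[seq(1, length(sense), by = 4)]) {
    for (c2 in codons) {
      npos <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      if (npos != 2) next
      got <- nei_gojobori_differences(c1, c2)
      want <- oracle_ng_pair(c1, c2)
      expect_equal(unname(got), unname(want), tolerance = 1e-12,
                   info = paste(c1, c2))
    }
  }
  for (i in 1:20) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    expect_equal(unname(nei_gojobori_differences(c1, c2)),
                 unname(oracle_ng_pair(c1, c2)), tolerance = 1e-12)
  }
})

test_that("piS/piN separate mutation classes and match the pair-and-pathway
           oracle on random alignments", {
  # fixed population
  orf <- paste0("ATG", strrep("CTG", 6), "TAA")
  r <- syn_nonsyn_diversity(make_aln(rep(orf, 3)))
  expect_equal(r$pi_s, 0)
  expect_equal(r$pi_n, 0)

  # one synonymous difference: piN = 0, piS > 0
  syn2 <- paste0("ATG", "CTA", strrep("CTG", 5), "TAA")
  r2 <- syn_nonsyn_diversity(make_aln(c(orf, syn2)))
  expect_equal(r2$pi_n, 0)
  expect_gt(r2$pi_s, 0)

  set.seed(303)
  for (rep in 1:6) {
    n <- sample(2:4, 1); ncod <- sample(4:8, 1)
    body <- random_codon_alignment(n, ncod)
    seqs <- paste0("ATG", body, "TAA")
    got <- syn_nonsyn_diversity(make_aln(seqs))
    want <- oracle_syn_nonsyn(body)
    expect_equal(got$pi_s, want$pi_s, tolerance = 1e-12)
    expect_equal(got$pi_n, want$pi_n, tolerance = 1e-12)
    expect_equal(got$syn_sites, want$syn_sites, tolerance = 1e-12)
  }
})

test_that("dxy handles trivial fixed-difference cases", {
  a <- make_aln(rep(strrep("A", 100), 3))
  expect_equal(dxy(a, make_aln(rep(strrep("A", 100), 2)))$d_xy, 0)
  b <- make_aln(rep(paste0(strrep("A", 99), "G"), 2))
  expect_equal(dxy(a, b)$d_xy, 0.01)
})

test_that("per-site FST: fixed difference gives 1, closed form elsewhere", {
  expect_identical(site_fst(0, 92, 20, 20), 1)
  expect_identical(site_fst(92, 92, 0, 20), 1)
  # identical frequencies: approximately 0
  expect_lt(abs(site_fst(46, 92, 10, 20)), 0.05)
  # independent closed-form computation for (70/92) vs (0/20)
  hw <- (92 * (2 * 70 * 22 / (92 * 91)) + 20 * 0) / 112
  hb <- (70 * 20 + 0) / (92 * 20)
  expect_equal(site_fst(70, 92, 0, 20), 1 - hw / hb, tolerance = 1e-12)
  # undefined when between-population diversity is zero
  expect_true(is.na(site_fst(0, 92, 0, 20)))
  expect_error(site_fst(0, 1, 5, 20), ">= 2")
})

test_that("FST never exceeds 1 and hits 1 only at fixed differences", {
  set.seed(9)
  for (i in 1:200) {
    na <- sample(2:92, 1); nb <- sample(2:20, 1)
    ka <- sample(0:na, 1); kb <- sample(0:nb, 1)
    f <- site_fst(ka, na, kb, nb)
    if (is.na(f)) next
    expect_lte(f, 1)
    fixed <- (ka %in% c(0, na)) && (kb %in% c(0, nb)) && (ka / na != kb / nb)
    expect_equal(f == 1, fixed)
  }
})

test_that("empirical percentile counts ties in the upper tail", {
  ref <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(empirical_percentile(0.05, ref), 1)
  expect_gte(empirical_percentile(0.3, ref), 0.5)
  expect_equal(empirical_percentile(0.9, ref), 0)
  expect_error(empirical_percentile(1, numeric(0)), "empty")
})

test_that("concatenation is length-weighted in pi and keeps gene order", {
  set.seed(55)
  a <- make_aln(random_seqs(4, 12), "gA")
  b <- make_aln(random_seqs(4, 30), "gB")
  cc <- concatenate_class(list(a, b))
  pa <- nucleotide_diversity(a); pb <- nucleotide_diversity(b)
  pc <- nucleotide_diversity(cc)
  expect_equal(pc$pi, (pa$pi * pa$L + pb$pi * pb$L) / (pa$L + pb$L),
               tolerance = 1e-12)
  # equal lengths -> plain mean
  b2 <- make_aln(random_seqs(4, 12), "gB")
  cc2 <- concatenate_class(list(a, b2))
  expect_equal(nucleotide_diversity(cc2)$pi,
               mean(c(nucleotide_diversity(a)$pi,
                      nucleotide_diversity(b2)$pi)), tolerance = 1e-12)
  # single gene is the identity
  expect_identical(concatenate_class(list(a))$sequences,
                   setNames(a$sequences, names(a$sequences)))
  # chromosomes missing from one gene are dropped (deletion policy)
  b3 <- make_aln(random_seqs(3, 30), "gB")
  cc3 <- concatenate_class(list(a, b3))
  expect_equal(length(cc3$sequences), 3L)
  expect_error(concatenate_class(list(a, b3), drop_missing = FALSE),
               "inconsistent")
})

test_that("the 19 old-class gene lengths concatenate to 17832 bp", {
  lens <- c(900, 912, 951, 900, 900, 978, 930, 939, 924, 912, 954, 876,
            1002, 1017, 972, 924, 945, 957, 939)
  alns <- lapply(seq_along(lens), function(i)
    make_aln(rep(strrep("A", lens[i]), 2), paste0("g", i)))
  expect_equal(concatenate_class(alns)$length, 17832)
})
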