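test_that("Tajima constants satisfy their defining identities", {
  for (n in c(4, 20, 92, 200)) {
    cc <- tajima_constants(n)
    expect_equal(cc$a1, sum(1 / seq_len(n - 1)), tolerance = 1e-12)
    expect_equal(cc$a2, sum(1 / seq_len(n - 1)^2), tolerance = 1e-12)
    expect_equal(cc$e1, (cc$b1 - 1 / cc$a1) / cc$a1, tolerance = 1e-12)
  }
})

test_that("Tajima's D matches an independent implementation and handles
           degenerate inputs", {
  # n=4, two singleton sites
  seqs <- c("AAAAAAAAAA", "AAAAAAAAAC", "AAAAGAAAAA", "AAAAAAAAAA")
  td <- tajimas_d(make_aln(seqs))
  expect_equal(td$S, 2L)
  expect_equal(td$D, oracle_tajima_d(seqs), tolerance = 1e-12)

  # monomorphic -> NA
  expect_true(is.na(tajimas_d(make_aln(rep("ACGTACGT", 5)))$D))

  # the variance term degenerates below n = 4: D undefined
  expect_true(is.na(tajimas_d(make_aln(c("AAAA", "CCAA")))$D))

  # k_bar == S/a1 -> D == 0: n = 4 with 8 singleton and 3 doubleton sites
  # gives sum of pair differences 8*3 + 3*4 = 36 = a1-scaled S exactly
  m <- matrix("A", nrow = 4, ncol = 11)
  for (s in 1:8) m[(s - 1) %% 4 + 1, s] <- "C"
  m[1:2, 9] <- "C"; m[3:4, 10] <- "C"; m[c(1, 3), 11] <- "C"
  zero <- make_aln(apply(m, 1, paste, collapse = ""))
  expect_equal(tajimas_d(zero)$S, 11L)
  expect_equal(tajimas_d(zero)$D, 0, tolerance = 1e-12)
})

test_that("coalescent null is reproducible, correctly sized and calibrated
           around Watterson's theta", {
  nul <- simulate_null_d(20, 10, replicates = 10000, seed = 3)
  expect_equal(length(nul$d_values), 10000L)
  nul2 <- simulate_null_d(20, 10, replicates = 10000, seed = 3)
  expect_identical(nul$d_values, nul2$d_values)
  expect_false(identical(
    nul$d_values, simulate_null_d(20, 10, 10000, seed = 4)$d_values))

  # mean S over replicates recovers theta_hat * a1 = S_obs within 2%
  expect_equal(mean(nul$s_values), 10, tolerance = 0.02)
  # neutral D distribution is centred near zero
  expect_lt(abs(mean(nul$d_values, na.rm = TRUE)), 0.1)

  # fixed-S conditioning pins the segregating count
  fx <- simulate_null_d(20, 7, replicates = 200, seed = 1,
                        conditioning = "fixed_S")
  expect_true(all(fx$s_values == 7L))
  expect_error(simulate_null_d(20, 10, replicates = 0), "replicates")
})

test_that("tajima_p is two-sided, floored at Monte Carlo resolution and
           sign-symmetric", {
  nul <- simulate_null_d(20, 8, replicates = 5000, seed = 11)
  med <- stats::median(nul$d_values, na.rm = TRUE)
  expect_gt(tajima_p(med, nul)$p, 0.9)

  extreme <- tajima_p(10, nul)
  expect_equal(extreme$p, 1 / 5000)
  expect_true(extreme$below_resolution)

  # flipping the sign of both D_obs and the null leaves p unchanged
  flipped <- nul
  flipped$d_values <- -nul$d_values
  d_obs <- 1.3
  expect_equal(tajima_p(d_obs, nul)$p, tajima_p(-d_obs, flipped)$p)

  expect_true(is.na(tajima_p(NA, nul)$p))
})

test_that("piN/piS Fisher test behaves at its anchors", {
  # many synonymous differences, none nonsynonymous: ratio 0, significant
  r <- pin_pis_test(counts = list(mean_nonsyn_diff = 0, mean_syn_diff = 12,
                                  nonsyn_sites = 700, syn_sites = 230))
  expect_equal(r$pi_n_over_pi_s, 0)
  expect_lt(r$p, 0.05)

  # proportional table: no association
  r2 <- pin_pis_test(counts = list(mean_nonsyn_diff = 10, mean_syn_diff = 10,
                                   nonsyn_sites = 500, syn_sites = 500))
  expect_equal(r2$pi_n_over_pi_s, 1)
  expect_equal(r2$p, 1)

  # tiny counts: no power (single difference on each side)
  r3 <- pin_pis_test(counts = list(mean_nonsyn_diff = 1, mean_syn_diff = 1,
                                   nonsyn_sites = 300, syn_sites = 300))
  expect_equal(r3$p, 1)

  # piS = 0: ratio undefined, no test
  orf <- paste0("ATG", strrep("CTG", 6), "TAA")
  expect_true(is.na(pin_pis_test(make_aln(rep(orf, 3)))$pi_n_over_pi_s))
})

test_that("Wilcoxon comparison of D distributions", {
  same <- c(-0.5, 0.1, 0.8)
  r <- compare_d_distributions(same, same)
  expect_gt(r$p, 0.9)
  expect_equal(r$median_d, 0.1)

  set.seed(2)
  ref <- seq(-1.5, 1.5, length.out = 26)
  shifted <- seq(-1.5, 1.5, length.out = 20) + 2
  expect_lt(compare_d_distributions(shifted, ref)$p, 0.01)

  expect_equal(compare_d_distributions(0.3, 0.9)$p, 1)
  # NA values (monomorphic loci) are dropped listwise
  expect_equal(compare_d_distributions(c(NA, 0.3), c(0.9, NA))$p, 1)
  expect_true(is.na(compare_d_distributions(c(NA_real_), ref)$p))
})
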