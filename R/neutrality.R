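# Tajima's D with a coalescent-simulated null, the Fisher exact test on
# piN/piS counts, and the Wilcoxon comparison of D distributions against a
# non-coding reference panel.

#' Constants of Tajima's D for sample size n
#'
#' @param n Number of sampled chromosomes (>= 2).
#' @return Named list `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2L)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

# D from (n, S, k_bar); NA when S == 0 or the variance term degenerates
# (n < 4 makes e1 = e2 = 0).
tajima_d_from_counts <- function(n, S, k_bar) {
  if (S == 0L) return(NA_real_)
  cc <- tajima_constants(n)
  denom <- cc$e1 * S + cc$e2 * S * (S - 1)
  if (denom <= 0) return(NA_real_)
  (k_bar - S / cc$a1) / sqrt(denom)
}

#' Tajima's D of one population sample
#'
#' Standard Tajima (1989) statistic computed on gap/N-free columns:
#' `D = (k_bar - S/a1) / sqrt(e1 S + e2 S (S-1))` with `k_bar` the mean
#' pairwise difference count.
#'
#' @param alignment A [gene_alignment()] restricted to one population.
#' @return list with `n`, `S`, `k_bar`, the constants, and `D` (`NA` when
#'   `S == 0`).
#' @export
tajimas_d <- function(alignment) {
  m <- aln_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) {
    return(list(n = n, S = NA_integer_, k_bar = NA_real_, D = NA_real_))
  }
  m <- m[, clean_columns(m), drop = FALSE]
  seg <- vapply(seq_len(ncol(m)), function(j)
    length(unique(m[, j])) > 1L, logical(1))
  S <- sum(seg)
  k_bar <- pairwise_diff_total(m) / choose(n, 2)
  cc <- tajima_constants(n)
  c(list(n = n, S = as.integer(S), k_bar = k_bar,
         D = tajima_d_from_counts(n, S, k_bar)), cc)
}

#' Simulate the neutral coalescent null distribution of Tajima's D
#'
#' Standard neutral genealogies of `n` tips (no recombination), mutations
#' placed as a Poisson process along branches.  By default the mutation rate
#' is conditioned on Watterson's estimate `theta_hat = S_obs / a1`; the
#' alternative conditions on exactly `S_obs` segregating sites per
#' replicate.
#'
#' @param n Sampled chromosomes.
#' @param S_obs Observed segregating sites (>= 1).
#' @param replicates Number of genealogies (default 10000).
#' @param seed Integer seed.
#' @param conditioning `"theta_watterson"` (default) or `"fixed_S"`.
#' @return list of class `coalescent_null` with the simulated `d_values`
#'   (NA for non-segregating replicates), `replicates`, `conditioning`,
#'   `theta_hat`, `seed`.
#' @export
simulate_null_d <- function(n, S_obs, replicates = 10000L, seed = 1L,
                            conditioning = c("theta_watterson", "fixed_S")) {
  conditioning <- match.arg(conditioning)
  stopifnot(n >= 2L, S_obs >= 1L, replicates >= 1L)
  cc <- tajima_constants(n)
  theta_hat <- S_obs / cc$a1
  set.seed(seed)
  sim <- coal_null_d_cpp(as.integer(n), theta_hat, as.integer(replicates),
                         conditioning == "fixed_S", as.integer(S_obs),
                         cc$a1, cc$e1, cc$e2)
  structure(list(d_values = sim[, 1L], s_values = as.integer(sim[, 2L]),
                 replicates = as.integer(replicates),
                 conditioning = conditioning, theta_hat = theta_hat,
                 seed = seed, n = n, S_obs = S_obs),
            class = "coalescent_null")
}

#' Two-sided coalescent p-value for an observed Tajima's D
#'
#' `p = 2 * min(Pr(null <= D), Pr(null >= D))`, capped at 1.  Replicates
#' without segregating sites have undefined D and are retained in the
#' denominator as non-exceedances on both sides (conservative).  p is
#' floored at `1/replicates`, flagged with `below_resolution`.
#'
#' @param d_obs Observed D (`NA` gives `NA`).
#' @param null A `coalescent_null` from [simulate_null_d()].
#' @return list with `p`, `below_resolution`, `p_lower`, `p_upper`.
#' @export
tajima_p <- function(d_obs, null) {
  d <- null$d_values
  if (is.na(d_obs) || all(is.na(d))) {
    return(list(p = NA_real_, below_resolution = FALSE,
                p_lower = NA_real_, p_upper = NA_real_))
  }
  R <- length(d)
  p_lower <- sum(d <= d_obs, na.rm = TRUE) / R
  p_upper <- sum(d >= d_obs, na.rm = TRUE) / R
  p <- min(1, 2 * min(p_lower, p_upper))
  below <- p < 1 / R
  list(p = max(p, 1 / R), below_resolution = below,
       p_lower = p_lower, p_upper = p_upper)
}

#' Fisher exact test of piN/piS against neutrality
#'
#' Tests whether nonsynonymous diversity is reduced (or elevated) relative
#' to synonymous diversity: a two-sided Fisher exact test on the 2x2 table
#' of rounded mean pairwise nonsynonymous/synonymous differences against the
#' remaining (non-varying) nonsynonymous/synonymous sites.
#'
#' @param alignment A class-level [gene_alignment()] (typically a
#'   concatenation) restricted to one population; or supply the counts
#'   directly.
#' @param counts Optional list with `mean_nonsyn_diff`, `mean_syn_diff`,
#'   `nonsyn_sites`, `syn_sites` (overrides `alignment`).
#' @return list with `pi_n_over_pi_s`, `p`, and the 2x2 `table` used.
#' @export
pin_pis_test <- function(alignment = NULL, counts = NULL) {
  if (is.null(counts)) {
    sn <- syn_nonsyn_diversity(alignment)
    counts <- list(mean_nonsyn_diff = sn$mean_nonsyn_diff,
                   mean_syn_diff = sn$mean_syn_diff,
                   nonsyn_sites = sn$nonsyn_sites,
                   syn_sites = sn$syn_sites)
    ratio <- if (!is.na(sn$pi_s) && sn$pi_s > 0) sn$pi_n / sn$pi_s else NA_real_
  } else {
    pis <- counts$mean_syn_diff / counts$syn_sites
    pin <- counts$mean_nonsyn_diff / counts$nonsyn_sites
    ratio <- if (pis > 0) pin / pis else NA_real_
  }
  if (is.na(ratio)) {
    return(list(pi_n_over_pi_s = NA_real_, p = NA_real_, table = NULL))
  }
  nd <- round(counts$mean_nonsyn_diff)
  sd_ <- round(counts$mean_syn_diff)
  tab <- matrix(c(nd, sd_,
                  round(counts$nonsyn_sites) - nd,
                  round(counts$syn_sites) - sd_),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("differences", "invariant"),
                                c("nonsynonymous", "synonymous")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(pi_n_over_pi_s = ratio, p = p, table = tab)
}

#' Compare a set of per-gene Tajima's D values with a reference panel
#'
#' Two-sided Wilcoxon rank-sum test of the per-gene D values against the D
#' values of putatively neutral non-coding loci.  `NA` values (monomorphic
#' loci) are removed listwise.  Exact enumeration is used for combined
#' sample sizes up to 20, the tie-corrected normal approximation otherwise.
#'
#' @param d_genes Numeric vector of per-gene D values.
#' @param d_reference Numeric vector of reference-panel D values.
#' @return list with `median_d`, `p`, `n_genes`, `n_reference`.
#' @export
compare_d_distributions <- function(d_genes, d_reference) {
  d_genes <- d_genes[!is.na(d_genes)]
  d_reference <- d_reference[!is.na(d_reference)]
  if (!length(d_genes) || !length(d_reference)) {
    return(list(median_d = NA_real_, p = NA_real_,
                n_genes = length(d_genes), n_reference = length(d_reference)))
  }
  exact <- (length(d_genes) + length(d_reference)) <= 20L
  p <- suppressWarnings(
    stats::wilcox.test(d_genes, d_reference, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
  list(median_d = stats::median(d_genes), p = p,
       n_genes = length(d_genes), n_reference = length(d_reference))
}
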