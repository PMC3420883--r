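# Nucleotide diversity (pi), Nei-Gojobori synonymous/nonsynonymous
# diversity, between-population divergence (dXY), per-site FST, empirical
# FST percentiles, and class-level concatenation.

# Columns free of gaps and Ns across all rows (complete deletion).
clean_columns <- function(m) {
  which(colSums(m == "-" | m == "N") == 0L)
}

# Allele counts of one column over the fixed alignment alphabet.
state_counts <- function(x) {
  tabulate(factor(x, levels = ALN_ALPHABET), nbins = length(ALN_ALPHABET))
}

# Sum over columns of the number of differing unordered pairs, via allele
# counts: C(n,2) - sum_a C(c_a,2) per column.
pairwise_diff_total <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (j in seq_len(ncol(m))) {
    cnt <- state_counts(m[, j])
    tot <- tot + (choose(n, 2) - sum(choose(cnt, 2)))
  }
  tot
}

#' Nucleotide diversity (pi) of one population sample
#'
#' Mean pairwise nucleotide differences per site, computed after complete
#' deletion of every column containing a gap or N.
#'
#' @param alignment A [gene_alignment()] already restricted to one
#'   population (use [aln_subset()] / the manifest helpers).
#' @return list with `pi` (raw proportion), `L` (analysed sites), `S`
#'   (segregating sites) and `n` (chromosomes).  `pi` is `NA` when `n < 2`
#'   or `L == 0`.
#' @export
nucleotide_diversity <- function(alignment) {
  m <- aln_matrix(alignment)
  n <- nrow(m)
  keep <- clean_columns(m)
  L <- length(keep)
  if (n < 2L || L == 0L) {
    return(list(pi = NA_real_, L = L, S = NA_integer_, n = n))
  }
  m <- m[, keep, drop = FALSE]
  S <- sum(vapply(seq_len(ncol(m)), function(j)
    length(unique(m[, j])) > 1L, logical(1)))
  pi <- pairwise_diff_total(m) / choose(n, 2) / L
  list(pi = pi, L = L, S = as.integer(S), n = n)
}

#' Nei-Gojobori synonymous and nonsynonymous site counts for one sequence
#'
#' Per codon, the synonymous site count at each position is the fraction of
#' the 3 possible single-base substitutions that preserve the amino acid;
#' nonsynonymous sites are `3 * codons - synonymous sites`.  Changes to stop
#' codons count as nonsynonymous.
#'
#' @param sequence Ungapped codon string (length divisible by 3), with start
#'   and stop codons already removed.
#' @return c(syn_sites = ..., nonsyn_sites = ...)
#' @export
nei_gojobori_sites <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n %% 3L != 0L) stop("nei_gojobori_sites: length not a multiple of 3")
  if (n == 0L) return(c(syn_sites = 0, nonsyn_sites = 0))
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(sequence, starts, starts + 2L)
  tab <- ng_site_table()
  syn <- tab[codons]
  if (anyNA(syn)) {
    # codons with ambiguity or stops contribute no sites
    bad <- is.na(syn)
    syn[bad] <- 0
    nonsyn <- 3 * sum(!bad) - sum(syn)
  } else {
    nonsyn <- 3 * length(codons) - sum(syn)
  }
  c(syn_sites = sum(syn), nonsyn_sites = nonsyn)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codon
#' strings
#'
#' @param seq1,seq2 Ungapped codon strings of equal length.
#' @return c(syn_diff = ..., nonsyn_diff = ...)
#' @export
nei_gojobori_differences <- function(seq1, seq2) {
  stopifnot(nchar(seq1) == nchar(seq2), nchar(seq1) %% 3L == 0L)
  n <- nchar(seq1)
  if (n == 0L) return(c(syn_diff = 0, nonsyn_diff = 0))
  starts <- seq.int(1L, n - 2L, by = 3L)
  c1 <- substring(seq1, starts, starts + 2L)
  c2 <- substring(seq2, starts, starts + 2L)
  sd <- 0; nd <- 0
  for (i in which(c1 != c2)) {
    d <- ng_pair_diff(c1[i], c2[i])
    sd <- sd + d[["syn"]]
    nd <- nd + d[["nonsyn"]]
  }
  c(syn_diff = sd, nonsyn_diff = nd)
}

# Strip alignment to the internal codons used for piS/piN: remove the start
# codon and (if present) the terminal stop codon of the reference frame,
# then drop every codon containing a gap or N in any haplotype.
ng_prepare <- function(alignment) {
  m <- aln_matrix(alignment)
  L <- ncol(m)
  n_codons <- L %/% 3L
  if (n_codons < 3L) return(NULL)
  keep_codons <- 2L:(n_codons - 1L)
  # drop trailing partial columns beyond complete codons
  cols <- unlist(lapply(keep_codons, function(ci) (3L * ci - 2L):(3L * ci)))
  m <- m[, cols, drop = FALSE]
  ncod <- length(keep_codons)
  bad <- vapply(seq_len(ncod), function(ci) {
    block <- m[, (3L * ci - 2L):(3L * ci), drop = FALSE]
    any(block == "-" | block == "N")
  }, logical(1))
  m <- m[, unlist(lapply(which(!bad), function(ci) (3L * ci - 2L):(3L * ci))),
         drop = FALSE]
  if (ncol(m) == 0L) return(NULL)
  m
}

#' Synonymous and nonsynonymous diversity of one population sample
#'
#' Pairwise Nei-Gojobori differences averaged over all unordered pairs of
#' haplotypes, divided by the mean synonymous (nonsynonymous) site count over
#' all haplotypes.  Start and stop codons and codons containing gaps or Ns
#' are removed first.  Uncorrected proportions.
#'
#' @param alignment A [gene_alignment()] restricted to one population.
#' @return list with `pi_s`, `pi_n`, `syn_sites`, `nonsyn_sites`,
#'   `mean_syn_diff`, `mean_nonsyn_diff`, `n`.
#' @export
syn_nonsyn_diversity <- function(alignment) {
  m <- ng_prepare(alignment)
  n <- length(alignment$sequences)
  empty <- list(pi_s = NA_real_, pi_n = NA_real_, syn_sites = NA_real_,
                nonsyn_sites = NA_real_, mean_syn_diff = NA_real_,
                mean_nonsyn_diff = NA_real_, n = n)
  if (is.null(m) || n < 2L) return(empty)
  seqs <- apply(m, 1L, paste, collapse = "")
  # collapse to unique haplotypes with multiplicities for speed
  uniq <- unique(unname(seqs))
  mult <- vapply(uniq, function(u) sum(seqs == u), numeric(1), USE.NAMES = FALSE)
  sites <- vapply(uniq, nei_gojobori_sites, numeric(2))
  syn_sites <- sum(sites["syn_sites", ] * mult) / n
  nonsyn_sites <- sum(sites["nonsyn_sites", ] * mult) / n
  sd_tot <- 0; nd_tot <- 0
  k <- length(uniq)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j < i) next
      npairs <- if (i == j) choose(mult[i], 2) else mult[i] * mult[j]
      if (npairs == 0 || i == j) next
      d <- nei_gojobori_differences(uniq[i], uniq[j])
      sd_tot <- sd_tot + npairs * d[["syn_diff"]]
      nd_tot <- nd_tot + npairs * d[["nonsyn_diff"]]
    }
  }
  npairs_tot <- choose(n, 2)
  mean_sd <- sd_tot / npairs_tot
  mean_nd <- nd_tot / npairs_tot
  list(pi_s = if (syn_sites > 0) mean_sd / syn_sites else NA_real_,
       pi_n = if (nonsyn_sites > 0) mean_nd / nonsyn_sites else NA_real_,
       syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
       mean_syn_diff = mean_sd, mean_nonsyn_diff = mean_nd, n = n)
}

#' Between-population nucleotide divergence (dXY)
#'
#' Mean per-site difference over all `nA * nB` between-population pairs,
#' after complete deletion of gap/N columns across the union of both
#' samples.
#'
#' @param alignment_a,alignment_b [gene_alignment()]s of the two populations
#'   (same columns).
#' @return list with `d_xy`, `L`, `n_a`, `n_b`.  `d_xy` is `NA` when a
#'   population is empty or no columns survive.
#' @export
dxy <- function(alignment_a, alignment_b) {
  ma <- aln_matrix(alignment_a)
  mb <- aln_matrix(alignment_b)
  stopifnot(ncol(ma) == ncol(mb))
  na <- nrow(ma); nb <- nrow(mb)
  keep <- intersect(clean_columns(rbind(ma, mb)), seq_len(ncol(ma)))
  L <- length(keep)
  if (na == 0L || nb == 0L || L == 0L) {
    return(list(d_xy = NA_real_, L = L, n_a = na, n_b = nb))
  }
  ma <- ma[, keep, drop = FALSE]
  mb <- mb[, keep, drop = FALSE]
  tot <- 0
  for (j in seq_len(L)) {
    ca <- state_counts(ma[, j])
    cb <- state_counts(mb[, j])
    tot <- tot + (na * nb - sum(ca * cb))
  }
  list(d_xy = tot / (na * nb) / L, L = L, n_a = na, n_b = nb)
}

#' Per-site FST between two populations from derived-allele counts
#'
#' Hudson-style estimator `1 - Hw/Hb` with unbiased within-population
#' heterozygosity `2k(n-k)/(n(n-1))`, `Hw` the sample-size-weighted mean of
#' the two within-population values, and
#' `Hb = (kA(nB-kB) + kB(nA-kA)) / (nA nB)`.
#'
#' @param k_a,n_a Derived count and sample size in population A.
#' @param k_b,n_b Derived count and sample size in population B.
#' @return FST (<= 1); `NA` when the between-population diversity is 0.
#' @export
site_fst <- function(k_a, n_a, k_b, n_b) {
  if (n_a < 2L || n_b < 2L) stop("site_fst: need >= 2 chromosomes per population")
  hw_a <- 2 * k_a * (n_a - k_a) / (n_a * (n_a - 1))
  hw_b <- 2 * k_b * (n_b - k_b) / (n_b * (n_b - 1))
  hw <- (n_a * hw_a + n_b * hw_b) / (n_a + n_b)
  hb <- (k_a * (n_b - k_b) + k_b * (n_a - k_a)) / (n_a * n_b)
  if (hb == 0) return(NA_real_)
  1 - hw / hb
}

#' Upper-tail empirical probability of a value against a reference set
#'
#' Fraction of reference values greater than or equal to `value` (ties count
#' in the tail).
#'
#' @param value Scalar.
#' @param reference Nonempty numeric vector.
#' @return Empirical upper-tail probability in \[0, 1\].
#' @export
empirical_percentile <- function(value, reference) {
  reference <- reference[!is.na(reference)]
  if (!length(reference)) stop("empirical_percentile: empty reference")
  mean(reference >= value)
}

#' Concatenate gene alignments into one class-level alignment
#'
#' Column-wise concatenation in the given order.  Chromosomes absent from
#' any member gene (e.g. flagged whole-gene deletions) are dropped from the
#' concatenation when `drop_missing` is TRUE; otherwise differing chromosome
#' sets raise an error.
#'
#' @param alignments List of [gene_alignment()]s.
#' @param gene_id Identifier for the result (default `"concatenated"`).
#' @param drop_missing Drop chromosomes not present in every gene?
#' @return A [gene_alignment()].
#' @export
concatenate_class <- function(alignments, gene_id = "concatenated",
                              drop_missing = TRUE) {
  stopifnot(length(alignments) >= 1L)
  idsets <- lapply(alignments, function(a) names(a$sequences))
  common <- Reduce(intersect, idsets)
  if (!drop_missing && !all(vapply(idsets, function(s)
    setequal(s, common), logical(1)))) {
    stop("concatenate_class: inconsistent chromosome sets")
  }
  if (!length(common)) stop("concatenate_class: no common chromosomes")
  seqs <- vapply(common, function(id) {
    paste(vapply(alignments, function(a) a$sequences[[id]], character(1)),
          collapse = "")
  }, character(1))
  gene_alignment(seqs, gene_id, alignments[[1L]]$class_label)
}

#' Per-gene, per-population diversity summary table
#'
#' Convenience wrapper producing one report row per gene x population
#' plus the between-population dXY for a focal pair.
#'
#' @param alignments Named list of [gene_alignment()]s.
#' @param manifest A [population_manifest()].
#' @param focal_pair Character vector of two population labels for dXY.
#' @param scale Multiplier applied to pi/piS/piN/dXY for display (the
#'   conventional printed scale is percent, `scale = 100`); statistics are
#'   computed as raw proportions.
#' @return data.frame with one row per gene x population.
#' @export
diversity_summary <- function(alignments, manifest,
                              focal_pair = manifest_populations(manifest)[1:2],
                              scale = 100) {
  rows <- list()
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    sub <- list()
    for (p in focal_pair) {
      ids <- intersect(population_chromosomes(manifest, p, aln$gene_id),
                       names(aln$sequences))
      sub[[p]] <- if (length(ids)) aln_subset(aln, ids) else NULL
    }
    dx <- if (!is.null(sub[[1]]) && !is.null(sub[[2]])) {
      dxy(sub[[1]], sub[[2]])$d_xy
    } else NA_real_
    for (p in focal_pair) {
      if (is.null(sub[[p]])) next
      nd <- nucleotide_diversity(sub[[p]])
      sn <- syn_nonsyn_diversity(sub[[p]])
      td <- tajimas_d(sub[[p]])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, class_label = aln$class_label, population = p,
        n = nd$n, L = aln$length, L_clean = nd$L, S = nd$S,
        pi = nd$pi * scale,
        pi_s = sn$pi_s * scale, pi_n = sn$pi_n * scale,
        tajima_d = td$D,
        d_xy = dx * scale,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
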