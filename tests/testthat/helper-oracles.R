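# Independent brute-force oracles and small fixture builders.  Oracles are
# written against the definitions directly (explicit pair loops, explicit
# pathway enumeration) and share no code with the package internals.

GC_TABLE <- Biostrings::GENETIC_CODE

aa_of <- function(codon) {
  a <- GC_TABLE[codon]
  if (is.na(a)) "X" else unname(a)
}

# Build a gene_alignment from a character vector of sequences.
make_aln <- function(seqs, gene_id = "g1", ids = NULL, ...) {
  if (is.null(ids)) ids <- sprintf("chr%02d", seq_along(seqs))
  gene_alignment(setNames(seqs, ids), gene_id, ...)
}

# Manifest assigning the first n1 ids to pop1 and the rest to pop2.
make_manifest <- function(ids, n1, pops = c("western", "eastern"),
                          deletions = NULL) {
  entries <- data.frame(
    chromosome = ids,
    subject = paste0("s", seq_along(ids)),
    population = c(rep(pops[1], n1), rep(pops[2], length(ids) - n1)),
    stringsAsFactors = FALSE)
  if (is.null(deletions)) {
    population_manifest(entries)
  } else {
    population_manifest(entries, deletions)
  }
}

# Random gap-free alignment of n sequences x L columns.
random_seqs <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
}

# --- pi / dxy oracles: explicit double loops over pairs and sites ----------

oracle_pi <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m); L <- ncol(m)
  if (n < 2 || L == 0) return(NA_real_)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  tot / (n * (n - 1) / 2) / L
}

oracle_dxy <- function(seqs_a, seqs_b) {
  all <- c(seqs_a, seqs_b)
  m <- do.call(rbind, strsplit(all, ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  ma <- m[seq_along(seqs_a), keep, drop = FALSE]
  mb <- m[length(seqs_a) + seq_along(seqs_b), keep, drop = FALSE]
  L <- ncol(ma)
  if (L == 0) return(NA_real_)
  tot <- 0
  for (i in seq_len(nrow(ma))) for (j in seq_len(nrow(mb)))
    tot <- tot + sum(ma[i, ] != mb[j, ])
  tot / (nrow(ma) * nrow(mb)) / L
}

# --- Tajima oracle: formula re-coded from scratch --------------------------

oracle_tajima_d <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  if (S == 0) return(NA_real_)
  k <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) k <- k + sum(m[i, ] != m[j, ])
  k <- k / (n * (n - 1) / 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  denom <- e1 * S + e2 * S * (S - 1)
  if (denom <= 0) return(NA_real_)  # variance degenerates below n = 4
  (k - S / a1) / sqrt(denom)
}

# --- Nei-Gojobori oracles: independent enumeration -------------------------

oracle_ng_sites_codon <- function(codon) {
  a0 <- aa_of(codon)
  syn <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      m <- codon; substr(m, p, p) <- b
      if (aa_of(m) == a0) syn <- syn + 1
    }
  }
  c(syn / 3, 3 - syn / 3)
}

# all orderings of positions via recursive enumeration
all_orders <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (r in all_orders(v[-i])) out <- c(out, list(c(v[i], r)))
  }
  out
}

oracle_ng_pair <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- all_orders(pos)
  res <- NULL; stops <- NULL
  for (ord in paths) {
    cur <- c1; s <- 0; ns <- 0; hit_stop <- FALSE
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
      if (aa_of(cur) == "*" || aa_of(nxt) == "*") hit_stop <- TRUE
      if (aa_of(cur) == aa_of(nxt)) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    res <- rbind(res, c(s, ns)); stops <- c(stops, hit_stop)
  }
  use <- if (all(stops)) res else res[!stops, , drop = FALSE]
  colMeans(use)
}

# piS/piN oracle over a gap-free in-frame alignment (start/stop codons and
# gap codons must already be absent); explicit pairs x codons enumeration.
oracle_syn_nonsyn <- function(seqs) {
  n <- length(seqs)
  ncod <- nchar(seqs[1]) / 3
  codons <- lapply(seqs, function(s)
    substring(s, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod)))
  sites <- sapply(codons, function(cs)
    rowSums(vapply(cs, oracle_ng_sites_codon, numeric(2))))
  syn_sites <- mean(sites[1, ]); nonsyn_sites <- mean(sites[2, ])
  sd_tot <- 0; nd_tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    for (c in seq_len(ncod)) {
      d <- oracle_ng_pair(codons[[i]][c], codons[[j]][c])
      sd_tot <- sd_tot + d[1]; nd_tot <- nd_tot + d[2]
    }
  }
  npairs <- n * (n - 1) / 2
  list(pi_s = (sd_tot / npairs) / syn_sites,
       pi_n = (nd_tot / npairs) / nonsyn_sites,
       syn_sites = syn_sites, nonsyn_sites = nonsyn_sites)
}

# Random in-frame alignment of sense codons sharing most positions (so NG
# pathway code is exercised on 1-3 base codon differences).
random_codon_alignment <- function(n, ncod, mut = 0.15) {
  sense <- setdiff(names(GC_TABLE), c("TAA", "TAG", "TGA"))
  base <- sample(sense, ncod, replace = TRUE)
  vapply(seq_len(n), function(i) {
    cs <- base
    flip <- runif(ncod) < mut
    cs[flip] <- sample(sense, sum(flip), replace = TRUE)
    paste(cs, collapse = "")
  }, character(1))
}
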