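# Codon-level utilities shared by the variant classifier and the
# Nei-Gojobori synonymous/nonsynonymous machinery.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Standard genetic code, indexed by codon string ("TAA" -> "*").
genetic_code <- local({
  gc <- Biostrings::GENETIC_CODE
  # Biostrings marks stops as "*" already; keep as a plain named vector.
  gc
})

# Translate an ungapped DNA string; trailing partial codon dropped.
# Codons containing N or '-' translate to "X".
translate_cds <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return("")
  starts <- seq.int(1L, n - (n %% 3L), by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- genetic_code[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

codon_aa <- function(codon) {
  aa <- genetic_code[codon]
  if (is.na(aa)) "X" else unname(aa)
}

# --- Nei-Gojobori site counting -------------------------------------------

# Per codon: expected number of synonymous sites = sum over the 3 positions
# of (# of the 3 possible single-base changes preserving the amino acid)/3.
# Changes to (or from) stop codons count as nonsynonymous.
ng_syn_sites_codon <- function(codon) {
  aa0 <- codon_aa(codon)
  if (aa0 %in% c("*", "X")) return(NA_real_)
  s <- 0
  for (pos in 1:3) {
    b0 <- substr(codon, pos, pos)
    for (b in setdiff(BASES, b0)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (identical(codon_aa(mut), aa0)) s <- s + 1 / 3
    }
  }
  s
}

# Cached 64-entry table of synonymous site counts.
ng_site_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      codons <- names(genetic_code)
      tab <<- vapply(codons, ng_syn_sites_codon, numeric(1))
    }
    tab
  }
})

# Pathway-averaged (syn, nonsyn) differences between two codons.
# All mutational pathways (orderings of the differing positions) are
# enumerated; pathways passing through a stop codon are excluded when at
# least one stop-free pathway exists.  Steps to a stop count as nonsynonymous
# if no stop-free pathway exists (degenerate input; diversity pipelines strip
# stop codons first).
ng_pair_diff_codon <- function(c1, c2) {
  if (identical(c1, c2)) return(c(syn = 0, nonsyn = 0))
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- permutations_of(diffpos)
  res <- matrix(NA_real_, nrow = length(perms), ncol = 2L)
  through_stop <- logical(length(perms))
  for (i in seq_along(perms)) {
    cur <- c1
    sd <- 0; nd <- 0; stopped <- FALSE
    for (pos in perms[[i]]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      a1 <- codon_aa(cur); a2 <- codon_aa(nxt)
      if (a2 == "*" || a1 == "*") stopped <- TRUE
      if (identical(a1, a2)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[i, ] <- c(sd, nd)
    through_stop[i] <- stopped
  }
  keep <- if (all(through_stop)) seq_along(perms) else which(!through_stop)
  c(syn = mean(res[keep, 1L]), nonsyn = mean(res[keep, 2L]))
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# Cached lookup of pairwise codon differences, built lazily per pair.
ng_pair_cache <- new.env(parent = emptyenv())
ng_pair_diff <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- ng_pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- ng_pair_diff_codon(c1, c2)
  ng_pair_cache[[key]] <- val
  ng_pair_cache[[paste0(c2, c1)]] <- val
  val
}
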