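# Detection of ectopic gene-conversion tracts between paralogous genes from
# aligned haplotype sets: informative sites where a candidate haplotype
# carries the donor-locus consensus at positions where donor and recipient
# consensus differ, and tracts as maximal runs of such sites uninterrupted
# by recipient-diagnostic sites.

# Shared setup: consensus vectors and candidate row checks.  Paralogs are
# assumed aligned to a common coordinate frame of equal length (the TAS2R
# cluster genes are equal-length CDSs); unequal lengths require a supplied
# pairwise alignment upstream.
conversion_frame <- function(recipient, donor, candidate) {
  if (donor$length != recipient$length) {
    stop("informative_sites: donor and recipient must share a coordinate frame")
  }
  if (!candidate %in% names(recipient$sequences)) {
    stop("informative_sites: candidate '", candidate, "' not in recipient")
  }
  m <- aln_matrix(recipient)
  cand <- m[candidate, ]
  others <- m[setdiff(rownames(m), candidate), , drop = FALSE]
  dcons <- donor_consensus(donor)
  rcons <- vapply(seq_len(ncol(others)), function(j) {
    tab <- table(others[, j])
    names(tab)[which.max(tab)]
  }, character(1))
  list(cand = cand, others = others, dcons = dcons, rcons = rcons)
}

#' Conversion-informative positions for one candidate haplotype
#'
#' Positions where the donor consensus differs from the recipient consensus,
#' the candidate carries the donor state, and the donor state is rare
#' (minority, < 50%) among the other recipient chromosomes.
#'
#' @param recipient Recipient [gene_alignment()].
#' @param donor Donor [gene_alignment()] on the same coordinate frame.
#' @param candidate Chromosome id of the candidate recipient haplotype.
#' @return Integer vector of 1-based CDS positions (possibly empty).
#' @export
informative_sites <- function(recipient, donor, candidate) {
  fr <- conversion_frame(recipient, donor, candidate)
  divergent <- fr$dcons != fr$rcons & fr$dcons != "-" & fr$rcons != "-"
  donor_rare <- vapply(seq_along(fr$dcons), function(j) {
    mean(fr$others[, j] == fr$dcons[j]) < 0.5
  }, logical(1))
  which(divergent & fr$cand == fr$dcons & donor_rare)
}

#' Detect gene-conversion tracts carried by recipient haplotypes
#'
#' For each distinct recipient haplotype, informative sites are computed and
#' tracts reported as maximal runs of consecutive informative sites with no
#' intervening discordant site (a donor/recipient-divergent position where
#' the candidate carries the recipient consensus).  The reported interval
#' spans the outermost informative sites (true endpoints between diagnostic
#' sites are unidentifiable).  Tracts supported by fewer than `min_support`
#' informative sites are discarded.
#'
#' @param recipient Recipient [gene_alignment()].
#' @param donor Donor [gene_alignment()] on the same coordinate frame.
#' @param min_support Minimum informative sites per tract (default 2,
#'   suppressing single-site homoplasy).
#' @return data.frame with columns `recipient_gene`, `donor_gene`,
#'   `haplotypes` (comma-joined carrier ids), `start`, `end`, `length`,
#'   `support`, `informative_positions`.
#' @export
detect_tracts <- function(recipient, donor, min_support = 2L) {
  ids <- setdiff(names(recipient$sequences), recipient$reference_id)
  seqs <- recipient$sequences[ids]
  empty <- data.frame(recipient_gene = character(), donor_gene = character(),
                      haplotypes = character(), start = integer(),
                      end = integer(), length = integer(),
                      support = integer(),
                      informative_positions = character(),
                      stringsAsFactors = FALSE)
  if (!length(ids)) return(empty)
  reps <- ids[!duplicated(seqs)]   # one candidate per distinct haplotype
  rows <- list()
  for (cand in reps) {
    carriers <- ids[seqs == seqs[[cand]]]
    inf <- informative_sites(recipient, donor, cand)
    if (length(inf) < min_support) next
    fr <- conversion_frame(recipient, donor, cand)
    divergent <- which(fr$dcons != fr$rcons & fr$dcons != "-" & fr$rcons != "-")
    discordant <- divergent[fr$cand[divergent] == fr$rcons[divergent]]
    # split informative sites into runs broken by discordant sites
    brk <- c(0L, sort(discordant), recipient$length + 1L)
    grp <- findInterval(inf, brk)
    for (g in unique(grp)) {
      run <- inf[grp == g]
      if (length(run) < min_support) next
      rows[[length(rows) + 1L]] <- data.frame(
        recipient_gene = recipient$gene_id, donor_gene = donor$gene_id,
        haplotypes = paste(carriers, collapse = ","),
        start = min(run), end = max(run),
        length = max(run) - min(run) + 1L,
        support = length(run),
        informative_positions = paste(run, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
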