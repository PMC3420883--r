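# Coalescent-based generator of multi-gene, two-population phased haplotype
# datasets emulating the cTAS2R study design: 28 coding loci of ~876-1002 bp,
# 92 + 20 sampled chromosomes, subspecies-skewed haplotype frequencies,
# segregating pseudogenes, whole-gene deletions, and paralog conversion
# tracts.  Truth records make every injected variant recoverable.

#' Configuration for the synthetic dataset generator
#'
#' Defaults reproduce the study design: 28 genes of 876-1002 bp (codon
#' multiples), western (92) and eastern (20) chromosomes, a per-site scaled
#' mutation rate matching the observed diversity magnitude (~0.1% per site),
#' and a 19:9 split between "old" and "human cluster" genes.
#'
#' @param n_genes Number of coding loci.
#' @param cds_length_range (min, max) CDS length in bp; sampled lengths are
#'   multiples of 3.
#' @param populations Named integer vector of chromosomes per population.
#' @param theta_per_site Scaled mutation rate per site for the shared
#'   (metapopulation) haplotype pool.
#' @param divergence_scale Between-population drift parameter in \[0, 1\];
#'   0 is panmixia, larger values add population-private fixed and
#'   polymorphic mutations in proportion to `theta`.
#' @param lesion_specs List of lesion specifications; each a list with
#'   `gene` (gene id or index), `type` (one of `loss_of_start`,
#'   `gain_of_stop`, `frameshift_indel`, `whole_gene_deletion`,
#'   `conversion_tract`), `population`, `frequency`, and for tracts `donor`
#'   (gene id/index) and `interval` (c(start, end), 1-based inclusive CDS).
#' @param n_human_cluster Number of genes labelled `human_cluster` (rest are
#'   `old`); default scales the study's 9 of 28.
#' @param seed Integer master seed; each gene uses a named substream so
#'   adding genes does not perturb earlier ones.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 28L,
                             cds_length_range = c(876L, 1002L),
                             populations = c(western = 92L, eastern = 20L),
                             theta_per_site = 0.001,
                             divergence_scale = 0,
                             lesion_specs = list(),
                             n_human_cluster = round(n_genes * 9 / 28),
                             seed = 1L) {
  stopifnot(n_genes >= 1L, length(cds_length_range) == 2L,
            cds_length_range[1] <= cds_length_range[2],
            cds_length_range[1] >= 9L,
            !is.null(names(populations)), all(populations >= 0L),
            theta_per_site >= 0, divergence_scale >= 0, divergence_scale <= 1)
  for (ls in lesion_specs) {
    stopifnot(!is.null(ls$gene), !is.null(ls$type), !is.null(ls$frequency))
    if (ls$frequency < 0 || ls$frequency > 1) {
      stop("synthetic_config: lesion frequency outside [0, 1]")
    }
    if (!ls$type %in% c("loss_of_start", "gain_of_stop", "frameshift_indel",
                        "whole_gene_deletion", "conversion_tract")) {
      stop("synthetic_config: unknown lesion type ", ls$type)
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 cds_length_range = as.integer(cds_length_range),
                 populations = populations,
                 theta_per_site = theta_per_site,
                 divergence_scale = divergence_scale,
                 lesion_specs = lesion_specs,
                 n_human_cluster = as.integer(n_human_cluster),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Deterministic per-name substream seed derived from the master seed.
substream_seed <- function(seed, name) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Random open reading frame: ATG, internal non-stop codons, terminal stop.
random_orf <- function(length_bp) {
  stopifnot(length_bp %% 3L == 0L, length_bp >= 9L)
  n_codons <- length_bp %/% 3L
  sense <- setdiff(names(genetic_code), STOP_CODONS)
  internal <- sample(sense, n_codons - 2L, replace = TRUE)
  paste(c("ATG", internal, sample(STOP_CODONS, 1L)), collapse = "")
}

# Neutral coalescent sample of n haplotypes from an ancestral sequence under
# the infinite-sites approximation (mutation positions drawn without
# replacement).  Returns the haplotype character matrix and the mutation
# truth table (position, ancestral, derived, carrier indices).
coalescent_pool <- function(n, ancestral, theta_locus) {
  L <- nchar(ancestral)
  anc <- strsplit(ancestral, "")[[1]]
  m <- matrix(rep(anc, each = n), nrow = n)
  muts <- list()
  if (n >= 2L && theta_locus > 0) {
    active <- lapply(seq_len(n), identity)  # tip sets
    len <- numeric(n)
    seg_len <- numeric(0)
    seg_tips <- list()
    k <- n
    total <- 0
    while (k > 1L) {
      t <- stats::rexp(1L, rate = k * (k - 1) / 2)
      len <- len + t
      total <- total + k * t
      pair <- sample.int(k, 2L)
      i <- min(pair); j <- max(pair)
      seg_len <- c(seg_len, len[i], len[j])
      seg_tips <- c(seg_tips, list(active[[i]], active[[j]]))
      active[[i]] <- c(active[[i]], active[[j]])
      len[i] <- 0
      active[[j]] <- NULL
      len <- len[-j]
      k <- k - 1L
    }
    # mutable positions exclude the start and terminal codon so injected
    # start/stop lesions stay unambiguous in the truth record
    mutable <- 4L:(L - 3L)
    S <- stats::rpois(1L, theta_locus / 2 * total)
    S <- min(S, length(mutable))  # infinite-sites on finite sequence
    if (S > 0L) {
      segs <- sample.int(length(seg_len), S, replace = TRUE, prob = seg_len)
      positions <- sample(mutable, S)
      for (s in seq_len(S)) {
        pos <- positions[s]
        carriers <- seg_tips[[segs[s]]]
        derived <- sample(setdiff(BASES, anc[pos]), 1L)
        m[carriers, pos] <- derived
        muts[[length(muts) + 1L]] <- list(position = pos,
                                          ancestral = anc[pos],
                                          derived = derived,
                                          carriers = carriers)
      }
    }
  }
  list(matrix = m, mutations = muts)
}

# Classify a single-base change within the ancestral reading frame (used to
# label generator truth records).
classify_truth_snv <- function(ancestral, pos, derived) {
  ci <- (pos - 1L) %/% 3L + 1L
  n_codons <- nchar(ancestral) %/% 3L
  rc <- substr(ancestral, 3L * ci - 2L, 3L * ci)
  mut <- rc
  substr(mut, (pos - 1L) %% 3L + 1L, (pos - 1L) %% 3L + 1L) <- derived
  if (ci == 1L && rc == "ATG" && mut != "ATG") return("loss_of_start")
  if (ci == n_codons) {
    return(if (mut %in% STOP_CODONS) "synonymous" else "loss_of_stop")
  }
  if (mut %in% STOP_CODONS) return("gain_of_stop")
  if (identical(codon_aa(mut), codon_aa(rc))) "synonymous" else "nonsynonymous"
}

#' Copy a donor-gene consensus tract into selected recipient chromosomes
#'
#' Emulates ectopic gene conversion: the listed chromosomes receive the
#' donor consensus (majority state, ties towards the donor reference) over
#' the 1-based inclusive interval; all other positions are untouched.
#'
#' @param alignment Recipient [gene_alignment()].
#' @param donor Donor [gene_alignment()] aligned to the same coordinates.
#' @param interval c(start, end), 1-based inclusive CDS positions.
#' @param chromosomes Character vector of recipient chromosome ids (may be
#'   empty, in which case the alignment is returned unchanged).
#' @return The modified [gene_alignment()].
#' @export
inject_conversion_tract <- function(alignment, donor, interval, chromosomes) {
  start <- interval[1]; end <- interval[2]
  if (start < 1L || end > alignment$length || start > end) {
    stop("inject_conversion_tract: interval outside CDS")
  }
  if (end > donor$length) {
    stop("inject_conversion_tract: interval outside donor CDS")
  }
  if (!length(chromosomes)) return(alignment)
  missing <- setdiff(chromosomes, names(alignment$sequences))
  if (length(missing)) {
    stop("inject_conversion_tract: unknown chromosomes: ",
         paste(missing, collapse = ", "))
  }
  cons <- donor_consensus(donor)[start:end]
  m <- aln_matrix(alignment)
  m[chromosomes, start:end] <- matrix(rep(cons, each = length(chromosomes)),
                                      nrow = length(chromosomes))
  aln_from_matrix(m, alignment)
}

# Majority-state consensus of an alignment; ties break toward the reference.
donor_consensus <- function(aln) {
  m <- aln_matrix(aln)
  ref <- m[aln$reference_id, ]
  vapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j])
    top <- names(tab)[tab == max(tab)]
    if (ref[j] %in% top) ref[j] else top[1L]
  }, character(1))
}

#' Generate a synthetic multi-gene two-population haplotype dataset
#'
#' Per gene: an ancestral random ORF is sampled, a shared haplotype pool is
#' drawn from the neutral coalescent at the configured theta, population-
#' private mutations are added in proportion to `divergence_scale`, and the
#' configured lesions are injected at exact chromosome counts
#' (`round(frequency * n)`).  Each gene alignment carries the ancestral
#' sequence as record `"ancestral"` (the reference haplotype, excluded from
#' population statistics via the manifest).
#'
#' @param config A [synthetic_config()].
#' @return list with `alignments` (named list of [gene_alignment()]),
#'   `manifest` ([population_manifest()]), and `truth` (data.frame of every
#'   injected variant: gene, type, effect, position/interval, population
#'   counts, carrier ids).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  pops <- config$populations
  gene_ids <- sprintf("gene%02d", seq_len(config$n_genes))
  class_labels <- rep("old", config$n_genes)
  if (config$n_human_cluster > 0L) {
    class_labels[seq_len(config$n_human_cluster) +
                   config$n_genes - config$n_human_cluster] <- "human_cluster"
  }

  chrom_ids <- unlist(lapply(names(pops), function(p)
    sprintf("%s_%03d", p, seq_len(pops[[p]]))), use.names = FALSE)
  pop_labels <- rep(names(pops), pops)
  subjects <- sprintf("%s_s%02d", pop_labels,
                      (unlist(lapply(pops, seq_len)) + 1L) %/% 2L)
  entries <- data.frame(chromosome = chrom_ids, subject = subjects,
                        population = pop_labels, stringsAsFactors = FALSE)

  # resolve lesion gene/donor references to gene ids
  resolve_gene <- function(g) {
    if (is.numeric(g)) gene_ids[g] else match.arg(g, gene_ids)
  }
  lesions <- lapply(config$lesion_specs, function(ls) {
    ls$gene <- resolve_gene(ls$gene)
    if (!is.null(ls$donor)) ls$donor <- resolve_gene(ls$donor)
    ls
  })

  # lengths: sampled per gene from its substream; genes receiving a
  # conversion tract share their donor's length so coordinates transfer
  lens <- integer(config$n_genes)
  names(lens) <- gene_ids
  lo <- ceiling(config$cds_length_range[1] / 3)
  hi <- floor(config$cds_length_range[2] / 3)
  for (i in seq_len(config$n_genes)) {
    set.seed(substream_seed(config$seed, paste0("len:", gene_ids[i])))
    lens[i] <- 3L * (lo + sample.int(hi - lo + 1L, 1L) - 1L)
  }
  for (ls in lesions) {
    if (ls$type == "conversion_tract") lens[ls$gene] <- lens[ls$donor]
  }

  alignments <- list()
  truth <- list()
  deletions <- data.frame(chromosome = character(), gene = character(),
                          stringsAsFactors = FALSE)
  pop_chroms <- split(chrom_ids, pop_labels)[names(pops)]

  add_truth <- function(gene, type, effect, position, end, carriers) {
    counts <- vapply(names(pops), function(p)
      length(intersect(carriers, pop_chroms[[p]])), numeric(1))
    rec <- data.frame(gene_id = gene, type = type, effect = effect,
                      position = position, end = end,
                      carriers = paste(carriers, collapse = ","),
                      stringsAsFactors = FALSE)
    for (p in names(pops)) {
      rec[[paste0("count_", p)]] <- counts[[p]]
      rec[[paste0("n_", p)]] <- pops[[p]]
    }
    truth[[length(truth) + 1L]] <<- rec
  }

  lesion_count <- function(f, n, gene, type) {
    k <- round(f * n)
    if (f > 0 && (k < 1L || k > n)) {
      stop("generate_dataset: infeasible lesion frequency ", f,
           " for n=", n, " (", gene, ", ", type, ")")
    }
    k
  }

  for (i in seq_len(config$n_genes)) {
    g <- gene_ids[i]
    set.seed(substream_seed(config$seed, g))
    L <- lens[i]
    ancestral <- random_orf(L)
    pool <- coalescent_pool(length(chrom_ids), ancestral,
                            config$theta_per_site * L)
    m <- pool$matrix
    rownames(m) <- chrom_ids
    used_pos <- vapply(pool$mutations, function(x) x$position, numeric(1))
    for (mu in pool$mutations) {
      add_truth(g, "snv", classify_truth_snv(ancestral, mu$position,
                                             mu$derived),
                mu$position, NA_integer_, chrom_ids[mu$carriers])
    }

    # population-private divergence mutations
    if (config$divergence_scale > 0) {
      theta_locus <- config$theta_per_site * L
      for (p in names(pops)) {
        ids <- pop_chroms[[p]]
        if (!length(ids)) next
        n_fix <- stats::rpois(1L, config$divergence_scale * theta_locus)
        n_poly <- stats::rpois(1L, config$divergence_scale * theta_locus)
        avail <- setdiff(4L:(L - 3L), used_pos)
        take <- sample(avail, min(n_fix + n_poly, length(avail)))
        used_pos <- c(used_pos, take)
        anc <- strsplit(ancestral, "")[[1]]
        for (s in seq_along(take)) {
          pos <- take[s]
          derived <- sample(setdiff(BASES, anc[pos]), 1L)
          carriers <- if (s <= n_fix) ids else
            sample(ids, sample.int(length(ids), 1L))
          m[carriers, pos] <- derived
          add_truth(g, "snv", classify_truth_snv(ancestral, pos, derived),
                    pos, NA_integer_, carriers)
        }
      }
    }

    # sequence lesions (loss of start, gain of stop, frameshift indels)
    for (ls in lesions) {
      if (ls$gene != g ||
          ls$type %in% c("conversion_tract", "whole_gene_deletion")) next
      targets <- unlist(pop_chroms[ls$population], use.names = FALSE)
      k <- lesion_count(ls$frequency, length(targets), g, ls$type)
      if (k == 0L) next
      carriers <- sample(targets, k)
      if (ls$type == "loss_of_start") {
        m[carriers, 1L] <- "G"   # ATG -> GTG
        add_truth(g, ls$type, "loss_of_start", 1L, NA_integer_, carriers)
      } else if (ls$type == "gain_of_stop") {
        hit <- find_stoppable_codon(ancestral, avoid = used_pos)
        used_pos <- c(used_pos, hit$position)
        m[carriers, hit$position] <- hit$derived
        add_truth(g, ls$type, "gain_of_stop", hit$position, NA_integer_,
                  carriers)
      } else { # frameshift_indel
        len <- sample(c(1L, 2L, 4L, 5L), 1L)
        start <- sample(seq(4L, L - 3L - len), 1L)
        m[carriers, start:(start + len - 1L)] <- "-"
        add_truth(g, ls$type, "indel", start, start + len - 1L, carriers)
      }
    }

    seqs <- setNames(apply(m, 1L, paste, collapse = ""), chrom_ids)
    alignments[[g]] <- gene_alignment(
      c(ancestral = ancestral, seqs), g, class_labels[i],
      reference_id = "ancestral")
  }

  # conversion tracts (donor alignments now exist)
  for (ls in lesions) {
    if (ls$type != "conversion_tract") next
    set.seed(substream_seed(config$seed, paste0("tract:", ls$gene)))
    targets <- unlist(pop_chroms[ls$population], use.names = FALSE)
    k <- lesion_count(ls$frequency, length(targets), ls$gene, ls$type)
    if (k == 0L) next
    carriers <- sample(targets, k)
    alignments[[ls$gene]] <- inject_conversion_tract(
      alignments[[ls$gene]], alignments[[ls$donor]], ls$interval, carriers)
    add_truth(ls$gene, "conversion_tract", "conversion",
              ls$interval[1], ls$interval[2], carriers)
  }

  # whole-gene deletions: flagged chromosomes leave the gene's alignment
  for (ls in lesions) {
    if (ls$type != "whole_gene_deletion") next
    set.seed(substream_seed(config$seed, paste0("wgd:", ls$gene)))
    targets <- unlist(pop_chroms[ls$population], use.names = FALSE)
    k <- lesion_count(ls$frequency, length(targets), ls$gene, ls$type)
    if (k == 0L) next
    carriers <- sample(targets, k)
    aln <- alignments[[ls$gene]]
    keep <- setdiff(names(aln$sequences), carriers)
    alignments[[ls$gene]] <- gene_alignment(aln$sequences[keep], ls$gene,
                                            aln$class_label, "ancestral")
    deletions <- rbind(deletions,
                       data.frame(chromosome = carriers, gene = ls$gene,
                                  stringsAsFactors = FALSE))
    add_truth(ls$gene, "whole_gene_deletion", "whole_gene_deletion",
              NA_integer_, NA_integer_, carriers)
  }

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), type = character(),
               effect = character(), position = integer(), end = integer(),
               carriers = character(), stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL

  list(alignments = alignments,
       manifest = population_manifest(entries, deletions),
       truth = truth_df,
       gene_config = data.frame(gene_id = gene_ids,
                                class_label = class_labels,
                                cds_length = unname(lens),
                                stringsAsFactors = FALSE))
}

#' Apply a described mutation class to a reference haplotype
#'
#' Builds the haplotype a catalogued variant describes, for classification
#' with [functional_status()]: loss of the start codon, gain of a premature
#' stop, an insertion or deletion of a given length, a whole-gene deletion,
#' or a gene-conversion tract copied from a paralog donor.
#'
#' @param reference Ungapped reference CDS (starts with ATG).
#' @param type One of `"loss_of_start"`, `"gain_of_stop"`, `"deletion"`,
#'   `"insertion"`, `"whole_gene_deletion"`, `"conversion"`.
#' @param indel_length Length in bp for deletion/insertion types.
#' @param donor Donor CDS string for `"conversion"` (same coordinates).
#' @param interval c(start, end) 1-based inclusive positions for
#'   `"conversion"`.
#' @return The mutated haplotype string (or [deletion_marker()]).
#' @export
apply_lesion <- function(reference, type, indel_length = NULL, donor = NULL,
                         interval = NULL) {
  switch(type,
    loss_of_start = {
      out <- reference
      substr(out, 1L, 1L) <- "G"   # ATG -> GTG
      out
    },
    gain_of_stop = {
      hit <- find_stoppable_codon(reference)
      out <- reference
      substr(out, hit$position, hit$position) <- hit$derived
      out
    },
    deletion = {
      stopifnot(!is.null(indel_length))
      at <- 10L  # internal, clear of the start codon
      paste0(substr(reference, 1L, at - 1L),
             substr(reference, at + indel_length, nchar(reference)))
    },
    insertion = {
      stopifnot(!is.null(indel_length))
      at <- 10L
      paste0(substr(reference, 1L, at - 1L), strrep("A", indel_length),
             substr(reference, at, nchar(reference)))
    },
    whole_gene_deletion = deletion_marker(),
    conversion = {
      stopifnot(!is.null(donor), !is.null(interval))
      out <- reference
      substr(out, interval[1], interval[2]) <-
        substr(donor, interval[1], interval[2])
      out
    },
    stop("apply_lesion: unknown type ", type))
}

# Internal codon one substitution away from a stop codon; returns the CDS
# position to change and the derived base, skipping positions in `avoid`
# (already-mutated sites).  Errors if none exists (random ORFs of realistic
# length essentially always contain one).
find_stoppable_codon <- function(ancestral, avoid = integer(0)) {
  n_codons <- nchar(ancestral) %/% 3L
  order_ci <- sample(2L:(n_codons - 1L))
  for (ci in order_ci) {
    rc <- substr(ancestral, 3L * ci - 2L, 3L * ci)
    for (stp in sample(STOP_CODONS)) {
      d <- which(strsplit(rc, "")[[1]] != strsplit(stp, "")[[1]])
      if (length(d) == 1L && !((3L * (ci - 1L) + d) %in% avoid)) {
        return(list(position = 3L * (ci - 1L) + d,
                    derived = substr(stp, d, d)))
      }
    }
  }
  stop("find_stoppable_codon: no codon one step from a stop")
}
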