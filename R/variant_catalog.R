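# Variant calling against a reference haplotype, coding-effect and
# functional-status classification, haplotype collapsing, and sharing
# summaries.

#' Marker used for whole-gene-deletion "haplotypes"
#' @export
deletion_marker <- function() "<WGD>"

#' Call variants in a gene alignment against a reference haplotype
#'
#' One record per variable site (substitutions, keyed by position and
#' alternative base) and per distinct contiguous indel.  Effects follow the
#' six coding classes: synonymous, nonsynonymous, loss_of_start,
#' gain_of_stop, loss_of_stop, indel.  `loss_of_start` takes precedence over
#' (non)synonymous for codon-1 changes destroying an ATG; internal
#' stop-creating substitutions are `gain_of_stop`; changes destroying the
#' terminal stop are `loss_of_stop`.  Positions are 1-based CDS coordinates
#' on the reference (A of ATG = 1); indels report the first affected
#' position and are left-aligned as given in the input alignment.
#'
#' @param alignment A [gene_alignment()] containing the reference record.
#' @param manifest A [population_manifest()]; population denominators exclude
#'   chromosomes flagged as whole-gene deletions for this gene.
#' @param reference_id Reference record id; defaults to the alignment's.
#' @return data.frame with columns `gene_id`, `position`, `ref_state`,
#'   `alt_state`, `effect`, `frameshift`, and per population `count_<pop>`,
#'   `n_<pop>`.
#' @export
call_variants <- function(alignment, manifest,
                          reference_id = alignment$reference_id) {
  if (!reference_id %in% names(alignment$sequences)) {
    stop("call_variants: reference '", reference_id, "' not in alignment")
  }
  m <- aln_matrix(alignment)
  ref <- m[reference_id, ]
  cdsmap <- cumsum(ref != "-")
  if (any(ref == "-" & cdsmap < 3L)) {
    stop("call_variants: reference has gaps within the start codon")
  }
  refseq <- paste(ref[ref != "-"], collapse = "")
  n_codons <- nchar(refseq) %/% 3L
  ref_codons <- substring(refseq, 3L * seq_len(n_codons) - 2L,
                          3L * seq_len(n_codons))
  terminal_is_stop <- n_codons >= 1L && ref_codons[n_codons] %in% STOP_CODONS

  pops <- manifest_populations(manifest)
  pop_ids <- lapply(pops, function(p)
    intersect(population_chromosomes(manifest, p, alignment$gene_id),
              rownames(m)))
  names(pop_ids) <- pops
  samples <- setdiff(rownames(m), reference_id)

  classify_sub <- function(pos, alt) {
    ci <- (pos - 1L) %/% 3L + 1L
    within <- (pos - 1L) %% 3L + 1L
    if (ci > n_codons) return("nonsynonymous")
    rc <- ref_codons[ci]
    if (grepl("[^ACGT]", rc)) return(NA_character_)
    mut <- rc
    substr(mut, within, within) <- alt
    if (ci == 1L && rc == "ATG" && mut != "ATG") return("loss_of_start")
    if (ci == n_codons && terminal_is_stop) {
      return(if (mut %in% STOP_CODONS) "synonymous" else "loss_of_stop")
    }
    if (mut %in% STOP_CODONS) return("gain_of_stop")
    if (identical(codon_aa(mut), codon_aa(rc))) "synonymous" else "nonsynonymous"
  }

  count_carriers <- function(ids) {
    vapply(pops, function(p) {
      c(count = length(intersect(ids, pop_ids[[p]])),
        n = length(pop_ids[[p]]))
    }, numeric(2))
  }

  rows <- list()
  add_row <- function(position, ref_state, alt_state, effect, frameshift, ids) {
    cc <- count_carriers(ids)
    rec <- data.frame(gene_id = alignment$gene_id, position = position,
                      ref_state = ref_state, alt_state = alt_state,
                      effect = effect, frameshift = frameshift,
                      stringsAsFactors = FALSE)
    for (p in pops) {
      rec[[paste0("count_", p)]] <- cc["count", p]
      rec[[paste0("n_", p)]] <- cc["n", p]
    }
    rows[[length(rows) + 1L]] <<- rec
  }

  # Substitutions: columns where the reference has a base.
  sub_cols <- which(ref != "-")
  for (col in sub_cols) {
    states <- m[samples, col]
    alts <- setdiff(unique(states), c(ref[col], "-", "N"))
    for (alt in alts) {
      ids <- samples[states == alt]
      add_row(cdsmap[col], ref[col], alt,
              classify_sub(cdsmap[col], alt), FALSE, ids)
    }
  }

  # Indels: per sample, contiguous runs of gap mismatch against the reference.
  indel_keys <- new.env(parent = emptyenv())
  for (s in samples) {
    row <- m[s, ]
    isdel <- row == "-" & ref != "-"
    isins <- row != "-" & ref == "-"
    for (kind in c("del", "ins")) {
      mask <- if (kind == "del") isdel else isins
      r <- rle(mask)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (i in which(r$values)) {
        cols <- starts[i]:ends[i]
        if (kind == "del") {
          len <- sum(ref[cols] != "-")
          pos <- cdsmap[starts[i]]
          key <- paste("del", starts[i], ends[i], sep = ":")
          refst <- paste(ref[cols][ref[cols] != "-"], collapse = "")
          altst <- "-"
        } else {
          len <- length(cols)
          pos <- cdsmap[starts[i]] + 1L
          inserted <- paste(row[cols], collapse = "")
          key <- paste("ins", starts[i], ends[i], inserted, sep = ":")
          refst <- "-"
          altst <- inserted
        }
        entry <- indel_keys[[key]]
        if (is.null(entry)) {
          indel_keys[[key]] <- list(pos = pos, ref = refst, alt = altst,
                                    len = len, ids = s)
        } else {
          entry$ids <- c(entry$ids, s)
          indel_keys[[key]] <- entry
        }
      }
    }
  }
  for (key in ls(indel_keys)) {
    e <- indel_keys[[key]]
    add_row(e$pos, e$ref, e$alt, "indel", e$len %% 3L != 0L, e$ids)
  }

  if (!length(rows)) {
    out <- data.frame(gene_id = character(), position = integer(),
                      ref_state = character(), alt_state = character(),
                      effect = character(), frameshift = logical(),
                      stringsAsFactors = FALSE)
    for (p in pops) {
      out[[paste0("count_", p)]] <- numeric(0)
      out[[paste0("n_", p)]] <- numeric(0)
    }
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$alt_state), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Functional status of a single haplotype
#'
#' A haplotype is non-functional (a segregating pseudogene) if it has no ATG
#' at positions 1-3 *and* no rescuing alternative ATG at positions 4-6, or if
#' it contains a premature stop codon before the terminal codon, or if its
#' length is not a multiple of 3 (frameshift).  The whole-gene-deletion
#' marker is non-functional with mechanism `whole_gene_deletion`.
#'
#' @param haplotype Ungapped CDS string (gaps, if present, are stripped), or
#'   [deletion_marker()].
#' @return list with `status` (`"functional"`/`"nonfunctional"`),
#'   `mechanism` (`"none"`/`"pseudogene"`/`"whole_gene_deletion"`) and
#'   `detail` (lesion signature string, `""` if functional).
#' @export
functional_status <- function(haplotype) {
  if (identical(haplotype, deletion_marker())) {
    return(list(status = "nonfunctional", mechanism = "whole_gene_deletion",
                detail = "WGD"))
  }
  seq <- gsub("-", "", toupper(haplotype), fixed = TRUE)
  if (!nzchar(seq)) {
    stop("functional_status: empty haplotype that is not a deletion marker")
  }
  lesions <- character(0)
  if (nchar(seq) %% 3L != 0L) {
    lesions <- c(lesions, sprintf("frameshift(len%%3=%d)", nchar(seq) %% 3L))
  }
  if (substr(seq, 1L, 3L) != "ATG" && substr(seq, 4L, 6L) != "ATG") {
    lesions <- c(lesions, "loss_of_start")
  }
  aa <- translate_cds(seq)
  ncod <- nchar(aa)
  if (ncod > 1L) {
    internal <- substr(aa, 1L, ncod - 1L)
    stop_at <- regexpr("*", internal, fixed = TRUE)
    if (stop_at > 0L) lesions <- c(lesions, sprintf("stop@codon%d", stop_at))
  }
  if (length(lesions)) {
    list(status = "nonfunctional", mechanism = "pseudogene",
         detail = paste(lesions, collapse = ";"))
  } else {
    list(status = "functional", mechanism = "none", detail = "")
  }
}

#' Collapse an alignment into nucleotide- or protein-level haplotype classes
#'
#' Nucleotide classes key on the full aligned sequence.  Protein classes key
#' on the predicted translation for functional haplotypes and on the lesion
#' signature plus the (frameshift-aware) translation for pseudogenes, so
#' distinct inactivating alleles form distinct classes.  Chromosomes flagged
#' as whole-gene deletions for the gene form one class with an empty key.
#'
#' @param alignment A [gene_alignment()].
#' @param manifest A [population_manifest()].
#' @param level `"nucleotide"` or `"protein"`.
#' @return data.frame with columns `gene_id`, `level`, `key`, `status`,
#'   `mechanism` and one `count_<pop>` column per manifest population.
#' @export
collapse_haplotypes <- function(alignment, manifest,
                                level = c("nucleotide", "protein")) {
  level <- match.arg(level)
  pops <- manifest_populations(manifest)
  ids <- names(alignment$sequences)
  pop_of <- setNames(manifest$entries$population, manifest$entries$chromosome)
  # an external reference haplotype (e.g. "ancestral") is not a sampled
  # chromosome and is excluded from the classes
  ids <- setdiff(ids, setdiff(alignment$reference_id, names(pop_of)))
  if (any(!ids %in% names(pop_of))) {
    stop("collapse_haplotypes: alignment contains chromosomes missing from manifest")
  }
  key_src <- alignment$sequences[ids]

  key_of <- if (level == "nucleotide") {
    key_src
  } else {
    vapply(key_src, function(s) {
      fs <- functional_status(s)
      prot <- translate_cds(gsub("-", "", s, fixed = TRUE))
      if (fs$status == "functional") prot else paste0("P[", fs$detail, "]:", prot)
    }, character(1))
  }

  recs <- list()
  for (k in unique(key_of)) {
    members <- ids[key_of == k]
    fs <- functional_status(alignment$sequences[[members[1L]]])
    rec <- data.frame(gene_id = alignment$gene_id, level = level, key = k,
                      status = fs$status, mechanism = fs$mechanism,
                      stringsAsFactors = FALSE)
    for (p in pops) {
      rec[[paste0("count_", p)]] <- sum(pop_of[members] == p)
    }
    recs[[length(recs) + 1L]] <- rec
  }

  del <- deleted_chromosomes(manifest, alignment$gene_id)
  if (length(del)) {
    rec <- data.frame(gene_id = alignment$gene_id, level = level, key = "",
                      status = "nonfunctional",
                      mechanism = "whole_gene_deletion",
                      stringsAsFactors = FALSE)
    for (p in pops) {
      rec[[paste0("count_", p)]] <- sum(pop_of[del] == p)
    }
    recs[[length(recs) + 1L]] <- rec
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Summarise haplotype sharing between populations
#'
#' A class is "unique" iff it has a nonzero count in exactly one of the
#' requested populations; classes absent from all requested populations are
#' dropped.  With `high_frequency_only`, classes observed on at most one
#' chromosome (total over the requested populations) are removed first.
#'
#' @param classes data.frame of haplotype classes, typically `rbind` of
#'   [collapse_haplotypes()] output across genes.
#' @param populations Character vector (length >= 2) of population labels.
#' @param high_frequency_only Drop singleton classes first?
#' @return list with `level`, `total_classes`, `unique_to_one_population`,
#'   `shared`, `per_population` (data.frame of unique/shared counts) and
#'   `high_frequency_only`.
#' @export
sharing_summary <- function(classes, populations,
                            high_frequency_only = FALSE) {
  if (length(populations) < 2L) {
    stop("sharing_summary: need at least two populations")
  }
  cols <- paste0("count_", populations)
  missing <- setdiff(cols, names(classes))
  if (length(missing)) {
    stop("sharing_summary: unknown population label(s): ",
         paste(sub("^count_", "", missing), collapse = ", "))
  }
  cm <- as.matrix(classes[, cols, drop = FALSE])
  tot <- rowSums(cm)
  keep <- tot > 0
  if (high_frequency_only) keep <- keep & tot > 1
  cm <- cm[keep, , drop = FALSE]
  npops <- rowSums(cm > 0)
  per_pop <- data.frame(
    population = populations,
    unique = vapply(seq_along(populations), function(j)
      sum(npops == 1L & cm[, j] > 0), numeric(1)),
    present = colSums(cm > 0)
  )
  list(level = unique(classes$level[keep]),
       total_classes = nrow(cm),
       unique_to_one_population = sum(npops == 1L),
       shared = sum(npops > 1L),
       per_population = per_pop,
       high_frequency_only = high_frequency_only)
}

#' Build a report catalog of inactivating and structural variants
#'
#' One row per (gene, mutation class) covering loss of start, gain of stop,
#' loss of stop, indels and whole-gene deletions, with a function verdict and
#' per-population allele frequencies rendered as `"k/n (percent)"`.  A
#' loss-of-start allele is functional when its carriers have a rescuing ATG
#' at positions 4-6.
#'
#' @param variants Output of [call_variants()].
#' @param alignment The [gene_alignment()] the variants came from.
#' @param manifest A [population_manifest()].
#' @return data.frame with columns `gene_id`, `mutation`, `functional`,
#'   and one frequency column per population.
#' @export
catalog_table <- function(variants, alignment, manifest) {
  pops <- manifest_populations(manifest)
  fmt <- function(k, n) {
    if (n == 0 || k == 0) "0" else sprintf("%d/%d (%.0f%%)", k, n, 100 * k / n)
  }
  rows <- list()
  add <- function(mutation, verdict, counts, ns) {
    rec <- data.frame(gene_id = alignment$gene_id, mutation = mutation,
                      functional = verdict, stringsAsFactors = FALSE)
    for (j in seq_along(pops)) {
      rec[[pops[j]]] <- fmt(counts[j], ns[j])
    }
    rows[[length(rows) + 1L]] <<- rec
  }
  special <- variants[variants$effect %in%
                        c("loss_of_start", "gain_of_stop", "loss_of_stop",
                          "indel"), , drop = FALSE]
  for (i in seq_len(nrow(special))) {
    v <- special[i, ]
    counts <- as.numeric(v[paste0("count_", pops)])
    ns <- as.numeric(v[paste0("n_", pops)])
    if (v$effect == "loss_of_start") {
      # rescue check on an actual carrier haplotype
      m <- aln_matrix(alignment)
      carriers <- rownames(m)[apply(m, 1L, function(r) {
        s <- gsub("-", "", paste(r, collapse = ""), fixed = TRUE)
        substr(s, 1, 3) != "ATG"
      })]
      verdict <- if (length(carriers) &&
                     all(vapply(carriers, function(id) {
                       s <- gsub("-", "", alignment$sequences[[id]], fixed = TRUE)
                       substr(s, 4, 6) == "ATG"
                     }, logical(1)))) "Functional" else "Non-functional"
      add("LIC", verdict, counts, ns)
    } else if (v$effect == "gain_of_stop") {
      add("GTC", "Non-functional", counts, ns)
    } else if (v$effect == "loss_of_stop") {
      add("LTC", "Non-functional", counts, ns)
    } else {
      len <- if (v$alt_state == "-") nchar(v$ref_state) else nchar(v$alt_state)
      kind <- if (v$alt_state == "-") "del." else "ins."
      add(sprintf("%d bp %s", len, kind),
          if (v$frameshift) "Non-functional" else "Functional", counts, ns)
    }
  }
  del <- deleted_chromosomes(manifest, alignment$gene_id)
  if (length(del)) {
    pop_of <- setNames(manifest$entries$population, manifest$entries$chromosome)
    counts <- vapply(pops, function(p) sum(pop_of[del] == p), numeric(1))
    ns <- vapply(pops, function(p)
      sum(manifest$entries$population == p), numeric(1))
    add("WGD", "Non-functional", counts, ns)
  }
  if (!length(rows)) {
    out <- data.frame(gene_id = character(), mutation = character(),
                      functional = character(), stringsAsFactors = FALSE)
    for (p in pops) out[[p]] <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a table of described variant classes by functional status
#'
#' Takes a curated catalog of inactivating/structural variant descriptions
#' (one row per gene x mutation class, as reported for the cTAS2R family:
#' `LIC` loss of start codon, `GTC` gain of stop codon, `del`/`ins` indels
#' with `indel_length`, `WGD` whole-gene deletion, `GC` gene conversion with
#' `interval_start`/`interval_end`; `alt_start = 1` marks alleles carrying a
#' rescuing alternative ATG at positions 4-6), materialises each described
#' haplotype on a reference ORF with [apply_lesion()], and classifies it
#' with [functional_status()].
#'
#' @param rows data.frame with columns `gene`, `mutation`, `indel_length`,
#'   `alt_start`, `interval_start`, `interval_end` (see
#'   `system.file("extdata", "tas2r_variant_classes.tsv", package = "tas2rdiv")`).
#' @return `rows` with added `status` and `mechanism` columns.
#' @export
classify_variant_rows <- function(rows) {
  # deterministic reference ORF: Leu/Gln internal codons (CAA is one
  # substitution from a stop, so gain-of-stop rows are constructible)
  make_ref <- function(alt_start) {
    codon2 <- if (alt_start) "ATG" else "CTG"
    paste(c("ATG", codon2, rep(c("CTG", "CAA"), 148), "TAA"), collapse = "")
  }
  donor_of <- function(ref) {
    # synonymous third-position differences throughout (Leu CTG->CTT,
    # Gln CAA->CAG): a conversion tract keeps the frame intact
    chartr_ref <- gsub("CTG", "CTT", ref, fixed = TRUE)
    gsub("CAA", "CAG", chartr_ref, fixed = TRUE)
  }
  status <- character(nrow(rows))
  mechanism <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    ref <- make_ref(isTRUE(r$alt_start == 1))
    hap <- switch(as.character(r$mutation),
      LIC = apply_lesion(ref, "loss_of_start"),
      GTC = apply_lesion(ref, "gain_of_stop"),
      del = apply_lesion(ref, "deletion", indel_length = r$indel_length),
      ins = apply_lesion(ref, "insertion", indel_length = r$indel_length),
      WGD = apply_lesion(ref, "whole_gene_deletion"),
      GC = apply_lesion(ref, "conversion", donor = donor_of(ref),
                        interval = c(r$interval_start, r$interval_end)),
      stop("classify_variant_rows: unknown mutation class ", r$mutation))
    fs <- functional_status(hap)
    status[i] <- fs$status
    mechanism[i] <- fs$mechanism
  }
  rows$status <- status
  rows$mechanism <- mechanism
  rows
}

#' Genomic span of a deletion or alignment hit
#'
#' @param start,end 1-based inclusive genomic coordinates, `start <= end`.
#' @return `end - start + 1` (bp).
#' @export
deletion_span <- function(start, end) {
  if (any(start > end)) stop("deletion_span: start > end")
  end - start + 1
}
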