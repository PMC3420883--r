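#' @useDynLib tas2rdiv, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fisher.test median pnorm rmultinom rpois runif sd setNames wilcox.test
#' @importFrom utils read.delim write.table
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct an aligned set of phased coding haplotypes for one gene
#'
#' The central container of the package: an alignment of phased
#' coding-sequence haplotypes (one record per sampled chromosome) for a single
#' bitter-taste-receptor gene.  Coding-sequence positions are 1-based with the
#' A of the annotated ATG start codon as position 1.
#'
#' @param sequences Named character vector of aligned sequences (alphabet
#'   `A/C/G/T/N/-`), names are chromosome identifiers.
#' @param gene_id Gene identifier, e.g. `"cTAS2R46"`.
#' @param class_label Either `"old"` or `"human_cluster"`.
#' @param reference_id Identifier of the reference haplotype; defaults to the
#'   first record.
#' @return An object of class `gene_alignment`: a list with elements
#'   `gene_id`, `class_label`, `sequences`, `reference_id` and `length`.
#' @export
gene_alignment <- function(sequences, gene_id, class_label = "old",
                           reference_id = NULL) {
  if (length(sequences) == 0L) {
    stop("gene_alignment: no sequences supplied for gene ", gene_id)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("gene_alignment: sequences must carry unique chromosome ids")
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("gene_alignment: unequal aligned lengths for gene ", gene_id,
         " (", paste(unique(lens), collapse = ", "), ")")
  }
  bad <- grepl(sprintf("[^%s]", paste(ALN_ALPHABET, collapse = "")), sequences)
  if (any(bad)) {
    stop("gene_alignment: illegal characters in sequences of gene ", gene_id,
         " (records: ", paste(names(sequences)[bad], collapse = ", "), ")")
  }
  class_label <- match.arg(class_label, c("old", "human_cluster"))
  if (is.null(reference_id)) reference_id <- names(sequences)[1L]
  structure(
    list(gene_id = gene_id, class_label = class_label,
         sequences = sequences, reference_id = reference_id,
         length = unname(lens[1L])),
    class = "gene_alignment"
  )
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s [%s]: %d chromosomes x %d columns (ref %s)\n",
              x$gene_id, x$class_label, length(x$sequences), x$length,
              x$reference_id))
  invisible(x)
}

# Alignment as a character matrix, rows = chromosomes, columns = positions.
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  rownames(m) <- names(aln$sequences)
  m
}

# Rebuild a gene_alignment from a character matrix, keeping metadata.
aln_from_matrix <- function(m, template) {
  seqs <- apply(m, 1L, paste, collapse = "")
  gene_alignment(setNames(seqs, rownames(m)), template$gene_id,
                 template$class_label,
                 if (template$reference_id %in% rownames(m))
                   template$reference_id else rownames(m)[1L])
}

#' Subset an alignment to a chromosome id set (order preserved)
#'
#' @param aln A [gene_alignment()].
#' @param ids Chromosome ids to keep (e.g. one population's, from
#'   [population_chromosomes()]).
#' @return A [gene_alignment()] restricted to `ids`.
#' @export
aln_subset <- function(aln, ids) {
  keep <- names(aln$sequences) %in% ids
  if (!any(keep)) stop("aln_subset: no chromosomes left after subsetting")
  gene_alignment(aln$sequences[keep], aln$gene_id, aln$class_label,
                 if (aln$reference_id %in% names(aln$sequences)[keep])
                   aln$reference_id else names(aln$sequences)[keep][1L])
}

#' Construct a population manifest
#'
#' Maps each sampled chromosome to a subject and a population, and records
#' per-gene whole-gene-deletion flags (chromosomes that produced no amplicon
#' for a gene and therefore must be absent from that gene's alignment).
#'
#' @param entries data.frame with columns `chromosome`, `subject`,
#'   `population`.
#' @param deletions data.frame with columns `chromosome`, `gene` (may have
#'   zero rows).
#' @return An object of class `population_manifest`.
#' @export
population_manifest <- function(entries,
                                deletions = data.frame(chromosome = character(),
                                                       gene = character())) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("chromosome", "subject", "population") %in% names(entries)))
  if (anyDuplicated(entries$chromosome)) {
    stop("population_manifest: duplicate chromosome ids: ",
         paste(unique(entries$chromosome[duplicated(entries$chromosome)]),
               collapse = ", "))
  }
  deletions <- as.data.frame(deletions, stringsAsFactors = FALSE)
  stopifnot(all(c("chromosome", "gene") %in% names(deletions)))
  unknown <- setdiff(deletions$chromosome, entries$chromosome)
  if (length(unknown)) {
    stop("population_manifest: deletion rows refer to unknown chromosomes: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(entries = entries, deletions = deletions),
            class = "population_manifest")
}

#' @export
print.population_manifest <- function(x, ...) {
  tab <- table(x$entries$population)
  cat(sprintf("<population_manifest> %d chromosomes (%s); %d deletion flags\n",
              nrow(x$entries),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", "),
              nrow(x$deletions)))
  invisible(x)
}

#' Population labels of a manifest, in order of first appearance
#' @param manifest A [population_manifest()].
#' @return Character vector of population labels.
#' @export
manifest_populations <- function(manifest) {
  unique(manifest$entries$population)
}

#' Chromosome ids of one population
#'
#' @param manifest A [population_manifest()].
#' @param population Population label.
#' @param gene_id Optional gene id; chromosomes flagged as whole-gene
#'   deletions for that gene are excluded.
#' @return Character vector of chromosome ids.
#' @export
population_chromosomes <- function(manifest, population, gene_id = NULL) {
  ids <- manifest$entries$chromosome[manifest$entries$population == population]
  if (!is.null(gene_id)) {
    del <- manifest$deletions$chromosome[manifest$deletions$gene == gene_id]
    ids <- setdiff(ids, del)
  }
  ids
}

# Chromosomes flagged deleted for a gene.
deleted_chromosomes <- function(manifest, gene_id) {
  manifest$deletions$chromosome[manifest$deletions$gene == gene_id]
}

#' Read an aligned haplotype FASTA
#'
#' @param path Path to a FASTA file; record ids are chromosome ids.  Any line
#'   wrapping is accepted.
#' @param gene_id Gene identifier to attach.
#' @param class_label `"old"` or `"human_cluster"`.
#' @param reference_id Optional reference haplotype id (defaults to the first
#'   record).
#' @return A [gene_alignment()].
#' @export
read_alignment <- function(path, gene_id, class_label = "old",
                           reference_id = NULL) {
  if (!file.exists(path)) stop("read_alignment: no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("read_alignment: cannot parse FASTA ", path,
                             ": ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("read_alignment: empty FASTA: ", path)
  seqs <- setNames(as.character(set), sub("\\s.*$", "", names(set)))
  gene_alignment(seqs, gene_id, class_label, reference_id)
}

#' Write a gene alignment as FASTA (wrapped at 60 columns)
#'
#' @param aln A [gene_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a population manifest TSV
#'
#' The manifest is a tab-separated file with header columns `chromosome`,
#' `subject`, `population` and an optional `deleted_genes` column holding a
#' comma-separated list of genes for which that chromosome carries a
#' whole-gene deletion (empty for none).
#'
#' @param path Path to the TSV.
#' @param genes Optional character vector of known gene ids; deletion flags
#'   naming other genes raise an error.
#' @return A [population_manifest()].
#' @export
read_manifest <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("read_manifest: no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("chromosome", "subject", "population")
  if (!all(need %in% names(df))) {
    stop("read_manifest: header must contain ",
         paste(need, collapse = ", "))
  }
  dels <- data.frame(chromosome = character(), gene = character())
  if ("deleted_genes" %in% names(df)) {
    has <- which(!is.na(df$deleted_genes) & nzchar(df$deleted_genes))
    if (length(has)) {
      lst <- strsplit(df$deleted_genes[has], ",", fixed = TRUE)
      dels <- data.frame(
        chromosome = rep(df$chromosome[has], lengths(lst)),
        gene = trimws(unlist(lst)), stringsAsFactors = FALSE)
    }
  }
  if (!is.null(genes)) {
    unknown <- setdiff(dels$gene, genes)
    if (length(unknown)) {
      stop("read_manifest: deletion flags name unknown genes: ",
           paste(unique(unknown), collapse = ", "))
    }
  }
  population_manifest(df[, need], dels)
}

#' Write a population manifest TSV
#'
#' @param manifest A [population_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- manifest$entries
  dg <- vapply(df$chromosome, function(ch) {
    paste(manifest$deletions$gene[manifest$deletions$chromosome == ch],
          collapse = ",")
  }, character(1))
  df$deleted_genes <- dg
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene configuration TSV
#'
#' Columns: `gene_id`, `class_label` (`old` / `human_cluster`), `cds_length`,
#' and optional `paralog_group` (genes sharing a non-empty group label are
#' eligible as conversion donors for one another).
#'
#' @param path Path to the TSV.
#' @return A list with `genes` (data.frame) and `paralog_groups` (list of
#'   character vectors).
#' @export
read_gene_config <- function(path) {
  if (!file.exists(path)) stop("read_gene_config: no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "class_label", "cds_length") %in% names(df)))
  if (!all(df$class_label %in% c("old", "human_cluster"))) {
    stop("read_gene_config: class_label must be 'old' or 'human_cluster'")
  }
  groups <- list()
  if ("paralog_group" %in% names(df)) {
    g <- df$paralog_group
    g[is.na(g)] <- ""
    for (lab in unique(g[nzchar(g)])) {
      groups[[lab]] <- df$gene_id[g == lab]
    }
  }
  list(genes = df[, c("gene_id", "class_label", "cds_length")],
       paralog_groups = groups)
}

#' Read a reference SNV table (putatively neutral non-coding loci)
#'
#' Columns: `locus_id`, `position`, then paired per-population count columns
#' `<pop>_derived` and `<pop>_n`.
#'
#' @param path Path to the TSV.
#' @return data.frame of the parsed rows.
#' @export
read_reference_snvs <- function(path) {
  if (!file.exists(path)) stop("read_reference_snvs: no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locus_id", "position") %in% names(df)))
  ncols <- grep("_n$", names(df), value = TRUE)
  if (length(ncols) < 2L) {
    stop("read_reference_snvs: need at least two populations (columns *_derived, *_n)")
  }
  ok <- rowSums(df[, ncols, drop = FALSE] > 0) >= 2L
  if (!all(ok)) {
    stop("read_reference_snvs: every row needs >=2 populations with nonzero n")
  }
  df
}

#' Write a set of result tables as TSV reports
#'
#' Writes one `<name>.tsv` per table with deterministic column order and
#' fixed float rendering: diversity-style values with 3 decimals, simulation
#' means with 1 decimal (columns are formatted by name suffix conventions:
#' numeric columns are rendered with `digits` decimals unless named in
#' `coarse_cols`).
#'
#' @param tables Named list of data.frames.
#' @param path Output directory (created if needed).
#' @param digits Decimals for ordinary numeric columns.
#' @param coarse_cols Column names rendered with 1 decimal (simulation means).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(tables, path, digits = 3L,
                         coarse_cols = c("null_mean", "null_sd")) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  written <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]], stringsAsFactors = FALSE)
    for (cn in names(df)) {
      if (is.double(df[[cn]])) {
        d <- if (cn %in% coarse_cols) 1L else digits
        df[[cn]] <- ifelse(is.na(df[[cn]]), "NA",
                           formatC(df[[cn]], digits = d, format = "f"))
      }
    }
    fp <- file.path(path, paste0(nm, ".tsv"))
    write.table(df, fp, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, fp)
  }
  invisible(written)
}
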