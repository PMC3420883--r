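# End-to-end orchestration: catalog -> diversity -> selection tests ->
# sharing null -> conversion scan, from a single configuration, with
# deterministic per-stage seed substreams and TSV reports.

#' Build a run configuration
#'
#' Inputs may be given as paths (read with the data_model readers) or as
#' in-memory objects from [generate_dataset()].
#'
#' @param alignments Named list of [gene_alignment()]s, or a directory of
#'   `<gene_id>.fasta` files.
#' @param manifest A [population_manifest()] or a manifest TSV path.
#' @param gene_config data.frame (`gene_id`, `class_label`, `cds_length`,
#'   optional `paralog_group`) or a gene-config TSV path.
#' @param focal_pair Two population labels used for dXY, FST and the
#'   sharing null; defaults to the first two manifest populations.
#' @param reference_fst Optional numeric vector of reference-panel FST
#'   values (putatively neutral non-coding SNVs) for the outlier screen.
#' @param replicates Replicates for the sharing and coalescent nulls.
#' @param seed Master seed; stages draw named substreams.
#' @param out_dir Output directory for TSV reports (NULL = no files).
#' @param stages Character subset of
#'   `c("catalog", "diversity", "tests", "sharing", "conversion")`.
#' @param pooling Pooling mode for [pooled_frequencies()].
#' @param fst_quantile Empirical tail-probability threshold for flagging
#'   FST outliers (default 0.05).
#' @param paralog_pairs Optional data.frame (`recipient`, `donor`) of gene
#'   pairs to scan for conversion; defaults to all ordered pairs within
#'   each paralog group of the gene config.
#' @return list of class `run_config`.
#' @export
run_config <- function(alignments, manifest, gene_config = NULL,
                       focal_pair = NULL, reference_fst = NULL,
                       replicates = 10000L, seed = 1L, out_dir = NULL,
                       stages = c("catalog", "diversity", "tests",
                                  "sharing", "conversion"),
                       pooling = "mean_of_frequencies",
                       fst_quantile = 0.05, paralog_pairs = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("run_config: missing manifest: ", manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.character(gene_config)) gene_config <- read_gene_config(gene_config)
  if (is.character(alignments)) {
    dir <- alignments
    if (!dir.exists(dir)) stop("run_config: missing alignments dir: ", dir)
    files <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
    gids <- sub("\\.fasta$", "", basename(files))
    cls <- setNames(rep("old", length(gids)), gids)
    if (!is.null(gene_config)) {
      gc_df <- if (is.data.frame(gene_config)) gene_config else gene_config$genes
      cls[gc_df$gene_id] <- gc_df$class_label
    }
    alignments <- setNames(
      lapply(seq_along(files), function(i)
        read_alignment(files[i], gids[i], cls[[gids[i]]])), gids)
  }
  if (is.null(focal_pair)) focal_pair <- manifest_populations(manifest)[1:2]
  stopifnot(replicates >= 1L)
  structure(list(alignments = alignments, manifest = manifest,
                 gene_config = gene_config, focal_pair = focal_pair,
                 reference_fst = reference_fst,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 out_dir = out_dir, stages = stages, pooling = pooling,
                 fst_quantile = fst_quantile, paralog_pairs = paralog_pairs),
            class = "run_config")
}

#' Per-SNV FST table for a set of genes
#'
#' One row per substitution SNV (indels excluded) with the per-site FST
#' between the focal populations; chromosomes carrying whole-gene deletions
#' are already excluded from the per-population denominators by
#' [call_variants()].
#'
#' @param variants `rbind` of [call_variants()] outputs.
#' @param focal_pair Two population labels.
#' @return data.frame `gene_id`, `position`, `effect`, `fst`, `k1`, `n1`,
#'   `k2`, `n2`; `fst` is `NA` where between-population diversity is 0.
#' @export
fst_table <- function(variants, focal_pair) {
  v <- variants[variants$effect != "indel" & !is.na(variants$effect), ,
                drop = FALSE]
  k1 <- v[[paste0("count_", focal_pair[1])]]
  n1 <- v[[paste0("n_", focal_pair[1])]]
  k2 <- v[[paste0("count_", focal_pair[2])]]
  n2 <- v[[paste0("n_", focal_pair[2])]]
  fst <- vapply(seq_len(nrow(v)), function(i) {
    if (n1[i] < 2 || n2[i] < 2) return(NA_real_)
    site_fst(k1[i], n1[i], k2[i], n2[i])
  }, numeric(1))
  data.frame(gene_id = v$gene_id, position = v$position, effect = v$effect,
             fst = fst, k1 = k1, n1 = n1, k2 = k2, n2 = n2,
             stringsAsFactors = FALSE)
}

#' Screen coding SNVs against a reference FST distribution
#'
#' Attaches the empirical upper-tail probability of each SNV's FST in the
#' reference (putatively neutral non-coding) distribution and flags SNVs
#' below the configured quantile.
#'
#' @param fst_records data.frame from [fst_table()].
#' @param reference Numeric vector of reference FST values.
#' @param quantile Tail-probability threshold (default 0.05).
#' @return `fst_records` with `tail_p` and `outlier` columns.
#' @export
fst_outlier_screen <- function(fst_records, reference, quantile = 0.05) {
  reference <- reference[!is.na(reference)]
  if (!length(reference)) stop("fst_outlier_screen: empty reference")
  tail_p <- vapply(fst_records$fst, function(x) {
    if (is.na(x)) NA_real_ else empirical_percentile(x, reference)
  }, numeric(1))
  fst_records$tail_p <- tail_p
  fst_records$outlier <- !is.na(tail_p) & tail_p < quantile
  fst_records
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (catalog, diversity, tests,
#' sharing, conversion), writes TSV reports and a run manifest when
#' `out_dir` is set, and returns the result bundle.  Any stage error aborts
#' with a stage-tagged message; partial reports already written are retained
#' alongside an `INCOMPLETE` marker file.
#'
#' @param config A [run_config()].
#' @return list with elements per executed stage: `catalog` (variants,
#'   catalog_report, classes, sharing), `diversity` (summary table), `tests`
#'   (per-class selection tests), `sharing` (null + p per level),
#'   `conversion` (tract table), plus `run_manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- list()
  tables <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
        writeLines(paste0("INCOMPLETE at stage: ", name),
                   file.path(config$out_dir, "INCOMPLETE"))
        write_report(tables, config$out_dir)
      }
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  aln <- config$alignments
  man <- config$manifest
  pair <- config$focal_pair

  variants <- classes_nuc <- classes_prot <- NULL
  if (any(c("catalog", "diversity", "tests", "sharing") %in% config$stages)) {
    stage("catalog", {
      variants <- do.call(rbind, lapply(aln, call_variants, manifest = man))
      classes_nuc <- do.call(rbind, lapply(aln, collapse_haplotypes,
                                           manifest = man,
                                           level = "nucleotide"))
      classes_prot <- do.call(rbind, lapply(aln, collapse_haplotypes,
                                            manifest = man,
                                            level = "protein"))
      t1 <- do.call(rbind, lapply(aln, function(a)
        catalog_table(call_variants(a, man), a, man)))
      sh <- lapply(list(nucleotide = classes_nuc, protein = classes_prot),
                   sharing_summary, populations = pair)
      out$catalog <- list(variants = variants, catalog_report = t1,
                          classes_nucleotide = classes_nuc,
                          classes_protein = classes_prot, sharing = sh)
      tables$variant_catalog_report <- t1
      tables$variants <- variants
    })
  }

  class_of <- vapply(aln, function(a) a$class_label, character(1))
  concat <- NULL
  if (any(c("diversity", "tests") %in% config$stages)) {
    stage("diversity", {
      div <- diversity_summary(aln, man, pair)
      fst <- fst_table(variants, pair)
      if (!is.null(config$reference_fst)) {
        fst <- fst_outlier_screen(fst, config$reference_fst,
                                  config$fst_quantile)
      }
      concat <- lapply(unique(class_of), function(cl)
        concatenate_class(aln[class_of == cl], paste0("concatenated_", cl)))
      names(concat) <- unique(class_of)
      out$diversity <- list(summary = div, fst = fst, concatenated = concat)
      tables$diversity_summary <- div
      tables$site_fst_report <- fst
    })
  }

  if ("tests" %in% config$stages) {
    stage("tests", {
      rows <- list()
      for (cl in names(concat)) {
        members <- aln[class_of == cl]
        for (p in pair) {
          ids <- intersect(names(concat[[cl]]$sequences),
                           population_chromosomes(man, p))
          if (length(ids) < 2L) next
          ft <- pin_pis_test(aln_subset(concat[[cl]], ids))
          dvals <- vapply(members, function(a) {
            pids <- intersect(population_chromosomes(man, p, a$gene_id),
                              names(a$sequences))
            if (length(pids) < 2L) return(NA_real_)
            tajimas_d(aln_subset(a, pids))$D
          }, numeric(1))
          rows[[length(rows) + 1L]] <- data.frame(
            class_label = cl, population = p,
            pi_n_over_pi_s = ft$pi_n_over_pi_s, fisher_p = ft$p,
            median_d = stats::median(dvals, na.rm = TRUE),
            stringsAsFactors = FALSE)
        }
      }
      t3 <- do.call(rbind, rows)
      out$tests <- t3
      tables$selection_tests <- t3
    })
  }

  if ("sharing" %in% config$stages) {
    stage("sharing", {
      n1 <- length(population_chromosomes(man, pair[1]))
      n2 <- length(population_chromosomes(man, pair[2]))
      res <- list()
      for (lv in c("nucleotide", "protein")) {
        cls <- if (lv == "nucleotide") classes_nuc else classes_prot
        fq <- pooled_frequencies(cls, pair, config$pooling)
        nul <- simulate_shared(fq, n1, n2, config$replicates,
                               substream_seed(config$seed,
                                              paste0("sharing:", lv)),
                               level = lv)
        obs <- observed_shared(cls, pair)
        res[[lv]] <- list(null = nul, observed = obs,
                          p = gaussian_tail_p(nul, obs))
      }
      out$sharing <- res
      tables$sharing_null <- data.frame(
        level = names(res),
        observed = vapply(res, function(r) r$observed, numeric(1)),
        null_mean = vapply(res, function(r) r$null$mean, numeric(1)),
        null_sd = vapply(res, function(r) r$null$sd, numeric(1)),
        gaussian_p = vapply(res, function(r) r$p$p, numeric(1)),
        empirical_p = vapply(res, function(r) r$p$empirical_p, numeric(1)))
    })
  }

  if ("conversion" %in% config$stages) {
    stage("conversion", {
      pairs <- config$paralog_pairs
      if (is.null(pairs) && !is.null(config$gene_config) &&
          length(config$gene_config$paralog_groups)) {
        pairs <- do.call(rbind, lapply(config$gene_config$paralog_groups,
                                       function(g) {
          expand.grid(recipient = g, donor = g, stringsAsFactors = FALSE)
        }))
        pairs <- pairs[pairs$recipient != pairs$donor, , drop = FALSE]
      }
      if (!is.null(pairs) && nrow(pairs)) {
        # paralog scan assumes a shared coordinate frame: equal-length CDSs
        same_len <- vapply(seq_len(nrow(pairs)), function(i)
          aln[[pairs$recipient[i]]]$length == aln[[pairs$donor[i]]]$length,
          logical(1))
        pairs <- pairs[same_len, , drop = FALSE]
      }
      tracts <- if (is.null(pairs) || !nrow(pairs)) {
        detect_tracts(aln[[1]], aln[[1]])[0, ]
      } else {
        do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
          detect_tracts(aln[[pairs$recipient[i]]], aln[[pairs$donor[i]]])
        }))
      }
      out$conversion <- tracts
      tables$conversion_tracts <- tracts
    })
  }

  out$run_manifest <- data.frame(
    key = c("seed", "replicates", "focal_pair", "pooling", "fst_quantile",
            "stages", "genes", "chromosomes", "package_version"),
    value = c(config$seed, config$replicates, paste(pair, collapse = ","),
              config$pooling, config$fst_quantile,
              paste(config$stages, collapse = ","), length(aln),
              nrow(man$entries),
              as.character(utils::packageVersion("tas2rdiv"))),
    stringsAsFactors = FALSE)
  tables$run_manifest <- out$run_manifest

  if (!is.null(config$out_dir)) {
    write_report(tables, config$out_dir)
    inc <- file.path(config$out_dir, "INCOMPLETE")
    if (file.exists(inc)) file.remove(inc)
  }
  out
}
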