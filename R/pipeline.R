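#' Evaluate a set of calls against ground truth
#'
#' Set comparison of called versus true items: precision = TP / (TP + FP),
#' recall = TP / (TP + FN). When a denominator is zero the value is 1 if the
#' other error class is also empty (a vacuously perfect call set) and `NA`
#' otherwise.
#'
#' @param called character vector (or data.frame whose rows are pasted into
#'   keys) of called items.
#' @param truth character vector (or data.frame) of true items.
#' @param task label recorded on the result
#'   (`"decontamination"`, `"linking"`, `"sharing"`, ...).
#' @return list with `task`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate_calls <- function(called, truth, task = "generic") {
  to_keys <- function(x) {
    if (is.data.frame(x)) {
      do.call(paste, c(lapply(x, as.character), sep = "\r"))
    } else {
      as.character(x)
    }
  }
  called <- unique(to_keys(called))
  truth <- unique(to_keys(truth))
  tp <- length(intersect(called, truth))
  fp <- length(setdiff(called, truth))
  fn <- length(setdiff(truth, called))
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else
    NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else if (fp == 0) 1 else
    NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  list(task = task, tp = tp, fp = fp, fn = fn, precision = precision,
       recall = recall, f1 = f1)
}

#' Configuration for a full pipeline run
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort to
#'   simulate (real-data ingestion enters through the stage functions
#'   directly).
#' @param seed global seed; stage-level seeds are derived from it.
#' @param min_bin_length minimum genome-bin length; defaults to a quarter
#'   of the simulated genome length (the 100 kb real-data default does not
#'   fit small simulated genomes).
#' @param target_median popgen downsampling target.
#' @param estimator popgen estimator mode.
#' @param alpha FDR threshold for differential abundance and enrichment.
#' @param da_days neonatal days pooled in the differential KO test.
#' @param output_dir optional directory; when set, stage outputs are
#'   persisted as FASTA/TSV/JSON.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), seed = cohort$seed,
                            min_bin_length = cohort$genome_length / 4,
                            target_median = 20, estimator = "plugin",
                            alpha = 0.05, da_days = c(3, 5),
                            output_dir = NULL) {
  structure(list(cohort = cohort, seed = as.integer(seed),
                 min_bin_length = min_bin_length,
                 target_median = target_median, estimator = estimator,
                 alpha = alpha, da_days = da_days,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> decontaminate -> bin/link -> strain sharing ->
#' population genomics -> functional analysis -> evaluation, and returns a
#' structured report. Identical configurations (including seed) give
#' identical report bodies.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-generated `synthetic_cohort` matching
#'   `config$cohort` (skips the simulation stage).
#' @return object of class `pipeline_report`; see Details.
#'
#' @details The report carries per-stage outputs (`decontam`, `link`,
#' `sharing`, `popgen`, `functional`), evaluation metrics against the
#' generator's ground truth (`evaluation`), the parameters used, and the
#' package version.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$cohort)
  }
  samples <- cohort$samples

  ## decontamination ----------------------------------------------------
  dec <- decontaminate_cohort(cohort$contigs)

  ## binning and linking -------------------------------------------------
  link <- link_genomes(dec$curated, cohort$contig_markers,
                       n_families = config$cohort$n_marker_families,
                       min_bin_length = config$min_bin_length)
  clade_genome <- community_truth_genome(link, cohort$truth$contig_sources)

  ## strain sharing ------------------------------------------------------
  sharing <- strain_sharing_analysis(link, samples)
  sharing$genome_id <- clade_genome[sharing$clade]

  ## population genomics -------------------------------------------------
  completeness <- bin_completeness_table(link, clade_genome)
  # compare only samples of the same mother-neonate pair
  within_pair <- local({
    s <- samples[samples$role != "control", ]
    do.call(rbind, lapply(split(s$sample_id, s$pair_id), function(ids) {
      if (length(ids) < 2) return(NULL)
      t(utils::combn(sort(ids), 2))
    }))
  })
  popgen <- list()
  for (g in unique(vapply(cohort$pileups, `[[`, "", "genome_id"))) {
    pls <- cohort$pileups[vapply(cohort$pileups, `[[`, "", "genome_id") == g]
    cmp <- completeness[[g]] %||% numeric(0)
    popgen[[g]] <- popgen_analysis(
      unname(pls), completeness = as.list(cmp),
      target_median = config$target_median, mode = config$estimator,
      seed = derive_seed(config$seed, paste0("popgen.", g)),
      pairs = within_pair
    )
  }
  fst_summary <- summarize_fst(popgen, samples, cohort$truth$transmitted)

  ## functional analysis -------------------------------------------------
  gh <- cohort$gene_hits
  removed <- dec$report$contig_id
  gh <- gh[is.na(gh$contig_id) | !(gh$contig_id %in% removed), ,
           drop = FALSE]
  ko <- aggregate_ko_counts(gh, cohort$gene_ko_candidates)
  da <- differential_kos(ko$relative, samples, days = config$da_days,
                         alpha = config$alpha)
  da_set <- da$ko[da$da]
  # pathway enrichment is run per direction of change: pooling VD-enriched
  # and VD-depleted KOs into one draw set dilutes both signals
  da_dir <- ifelse(is.na(da$dir_csd), da$dir_sga, da$dir_csd)
  da_up <- da$ko[da$da & da_dir > 0]
  da_down <- da$ko[da$da & da_dir < 0]
  enrich <- pathway_enrichment(da_up, colnames(ko$relative),
                               cohort$pathway_map)
  enrich_down <- pathway_enrichment(da_down, colnames(ko$relative),
                                    cohort$pathway_map)
  gram <- t(vapply(rownames(cohort$taxon_profiles), function(s) {
    suppressMessages(
      gram_fraction(cohort$taxon_profiles[s, ], cohort$gram_table)$fractions
    )
  }, c(negative = 0, positive = 0, unknown = 0)))
  genome_or <- lapply(cohort$ko_sets, function(kos) {
    genome_function_enrichment(intersect(kos, colnames(ko$relative)),
                               da_set, colnames(ko$relative))
  })

  ## evaluation ----------------------------------------------------------
  evaluation <- list(
    decontamination = evaluate_calls(
      dec$report$contig_id, cohort$truth$contaminant_contigs,
      task = "decontamination"
    ),
    sharing = evaluate_sharing(sharing, cohort$truth$transmitted),
    linking = evaluate_linking(link, cohort$truth$contig_sources, samples)
  )

  report <- structure(list(
    parameters = list(seed = config$seed,
                      min_bin_length = config$min_bin_length,
                      target_median = config$target_median,
                      estimator = config$estimator, alpha = config$alpha,
                      da_days = config$da_days,
                      cohort = unclass(config$cohort)),
    decontam = dec, link = link, sharing = sharing, popgen = popgen,
    fst_summary = fst_summary,
    functional = list(ko = ko, da = da, enrichment = enrich,
                      enrichment_down = enrich_down,
                      gram_fractions = gram, genome_or = genome_or),
    evaluation = evaluation,
    version = as.character(packageVersion("strainrelay"))
  ), class = "pipeline_report")
  if (!is.null(config$output_dir)) {
    persist_report(report, cohort, config$output_dir)
  }
  report
}

# completeness per genome: named list genome -> (sample -> completeness),
# taking the best bin of each sample among communities mapped to the genome
bin_completeness_table <- function(link, clade_genome) {
  out <- list()
  memb <- link$communities$membership
  for (b in names(link$bins)) {
    g <- clade_genome[memb[[b]]]
    if (is.na(g)) next
    sid <- link$bins[[b]]$sample_id
    cur <- out[[g]][[sid]] %||% 0
    if (is.null(out[[g]])) out[[g]] <- list()
    out[[g]][[sid]] <- max(cur, link$bins[[b]]$completeness)
  }
  lapply(out, function(x) unlist(x))
}

# Median mother:day3 and day3:day5 fixation indices of transmitted strains
summarize_fst <- function(popgen, samples, transmitted) {
  day_of <- setNames(samples$day, samples$sample_id)
  role_of <- setNames(samples$role, samples$sample_id)
  pair_of <- setNames(samples$pair_id, samples$sample_id)
  md3 <- c()
  d35 <- c()
  strain_rows <- list()
  for (g in names(popgen)) {
    fst <- popgen[[g]]$fst
    if (is.null(fst)) next
    for (p in unique(transmitted$pair_id[transmitted$genome_id == g])) {
      pick <- function(r1, d1, r2, d2) {
        sel <- (role_of[fst$sample_1] == r1 & role_of[fst$sample_2] == r2 &
                pair_of[fst$sample_1] == p & pair_of[fst$sample_2] == p &
                (is.na(d1) | day_of[fst$sample_1] %in% d1) &
                (is.na(d2) | day_of[fst$sample_2] %in% d2)) |
               (role_of[fst$sample_2] == r1 & role_of[fst$sample_1] == r2 &
                pair_of[fst$sample_1] == p & pair_of[fst$sample_2] == p &
                (is.na(d2) | day_of[fst$sample_1] %in% d2) &
                (is.na(d1) | day_of[fst$sample_2] %in% d1))
        fst$fst[sel]
      }
      a <- pick("mother", NA, "neonate", 3)
      b <- pick("neonate", 3, "neonate", 5)
      if (length(a) && length(b) && !is.na(a[1]) && !is.na(b[1])) {
        md3 <- c(md3, a[1])
        d35 <- c(d35, b[1])
        strain_rows[[length(strain_rows) + 1]] <- data.frame(
          genome_id = g, pair_id = p, fst_mother_day3 = a[1],
          fst_day3_day5 = b[1], stringsAsFactors = FALSE
        )
      }
    }
  }
  list(per_strain = do.call(rbind, strain_rows),
       median_mother_day3 = if (length(md3)) median(md3) else NA_real_,
       median_day3_day5 = if (length(d35)) median(d35) else NA_real_,
       ordering_fraction = if (length(md3)) mean(md3 > d35) else NA_real_)
}

# sharing calls vs planted transmissions on (pair, genome) keys
evaluate_sharing <- function(sharing, transmitted) {
  called <- sharing[sharing$shared & !is.na(sharing$genome_id),
                    c("pair_id", "genome_id")]
  evaluate_calls(called, transmitted, task = "sharing")
}

# linking evaluated on co-community bin pairs within each mother-neonate
# pair: truth pairs are bins of the same source genome
evaluate_linking <- function(link, contig_sources, samples) {
  bins <- link$bins
  if (length(bins) < 2) {
    return(evaluate_calls(character(0), character(0), task = "linking"))
  }
  src <- setNames(contig_sources$genome_id, contig_sources$contig_id)
  pair_of <- setNames(samples$pair_id, samples$sample_id)
  bin_pair <- vapply(bins, function(b) unname(pair_of[b$sample_id]), "")
  bin_genome <- vapply(bins, function(b) {
    g <- src[b$members]
    names(sort(table(g), decreasing = TRUE))[1]
  }, "")
  memb <- link$communities$membership
  ids <- names(bins)
  called <- character(0)
  truth <- character(0)
  for (i in seq_len(length(ids) - 1)) {
    for (j in seq(i + 1, length(ids))) {
      if (is.na(bin_pair[i]) || bin_pair[i] != bin_pair[j]) next
      key <- paste(ids[i], ids[j], sep = "\r")
      if (memb[[ids[i]]] == memb[[ids[j]]]) called <- c(called, key)
      if (bin_genome[i] == bin_genome[j]) truth <- c(truth, key)
    }
  }
  evaluate_calls(called, truth, task = "linking")
}

persist_report <- function(report, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contig_fasta(report$decontam$curated, file.path(dir, "curated"))
  write.table(report$decontam$report,
              file.path(dir, "removal_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$sharing, file.path(dir, "sharing_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$functional$da, file.path(dir, "differential_kos.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$functional$enrichment,
              file.path(dir, "pathway_enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pi_all <- do.call(rbind, lapply(names(report$popgen), function(g) {
    x <- report$popgen[[g]]$pi
    if (is.null(x)) return(NULL)
    cbind(genome_id = g, x)
  }))
  if (!is.null(pi_all)) {
    write.table(pi_all, file.path(dir, "pi.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  fst_all <- do.call(rbind, lapply(names(report$popgen), function(g) {
    x <- report$popgen[[g]]$fst
    if (is.null(x)) return(NULL)
    cbind(genome_id = g, x)
  }))
  if (!is.null(fst_all)) {
    write.table(fst_all, file.path(dir, "fst.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    evaluation = report$evaluation, fst_summary = report$fst_summary[
      c("median_mother_day3", "median_day3_day5", "ordering_fraction")],
    parameters = report$parameters, version = report$version
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("strainrelay pipeline report\n")
  ev <- x$evaluation
  cat(sprintf("  decontamination: precision %.3f recall %.3f\n",
              ev$decontamination$precision, ev$decontamination$recall))
  cat(sprintf("  strain sharing:  precision %.3f recall %.3f (%d calls)\n",
              ev$sharing$precision, ev$sharing$recall, nrow(x$sharing)))
  cat(sprintf("  linking:         precision %.3f recall %.3f\n",
              ev$linking$precision, ev$linking$recall))
  fs <- x$fst_summary
  cat(sprintf("  F_ST median mother:day3 %.3f, day3:day5 %.3f (ordering %.2f)\n",
              fs$median_mother_day3, fs$median_day3_day5,
              fs$ordering_fraction))
  cat(sprintf("  DA KOs: %d; top VD-enriched pathway: %s (q = %.3g)\n",
              sum(x$functional$da$da),
              x$functional$enrichment$pathway_id[
                which.min(x$functional$enrichment$q)],
              min(x$functional$enrichment$q)))
  invisible(x)
}
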