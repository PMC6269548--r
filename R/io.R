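#' Write per-sample contig FASTA files
#'
#' @param contigs contig data.frame (`contig_id`, `sample_id`, `sequence`).
#' @param dir output directory (created if needed); one
#'   `<sample_id>.contigs.fasta` per sample.
#' @return invisibly, the written paths.
#' @export
write_contig_fasta <- function(contigs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sid in unique(contigs$sample_id)) {
    sub <- contigs[contigs$sample_id == sid, ]
    x <- Biostrings::DNAStringSet(setNames(sub$sequence, sub$contig_id))
    path <- file.path(dir, paste0(sid, ".contigs.fasta"))
    Biostrings::writeXStringSet(x, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a contig FASTA file
#'
#' @param path FASTA path.
#' @param sample_id sample id to attach (default: file name stem).
#' @return contig data.frame (`contig_id`, `sample_id`, `sequence`,
#'   `length`).
#' @export
read_contig_fasta <- function(path, sample_id = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  sid <- sample_id %||% sub("\\.contigs\\.fasta$", "", basename(path))
  data.frame(contig_id = names(x), sample_id = sid,
             sequence = as.character(x), length = Biostrings::width(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write marker proteins as FASTA
#'
#' @param contig_markers marker table (`protein_id`, `aa_seq`).
#' @param path output path.
#' @export
write_marker_fasta <- function(contig_markers, path) {
  x <- Biostrings::AAStringSet(setNames(contig_markers$aa_seq,
                                        contig_markers$protein_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write pileups as a TSV table
#'
#' Columns: `genome_id`, `pos` (0-based), `sample_id`, `A`, `C`, `G`, `T`.
#' A `#genome_length=<n>` header line preserves the genome length.
#'
#' @param pileups list of pileups.
#' @param path output path.
#' @export
write_pileup_tsv <- function(pileups, path) {
  gl <- unique(vapply(pileups, `[[`, 0L, "genome_length"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#genome_length=%d", gl[1]), con)
  writeLines(paste(c("genome_id", "pos", "sample_id", DNA_ALPHABET),
                   collapse = "\t"), con)
  for (p in pileups) {
    if (!length(p$pos)) next
    df <- data.frame(p$genome_id, p$pos, p$sample_id, p$counts)
    write.table(df, con, sep = "\t", quote = FALSE, col.names = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a pileup TSV written by [write_pileup_tsv()]
#'
#' @param path TSV path.
#' @param genome_length override for the genome length (otherwise taken
#'   from the header line).
#' @return named list of pileups, keyed `"genome|sample"`.
#' @export
read_pileup_tsv <- function(path, genome_length = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(genome_length)) {
    if (!grepl("^#genome_length=", first)) {
      stop("genome_length not given and no header line found")
    }
    genome_length <- as.integer(sub("^#genome_length=", "", first))
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste0(df$genome_id, "|", df$sample_id))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sub <- df[df$genome_id == parts[1] & df$sample_id == parts[2], ]
    cnt <- as.matrix(sub[, DNA_ALPHABET])
    dimnames(cnt) <- list(NULL, DNA_ALPHABET)
    out[[key]] <- new_pileup(parts[1], parts[2], sub$pos, cnt,
                             genome_length)
  }
  out
}

#' Export pileups of one genome as a minimal VCF 4.2
#'
#' One record per position covered in any sample; `CHROM` is the genome id,
#' `POS` is 1-based, `REF` is the overall majority allele, `ALT` lists the
#' other observed alleles, and each sample column carries `AD:DP` (allelic
#' depths in REF,ALT order and total depth).
#'
#' @param pileups list of pileups of one genome.
#' @param path output path.
#' @export
write_pileup_vcf <- function(pileups, path) {
  gid <- unique(vapply(pileups, `[[`, "", "genome_id"))
  if (length(gid) != 1) stop("all pileups must be of one genome")
  sids <- vapply(pileups, `[[`, "", "sample_id")
  all_pos <- sort(unique(unlist(lapply(pileups, `[[`, "pos"))))
  # pooled counts decide REF/ALT
  pooled <- matrix(0L, length(all_pos), 4,
                   dimnames = list(NULL, DNA_ALPHABET))
  for (p in pileups) {
    i <- match(p$pos, all_pos)
    pooled[i, ] <- pooled[i, ] + p$counts
  }
  ref_idx <- max.col(pooled, ties.method = "first")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", gid,
            pileups[[1]]$genome_length),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sids), collapse = "\t")
  ), con)
  for (i in seq_along(all_pos)) {
    ref <- DNA_ALPHABET[ref_idx[i]]
    alts <- DNA_ALPHABET[pooled[i, ] > 0 &
                         seq_len(4) != ref_idx[i]]
    alt_field <- if (length(alts)) paste(alts, collapse = ",") else "."
    alleles <- c(ref, alts)
    cells <- vapply(pileups, function(p) {
      j <- match(all_pos[i], p$pos)
      if (is.na(j)) return("./.:.")
      ad <- p$counts[j, alleles]
      sprintf("%s:%d", paste(ad, collapse = ","), sum(p$counts[j, ]))
    }, "")
    writeLines(paste(c(gid, all_pos[i] + 1L, ".", ref, alt_field, ".",
                       "PASS", ".", "AD:DP", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal AD:DP VCF back into pileups
#'
#' Counterpart of [write_pileup_vcf()] (requires the vcfR package).
#'
#' @param path VCF path.
#' @param genome_length genome length; default parsed from the contig
#'   header.
#' @return named list of pileups keyed `"genome|sample"`.
#' @export
read_pileup_vcf <- function(path, genome_length = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (is.null(genome_length)) {
    m <- regmatches(v@meta, regexec("length=([0-9]+)", v@meta))
    lens <- as.integer(unlist(lapply(m, `[`, 2)))
    genome_length <- lens[!is.na(lens)][1]
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  out <- list()
  for (sid in colnames(ad)) {
    counts <- matrix(0L, nrow(fix), 4, dimnames = list(NULL, DNA_ALPHABET))
    for (i in seq_len(nrow(fix))) {
      alleles <- c(fix$REF[i],
                   if (is.na(fix$ALT[i]) || fix$ALT[i] == ".")
                     character(0) else strsplit(fix$ALT[i], ",")[[1]])
      if (is.na(ad[i, sid]) || ad[i, sid] == ".") next
      depths <- as.integer(strsplit(ad[i, sid], ",")[[1]])
      counts[i, alleles] <- depths
    }
    keep <- rowSums(counts) > 0
    key <- paste0(fix$CHROM[1], "|", sid)
    out[[key]] <- new_pileup(fix$CHROM[1], sid,
                             as.integer(fix$POS[keep]) - 1L,
                             counts[keep, , drop = FALSE], genome_length)
  }
  out
}

#' Write / read a cohort configuration as YAML
#'
#' @param config a [cohort_config()].
#' @param path YAML path.
#' @export
write_cohort_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$transmission_prob <- list(
    groups = rownames(config$transmission_prob),
    classes = colnames(config$transmission_prob),
    values = as.vector(config$transmission_prob)
  )
  for (nm in c("n_pairs_per_group", "class_counts", "gc_by_class",
               "carriage_prob", "within_host_maf", "depth_mean",
               "contaminant_load", "pathway_map_spec")) {
    x[[nm]] <- as.list(x[[nm]])  # keep names through YAML maps
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config_yaml
#' @export
read_cohort_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  tp <- matrix(unlist(x$transmission_prob$values),
               nrow = length(x$transmission_prob$groups),
               dimnames = list(x$transmission_prob$groups,
                               x$transmission_prob$classes))
  x$transmission_prob <- tp
  for (nm in c("n_pairs_per_group", "class_counts", "gc_by_class",
               "carriage_prob", "within_host_maf", "depth_mean",
               "contaminant_load", "pathway_map_spec")) {
    x[[nm]] <- unlist(x[[nm]])
  }
  do.call(cohort_config, x)
}

#' Write the ground truth of a synthetic cohort as JSON
#'
#' @param cohort a `synthetic_cohort`.
#' @param path JSON path.
#' @export
write_truth_json <- function(cohort, path) {
  tr <- cohort$truth
  out <- list(
    transmitted = tr$transmitted,
    env_acquired = tr$env_acquired,
    contaminant_contigs = tr$contaminant_contigs,
    planted_da_kos = tr$planted_da_kos,
    gram_labels = tr$gram_labels,
    true_pi = tr$true_pi
  )
  jsonlite::write_json(out, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
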