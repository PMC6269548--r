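#' Screen sample contigs against a negative control by k-mer containment
#'
#' Contig-level analogue of mapping study reads against negative-control
#' contigs: a sample contig is removed when the fraction of its canonical
#' k-mers found in the control k-mer set reaches `min_containment`. Removal
#' is order-independent (each contig is judged against the fixed control
#' set).
#'
#' @param sample_contigs data.frame with `contig_id` and `sequence`.
#' @param control_contigs data.frame with `sequence` (control sample).
#' @param k k-mer size (>= 11).
#' @param min_containment containment fraction at or above which a contig is
#'   removed.
#' @return list with `removed` and `kept` contig-id vectors and a
#'   `containment` named numeric vector.
#' @export
screen_against_control <- function(sample_contigs, control_contigs,
                                   k = 31, min_containment = 0.9) {
  if (k < 11) stop("k must be >= 11")
  if (k > 32) stop("k must be <= 32 (k-mers are 2-bit packed)")
  if (!nrow(sample_contigs) || !nrow(control_contigs)) {
    stop("contig sets must be non-empty")
  }
  containment <- .kmer_containment(sample_contigs$sequence,
                                   control_contigs$sequence, as.integer(k))
  names(containment) <- sample_contigs$contig_id
  short <- is.na(containment)
  if (any(short)) {
    warning(sprintf("%d contig(s) shorter than k = %d; kept",
                    sum(short), k))
    containment[short] <- 0
  }
  removed <- names(containment)[containment >= min_containment]
  list(removed = removed,
       kept = setdiff(sample_contigs$contig_id, removed),
       containment = containment)
}

# Canonical (reverse-complement-collapsed) tetranucleotide frequency matrix,
# 136 columns, one row per contig.
tetranucleotide_freq <- function(sequences) {
  x <- Biostrings::DNAStringSet(sequences)
  counts <- Biostrings::oligonucleotideFrequency(x, width = 4)
  kmers <- colnames(counts)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)
  ))
  canon <- ifelse(kmers <= rc, kmers, rc)
  collapsed <- t(rowsum(t(counts), canon))
  # palindromic 4-mers are their own reverse complement; halve to keep a
  # single count scale? no -- keep raw summed counts, CLR is scale-free
  collapsed / pmax(rowSums(collapsed), 1)
}

#' Embed contigs in two dimensions by genomic signature
#'
#' Computes canonical tetranucleotide frequencies (136 dimensions after
#' reverse-complement collapsing), applies a centered-log-ratio transform
#' with a pseudocount, and projects to two dimensions. The default
#' projection is principal components with a fixed sign convention (each
#' component is flipped so its largest-magnitude loading is positive),
#' making the embedding fully deterministic. `method = "sammon"` selects a
#' seeded stochastic neighbour-preserving alternative (Sammon mapping from a
#' random initial configuration).
#'
#' @param contigs data.frame with `contig_id` and `sequence` (>= 3 rows).
#' @param pseudocount added to frequencies before the log-ratio transform.
#' @param method `"pca"` (default, deterministic) or `"sammon"`.
#' @param seed seed for the stochastic method.
#' @return data.frame `contig_id`, `x`, `y`.
#' @export
embed_contigs <- function(contigs, pseudocount = 3e-3,
                          method = c("pca", "sammon"), seed = 1) {
  method <- match.arg(method)
  if (nrow(contigs) < 3) stop("need at least 3 contigs to embed")
  freq <- tetranucleotide_freq(contigs$sequence)
  lg <- log(freq + pseudocount)
  clr <- lg - rowMeans(lg)
  if (all(abs(apply(clr, 2, stats::var)) < 1e-18)) {
    warning("all contigs have identical composition; embedding at origin")
    return(data.frame(contig_id = contigs$contig_id, x = 0, y = 0))
  }
  coords <- if (method == "pca") {
    p <- prcomp(clr, center = TRUE, scale. = FALSE)
    xy <- p$x[, 1:2, drop = FALSE]
    if (ncol(xy) < 2) xy <- cbind(xy, 0)
    for (j in 1:2) {
      if (j <= ncol(p$rotation)) {
        load <- p$rotation[, j]
        if (load[which.max(abs(load))] < 0) xy[, j] <- -xy[, j]
      }
    }
    xy
  } else {
    with_seed(seed, {
      d <- dist(clr)
      d[d == 0] <- 1e-12
      init <- matrix(rnorm(nrow(clr) * 2), ncol = 2)
      MASS::sammon(d, y = init, trace = FALSE)$points
    })
  }
  data.frame(contig_id = contigs$contig_id,
             x = coords[, 1], y = coords[, 2])
}

#' Jointly bin embedded contigs with DBSCAN
#'
#' Density-based clustering of a 2-D contig embedding (sample plus control
#' contigs embedded together), with noise labelling. Each bin records its
#' total length and the length contributed by control-sample contigs, the
#' quantities the artefact-flagging rule consumes.
#'
#' @param embedding data.frame from [embed_contigs()].
#' @param contigs data.frame with `contig_id`, `sample_id`, `length`.
#' @param control_sample_id sample id of the negative control.
#' @param eps DBSCAN radius; `NULL` (default) uses the 95th percentile of
#'   4-nearest-neighbour distances (heuristic, reported on the result).
#' @param min_points DBSCAN core-point threshold.
#' @return list with `bins` (list of bins: `bin_id`, `members`,
#'   `total_length`, `control_length`), `noise` (contig ids) and `eps`.
#' @export
joint_bin <- function(embedding, contigs, control_sample_id = "CTRL",
                      eps = NULL, min_points = 5) {
  if (!nrow(embedding)) stop("embedding is empty")
  xy <- as.matrix(embedding[, c("x", "y")])
  if (is.null(eps)) eps <- knn_dist_quantile(xy, k = 4, prob = 0.95)
  if (eps <= 0) stop("eps must be > 0")
  labels <- dbscan_cluster(xy, eps = eps, min_points = min_points)
  info <- contigs[match(embedding$contig_id, contigs$contig_id), ]
  bins <- lapply(sort(unique(labels[labels > 0])), function(b) {
    sel <- labels == b
    list(bin_id = sprintf("jbin%03d", b),
         members = embedding$contig_id[sel],
         total_length = sum(info$length[sel]),
         control_length = sum(info$length[sel &
                                info$sample_id == control_sample_id]))
  })
  list(bins = bins, noise = embedding$contig_id[labels == 0], eps = eps)
}

#' Flag putative artefact bins
#'
#' A bin is flagged as a putative reconstructed genome of artefactual DNA
#' when its total length is strictly below 10 Mbp and its control-derived
#' length exceeds 0.01% of the total contig length of the negative-control
#' sample. Both inequalities are strict.
#'
#' @param bins list of bins from [joint_bin()].
#' @param control_total_length total contig length (bp) of the control
#'   sample; must be positive.
#' @param max_bin_length flag only bins strictly shorter than this (bp).
#' @param min_control_frac flag only bins whose control-length fraction
#'   strictly exceeds this.
#' @return character vector of flagged `bin_id`s.
#' @export
flag_artefact_bins <- function(bins, control_total_length,
                               max_bin_length = 1e7,
                               min_control_frac = 1e-4) {
  if (control_total_length <= 0) stop("control_total_length must be > 0")
  flagged <- vapply(bins, function(b) {
    b$total_length < max_bin_length &&
      (b$control_length / control_total_length) > min_control_frac
  }, TRUE)
  vapply(bins[flagged], `[[`, "", "bin_id")
}

#' Apply decontamination to one sample
#'
#' Removes screened contigs and members of flagged bins from a sample's
#' contig set. A contig caught by both stages is reported once with reason
#' `"screen"` (the screening stage wins).
#'
#' @param sample_contigs data.frame of the sample's contigs.
#' @param bins list of bins from [joint_bin()].
#' @param flagged_bin_ids bin ids from [flag_artefact_bins()].
#' @param screened_ids contig ids removed by [screen_against_control()].
#' @return list with `curated` (data.frame) and `report` (data.frame
#'   `contig_id`, `sample_id`, `reason`, `bin_id`).
#' @export
apply_decontamination <- function(sample_contigs, bins = list(),
                                  flagged_bin_ids = character(0),
                                  screened_ids = character(0)) {
  bin_of <- character(0)
  for (b in bins) {
    if (b$bin_id %in% flagged_bin_ids) {
      bin_of[b$members] <- b$bin_id
    }
  }
  in_flagged <- sample_contigs$contig_id[
    sample_contigs$contig_id %in% names(bin_of)
  ]
  screened <- intersect(sample_contigs$contig_id, screened_ids)
  bin_removed <- setdiff(in_flagged, screened)
  report <- rbind(
    data.frame(contig_id = screened,
               sample_id = sample_contigs$sample_id[
                 match(screened, sample_contigs$contig_id)],
               reason = rep("screen", length(screened)),
               bin_id = rep(NA_character_, length(screened)),
               stringsAsFactors = FALSE),
    data.frame(contig_id = bin_removed,
               sample_id = sample_contigs$sample_id[
                 match(bin_removed, sample_contigs$contig_id)],
               reason = rep("bin", length(bin_removed)),
               bin_id = unname(bin_of[bin_removed]),
               stringsAsFactors = FALSE)
  )
  curated <- sample_contigs[!(sample_contigs$contig_id %in%
                                report$contig_id), , drop = FALSE]
  list(curated = curated, report = report)
}

#' Decontaminate one sample against the control (full procedure)
#'
#' Runs the combined artefact-removal procedure for a single study sample:
#' k-mer screening against the control, joint 2-D embedding and DBSCAN
#' binning of sample plus control contigs, flagging of small
#' control-containing bins, and removal. An exclusion list (e.g. rRNA
#' contigs identified upstream) can be removed before binning.
#'
#' @param sample_contigs,control_contigs data.frames of contigs
#'   (`contig_id`, `sample_id`, `sequence`, `length`).
#' @param k,min_containment screening parameters.
#' @param eps,min_points joint-binning parameters.
#' @param exclude_ids contigs to drop before binning (pass-through hook for
#'   rRNA removal on real data; synthetic contigs carry none).
#' @param embed_method embedding method, see [embed_contigs()].
#' @param screen optional precomputed [screen_against_control()] result for
#'   this sample (used by [decontaminate_cohort()] to screen all samples in
#'   one pass).
#' @return list with `curated`, `report`, `bins`, `flagged`, `screen`.
#' @export
decontaminate_sample <- function(sample_contigs, control_contigs,
                                 k = 31, min_containment = 0.9,
                                 eps = NULL, min_points = 5,
                                 exclude_ids = character(0),
                                 embed_method = "pca", screen = NULL) {
  sample_contigs <- sample_contigs[
    !(sample_contigs$contig_id %in% exclude_ids), , drop = FALSE]
  scr <- screen %||%
    screen_against_control(sample_contigs, control_contigs,
                           k = k, min_containment = min_containment)
  joint <- rbind(
    sample_contigs[, c("contig_id", "sample_id", "sequence", "length")],
    control_contigs[, c("contig_id", "sample_id", "sequence", "length")]
  )
  emb <- embed_contigs(joint, method = embed_method)
  bins <- joint_bin(emb, joint,
                    control_sample_id = control_contigs$sample_id[1],
                    eps = eps, min_points = min_points)
  flagged <- flag_artefact_bins(bins$bins,
                                control_total_length =
                                  sum(control_contigs$length))
  res <- apply_decontamination(sample_contigs, bins$bins, flagged,
                               scr$removed)
  c(res, list(bins = bins, flagged = flagged, screen = scr))
}

#' Decontaminate every study sample of a contig table
#'
#' Convenience wrapper running [decontaminate_sample()] for each study
#' sample against the shared control sample. Returns the pooled curated
#' contig table and removal report.
#'
#' @param contigs contig data.frame covering all samples incl. the control.
#' @param control_sample_id sample id of the negative control.
#' @param ... passed to [decontaminate_sample()].
#' @return list with `curated` and `report` data.frames.
#' @export
decontaminate_cohort <- function(contigs, control_sample_id = "CTRL",
                                 k = 31, min_containment = 0.9, ...) {
  control_contigs <- contigs[contigs$sample_id == control_sample_id, ,
                             drop = FALSE]
  if (!nrow(control_contigs)) stop("no control contigs found")
  study <- contigs[contigs$sample_id != control_sample_id, , drop = FALSE]
  all_screen <- screen_against_control(study, control_contigs, k = k,
                                       min_containment = min_containment)
  curated <- list()
  report <- list()
  for (sid in unique(study$sample_id)) {
    sel <- study$sample_id == sid
    cont <- all_screen$containment[study$contig_id[sel]]
    scr <- list(removed = names(cont)[cont >= min_containment],
                kept = names(cont)[cont < min_containment],
                containment = cont)
    res <- decontaminate_sample(
      study[sel, , drop = FALSE], control_contigs,
      k = k, screen = scr, ...
    )
    curated[[sid]] <- res$curated
    report[[sid]] <- res$report
  }
  list(curated = do.call(rbind, curated), report = do.call(rbind, report))
}
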