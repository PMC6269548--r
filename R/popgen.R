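#' Coverage summary of a pileup
#'
#' @param pileup a pileup (see [simulate_pileup()] / [read_pileup_tsv()]).
#' @param genome_length genome length; defaults to the pileup's own.
#' @param completeness completeness of the matching genome reconstruction
#'   (fraction of marker families recovered), `NA` if unknown.
#' @return list with `genome_id`, `sample_id`, `median_depth` (median over
#'   covered positions), `breadth` (fraction of genome positions with depth
#'   >= 1) and `completeness`.
#' @export
coverage_summary <- function(pileup, genome_length = pileup$genome_length,
                             completeness = NA_real_) {
  depth <- rowSums(pileup$counts)
  list(genome_id = pileup$genome_id, sample_id = pileup$sample_id,
       median_depth = if (length(depth)) median(depth) else 0,
       breadth = length(pileup$pos) / genome_length,
       completeness = completeness)
}

#' Qualify a genome-sample combination for population-genomic analysis
#'
#' A combination is included when the median coverage is at least 20x, the
#' breadth is at least 40% and the genome reconstruction is more than 65%
#' complete. All failing gates are reported.
#'
#' @param summary a [coverage_summary()].
#' @param min_median,min_breadth,min_completeness the three gates; the
#'   coverage and breadth gates are inclusive (`>=`), the completeness gate
#'   strict (`>`).
#' @return list with `include` (logical) and `reasons` (character vector of
#'   failed gates, empty when included).
#' @export
qualify_genome_sample <- function(summary, min_median = 20,
                                  min_breadth = 0.40,
                                  min_completeness = 0.65) {
  reasons <- character(0)
  if (summary$median_depth < min_median) reasons <- c(reasons, "coverage")
  if (summary$breadth < min_breadth) reasons <- c(reasons, "breadth")
  if (is.na(summary$completeness) ||
      summary$completeness <= min_completeness) {
    reasons <- c(reasons, "completeness")
  }
  list(include = length(reasons) == 0, reasons = reasons)
}

#' Downsample a pileup to a target median coverage
#'
#' When the median depth exceeds the target, every allele count is thinned
#' binomially with probability `target / median_depth` (one draw per allele
#' per column); otherwise the pileup is returned unchanged. Columns whose
#' depth reaches zero are dropped.
#'
#' @param pileup a pileup.
#' @param target target median coverage (> 0).
#' @param seed optional seed for the thinning draws.
#' @return a pileup.
#' @export
downsample_to_median <- function(pileup, target = 20, seed = NULL) {
  if (target <= 0) stop("target must be > 0")
  depth <- rowSums(pileup$counts)
  med <- if (length(depth)) median(depth) else 0
  if (med <= target) return(pileup)
  p <- target / med
  thin <- function() {
    cnt <- pileup$counts
    cnt[] <- rbinom(length(cnt), as.integer(cnt), p)
    keep <- rowSums(cnt) > 0
    new_pileup(pileup$genome_id, pileup$sample_id, pileup$pos[keep],
               cnt[keep, , drop = FALSE], pileup$genome_length)
  }
  if (is.null(seed)) thin() else with_seed(seed, thin())
}

#' Call single-nucleotide variants from a pileup
#'
#' At each column, every non-major allele supported by at least
#' `min_support` reads and reaching an allele frequency of at least
#' `min_af` is retained (both thresholds inclusive). Columns with no
#' retained minor allele are monomorphic.
#'
#' @param pileup a pileup.
#' @param min_support minimum supporting reads (default 4).
#' @param min_af minimum allele frequency (default 0.01).
#' @return data.frame `genome_id`, `pos` (0-based), `allele`, `count`,
#'   `freq`, `major` (the column's majority allele).
#' @export
call_snvs <- function(pileup, min_support = 4, min_af = 0.01) {
  if (!length(pileup$pos)) {
    return(data.frame(genome_id = character(0), pos = integer(0),
                      allele = character(0), count = integer(0),
                      freq = numeric(0), major = character(0)))
  }
  cnt <- pileup$counts
  depth <- rowSums(cnt)
  major_idx <- max.col(cnt, ties.method = "first")
  rows <- list()
  for (a in seq_len(4)) {
    sel <- which(cnt[, a] >= min_support &
                 cnt[, a] / depth >= min_af &
                 a != major_idx)
    if (length(sel)) {
      rows[[length(rows) + 1]] <- data.frame(
        genome_id = pileup$genome_id, pos = pileup$pos[sel],
        allele = DNA_ALPHABET[a], count = cnt[sel, a],
        freq = cnt[sel, a] / depth[sel],
        major = DNA_ALPHABET[major_idx[sel]], stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows) %||%
    data.frame(genome_id = character(0), pos = integer(0),
               allele = character(0), count = integer(0), freq = numeric(0),
               major = character(0))
  res <- res[order(res$pos, res$allele), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Common loci of several pileups
#'
#' Positions covered (depth >= 1, after any downsampling) in every pileup
#' of the comparison; restricting all statistics to this set makes the
#' intra- and inter-population diversities commensurable.
#'
#' @param pileups list of >= 2 pileups on the same genome.
#' @return sorted integer vector of 0-based positions.
#' @export
intersect_loci <- function(pileups) {
  if (length(pileups) < 2) stop("need at least 2 pileups")
  loci <- Reduce(intersect, lapply(pileups, `[[`, "pos"))
  if (!length(loci)) {
    stop("no loci are covered in all samples; comparison skipped")
  }
  sort(loci)
}

#' Intra-population nucleotide diversity (pi)
#'
#' Average per-site probability that two reads drawn from the sample differ.
#' The `plugin` estimator draws reads with replacement
#' (`pi_l = 1 - sum_a f_a^2`); the `unbiased` estimator draws without
#' replacement (`pi_l = sum_{a != b} c_a c_b / (n (n - 1))`). The per-site
#' values are averaged over all requested loci, monomorphic loci
#' contributing zero, so pi is a per-site quantity in `[0, 1)`.
#'
#' @param pileup a pileup.
#' @param loci 0-based positions to average over (must be covered);
#'   defaults to all covered positions.
#' @param mode `"plugin"` (default) or `"unbiased"`.
#' @return pi (numeric scalar).
#' @export
compute_pi <- function(pileup, loci = pileup$pos,
                       mode = c("plugin", "unbiased")) {
  mode <- match.arg(mode)
  idx <- match(loci, pileup$pos)
  if (anyNA(idx)) stop("some loci are not covered in the pileup")
  cnt <- pileup$counts[idx, , drop = FALSE]
  mean(per_locus_pi(cnt, mode), na.rm = TRUE)
}

# Per-locus diversity; loci with depth < 2 are NA in unbiased mode
# (callers average with na.rm and have been warned).
per_locus_pi <- function(cnt, mode) {
  n <- rowSums(cnt)
  if (mode == "plugin") {
    1 - rowSums((cnt / n) ^ 2)
  } else {
    low <- n < 2
    if (any(low)) {
      warning(sprintf("%d locus/loci with depth < 2 excluded (unbiased mode)",
                      sum(low)))
    }
    v <- (n ^ 2 - rowSums(cnt ^ 2)) / (n * (n - 1))
    v[low] <- NA_real_
    v
  }
}

#' Fixation index (F_ST) between two samples
#'
#' One minus the average intra-population diversity of the two samples
#' divided by the inter-population (between-sample) diversity, all three
#' averaged over the same locus set. Per locus, the between-sample
#' diversity is `1 - sum_a f1_a f2_a` (the probability that one read from
#' each sample differ).
#'
#' @param pileup_1,pileup_2 pileups of the two samples on one genome.
#' @param loci common loci (from [intersect_loci()]); both pileups must
#'   cover all of them.
#' @param mode intra-population estimator, `"plugin"` or `"unbiased"`.
#' @return list with `fst` (NA when the between-sample diversity is zero),
#'   `pi_intra` (length 2), `pi_between`, `n_loci`, `mode`.
#' @export
compute_fst <- function(pileup_1, pileup_2, loci,
                        mode = c("plugin", "unbiased")) {
  mode <- match.arg(mode)
  i1 <- match(loci, pileup_1$pos)
  i2 <- match(loci, pileup_2$pos)
  if (anyNA(i1) || anyNA(i2)) {
    stop("loci must be covered in both pileups")
  }
  c1 <- pileup_1$counts[i1, , drop = FALSE]
  c2 <- pileup_2$counts[i2, , drop = FALSE]
  f1 <- c1 / rowSums(c1)
  f2 <- c2 / rowSums(c2)
  pi_between <- mean(1 - rowSums(f1 * f2))
  pi1 <- mean(per_locus_pi(c1, mode), na.rm = TRUE)
  pi2 <- mean(per_locus_pi(c2, mode), na.rm = TRUE)
  fst <- if (pi_between == 0) NA_real_ else
    1 - ((pi1 + pi2) / 2) / pi_between
  list(fst = fst, pi_intra = c(pi1, pi2), pi_between = pi_between,
       n_loci = length(loci), mode = mode)
}

#' Population-genomic analysis of a set of pileups
#'
#' Full popgen stage for one genome: qualification (coverage, breadth,
#' completeness), downsampling to the target median coverage, restriction
#' to loci recovered in all qualified samples, per-sample pi and pairwise
#' F_ST.
#'
#' @param pileups list of pileups of one genome (one per sample).
#' @param completeness named numeric: completeness per sample id.
#' @param target_median downsampling target.
#' @param mode estimator mode.
#' @param min_median,min_breadth,min_completeness qualification gates.
#' @param seed seed for the downsampling draws.
#' @param pairs optional 2-column matrix/data.frame of sample-id pairs to
#'   compare; default all pairs of qualified samples.
#' @return list with `pi` (data.frame sample, pi, n_loci, mode), `fst`
#'   (data.frame sample_1, sample_2, fst, n_loci, mode), `included`,
#'   `excluded` (named list of reasons).
#' @export
popgen_analysis <- function(pileups, completeness = NULL,
                            target_median = 20,
                            mode = "plugin",
                            min_median = 20, min_breadth = 0.40,
                            min_completeness = 0.65, seed = 1,
                            pairs = NULL) {
  excluded <- list()
  qualified <- list()
  for (p in pileups) {
    cmp <- if (is.null(completeness)) 1 else
      completeness[[p$sample_id]] %||% NA_real_
    q <- qualify_genome_sample(
      coverage_summary(p, completeness = cmp),
      min_median = min_median, min_breadth = min_breadth,
      min_completeness = min_completeness
    )
    if (q$include) qualified[[p$sample_id]] <- p else
      excluded[[p$sample_id]] <- q$reasons
  }
  if (length(qualified) < 2) {
    return(list(pi = NULL, fst = NULL, included = names(qualified),
                excluded = excluded))
  }
  qualified <- lapply(seq_along(qualified), function(i) {
    downsample_to_median(qualified[[i]], target = target_median,
                         seed = derive_seed(seed, names(qualified)[i]))
  })
  names(qualified) <- vapply(qualified, `[[`, "", "sample_id")
  loci <- tryCatch(intersect_loci(qualified), error = function(e) NULL)
  if (is.null(loci)) {
    return(list(pi = NULL, fst = NULL, included = names(qualified),
                excluded = excluded, note = "empty common locus set"))
  }
  ids <- names(qualified)
  # cache per-sample allele counts and frequencies at the common loci
  cnt_cache <- lapply(qualified, function(p) {
    p$counts[match(loci, p$pos), , drop = FALSE]
  })
  freq_cache <- lapply(cnt_cache, function(cnt) cnt / rowSums(cnt))
  pi_cache <- vapply(cnt_cache, function(cnt) {
    mean(per_locus_pi(cnt, mode), na.rm = TRUE)
  }, 0)
  pi_df <- data.frame(sample_id = ids, pi = unname(pi_cache),
                      n_loci = length(loci), mode = mode,
                      stringsAsFactors = FALSE)
  if (is.null(pairs)) {
    pairs <- if (length(ids) >= 2) t(utils::combn(ids, 2)) else
      matrix(character(0), 0, 2)
  } else {
    pairs <- as.matrix(pairs)
    pairs <- pairs[pairs[, 1] %in% ids & pairs[, 2] %in% ids, ,
                   drop = FALSE]
  }
  fst_rows <- lapply(seq_len(nrow(pairs)), function(r) {
    s1 <- pairs[r, 1]
    s2 <- pairs[r, 2]
    pi_between <- mean(1 - rowSums(freq_cache[[s1]] * freq_cache[[s2]]))
    fst <- if (pi_between == 0) NA_real_ else
      1 - ((pi_cache[[s1]] + pi_cache[[s2]]) / 2) / pi_between
    data.frame(sample_1 = s1, sample_2 = s2, fst = fst,
               n_loci = length(loci), mode = mode, stringsAsFactors = FALSE)
  })
  rownames(pi_df) <- NULL
  list(pi = pi_df, fst = do.call(rbind, fst_rows), included = ids,
       excluded = excluded)
}
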