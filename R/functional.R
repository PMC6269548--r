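#' Assign the best KO to a gene
#'
#' The candidate KO with the highest bit score is assigned if and only if
#' that score strictly exceeds the binary logarithm of the number of target
#' genes; score ties are broken by the lexicographically smallest KO id.
#'
#' @param candidates data.frame with `ko` and `bit_score` for one gene (may
#'   be empty).
#' @param n_target_genes number of target genes in the search database
#'   (>= 1).
#' @return a KO id, or `NA_character_` when no candidate qualifies.
#' @export
assign_best_ko <- function(candidates, n_target_genes) {
  if (n_target_genes < 1) stop("n_target_genes must be >= 1")
  if (is.null(candidates) || !nrow(candidates)) return(NA_character_)
  best <- max(candidates$bit_score)
  if (!(best > log2(n_target_genes))) return(NA_character_)
  min(candidates$ko[candidates$bit_score == best])
}

#' Aggregate gene read counts into a sample x KO table
#'
#' Resolves each gene's KO with [assign_best_ko()] (the number of target
#' genes defaults to the per-sample gene count) and sums read counts per
#' KO. Unassigned genes are excluded. The relative view row-normalizes each
#' sample; samples with zero assigned reads are flagged and left `NA` in
#' the relative view.
#'
#' @param gene_hits data.frame `sample_id`, `gene_id`, `read_count`.
#' @param candidates data.frame `gene_id`, `ko`, `bit_score`.
#' @param n_target_genes optional fixed database size; default = number of
#'   genes in each gene's sample.
#' @return list with `counts` (samples x KOs matrix), `relative` (same
#'   shape, rows summing to 1), `unassigned` (gene ids) and
#'   `empty_samples`.
#' @export
aggregate_ko_counts <- function(gene_hits, candidates,
                                n_target_genes = NULL) {
  cand_by_gene <- split(candidates[, c("ko", "bit_score")],
                        candidates$gene_id)
  genes_per_sample <- table(gene_hits$sample_id)
  assigned <- vapply(seq_len(nrow(gene_hits)), function(i) {
    nt <- n_target_genes %||%
      as.integer(genes_per_sample[[gene_hits$sample_id[i]]])
    assign_best_ko(cand_by_gene[[gene_hits$gene_id[i]]], nt)
  }, "")
  keep <- !is.na(assigned)
  kos <- sort(unique(assigned[keep]))
  samples <- sort(unique(gene_hits$sample_id))
  counts <- matrix(0, length(samples), length(kos),
                   dimnames = list(samples, kos))
  if (any(keep)) {
    agg <- tapply(gene_hits$read_count[keep],
                  list(gene_hits$sample_id[keep], assigned[keep]), sum)
    counts[rownames(agg), colnames(agg)] <-
      ifelse(is.na(agg), 0, agg)
  }
  totals <- rowSums(counts)
  rel <- counts / totals
  empty <- names(totals)[totals == 0]
  if (length(empty)) rel[empty, ] <- NA_real_
  list(counts = counts, relative = rel,
       unassigned = gene_hits$gene_id[!keep], empty_samples = empty)
}

#' Jensen-Shannon divergence
#'
#' JSD with base-2 logarithms (range `[0, 1]`); `0 log 0` is taken as 0.
#' The square-root distance variant is selectable.
#'
#' @param p,q non-negative vectors over the same support, each summing to 1
#'   (within 1e-6).
#' @param sqrt_distance return `sqrt(JSD)` (a metric) instead of the
#'   divergence.
#' @return divergence (or distance) in `[0, 1]`.
#' @export
jensen_shannon <- function(p, q, sqrt_distance = FALSE) {
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("p and q must be non-negative and sum to 1")
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    sel <- a > 0
    sum(a[sel] * log2(a[sel] / b[sel]))
  }
  d <- (kl(p, m) + kl(q, m)) / 2
  d <- min(max(d, 0), 1)  # guard rounding
  if (sqrt_distance) sqrt(d) else d
}

#' Spearman correlation of two functional profiles
#'
#' Rank correlation with average ranks for ties, over the union KO set
#' (missing KOs count as zero).
#'
#' @param p,q named abundance vectors.
#' @return rho, or `NA` (with a warning) when either profile has zero
#'   variance.
#' @export
spearman_profile_correlation <- function(p, q) {
  kos <- union(names(p), names(q))
  x <- setNames(rep(0, length(kos)), kos)
  y <- x
  x[names(p)] <- p
  y[names(q)] <- q
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance profile; Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Wilcoxon test between two groups
#'
#' Two-sided rank-sum test (or signed-rank test when `paired = TRUE`).
#' The exact distribution is used for combined sample sizes up to 20 when
#' the data are tie-free; larger or tied data use the normal approximation
#' with tie correction. All-tied data return p = 1 with a warning.
#'
#' @param x,y numeric observations of the two groups (pairs when
#'   `paired = TRUE`).
#' @param paired logical.
#' @return two-sided p-value.
#' @export
wilcoxon_groups <- function(x, y, paired = FALSE) {
  if (!length(x) || !length(y)) stop("both groups need observations")
  if (paired && length(x) != length(y)) stop("paired groups must match")
  vals <- c(x, y)
  if (length(unique(vals)) == 1 || (paired && all(x == y))) {
    warning("all observations tied; p = 1")
    return(1)
  }
  has_ties <- anyDuplicated(if (paired) (x - y)[x != y] else vals) > 0
  exact <- (length(vals) <= 20) && !has_ties
  suppressWarnings(
    wilcox.test(x, y, paired = paired, exact = exact,
                correct = !exact)$p.value
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement; output order
#' matches input order.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
adjust_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differentially abundant KOs between delivery groups
#'
#' For each KO, compares relative abundances in VD versus CSD and VD versus
#' CSD_SGA neonatal samples (pooled over the requested days) with two-sided
#' rank-sum tests; p-values are BH-adjusted across KOs within each
#' comparison. A KO is flagged differentially abundant when the adjusted p
#' is below `alpha` in at least one comparison and the direction of change
#' (sign of the VD-minus-other median difference) agrees across the
#' available comparisons.
#'
#' @param relative samples x KOs relative-abundance matrix.
#' @param samples sample metadata (`sample_id`, `role`, `day`, `group`).
#' @param days neonatal days pooled into the comparison (default 3 and 5).
#' @param alpha FDR threshold.
#' @return data.frame per KO: `ko`, `p_csd`, `q_csd`, `dir_csd`, `p_sga`,
#'   `q_sga`, `dir_sga`, `da`.
#' @export
differential_kos <- function(relative, samples, days = c(3, 5),
                             alpha = 0.05) {
  neo <- samples[samples$role == "neonate" & samples$day %in% days, ]
  sel <- function(grp) {
    ids <- neo$sample_id[neo$group == grp]
    relative[intersect(ids, rownames(relative)), , drop = FALSE]
  }
  vd <- sel("VD")
  comps <- list(csd = sel("CSD"), sga = sel("CSD_SGA"))
  kos <- colnames(relative)
  res <- data.frame(ko = kos, stringsAsFactors = FALSE)
  for (nm in names(comps)) {
    other <- comps[[nm]]
    if (nrow(vd) < 2 || nrow(other) < 2) {
      res[[paste0("p_", nm)]] <- NA_real_
      res[[paste0("q_", nm)]] <- NA_real_
      res[[paste0("dir_", nm)]] <- NA_real_
      next
    }
    p <- vapply(kos, function(k) {
      # KOs absent from every sample of a comparison are all-tied; they get
      # p = 1 by design, no need to surface the per-KO warning here
      suppressWarnings(wilcoxon_groups(vd[, k], other[, k]))
    }, 0)
    dirs <- vapply(kos, function(k) {
      sign(median(vd[, k]) - median(other[, k]))
    }, 0)
    res[[paste0("p_", nm)]] <- p
    res[[paste0("q_", nm)]] <- adjust_fdr(p)
    res[[paste0("dir_", nm)]] <- dirs
  }
  q <- cbind(res$q_csd, res$q_sga)
  d <- cbind(res$dir_csd, res$dir_sga)
  res$da <- vapply(seq_len(nrow(res)), function(i) {
    qi <- q[i, !is.na(q[i, ])]
    di <- d[i, !is.na(d[i, ])]
    if (!length(qi)) return(FALSE)
    any(qi < alpha) && length(unique(di)) == 1 && all(di != 0)
  }, TRUE)
  res
}

#' Hypergeometric pathway enrichment
#'
#' One-sided hypergeometric upper-tail test (P(X >= overlap), including the
#' observed count) of each pathway's KOs among the differentially abundant
#' set, with the detected KO universe as population; BH adjustment across
#' pathways.
#'
#' @param da_kos differentially abundant KO ids (subset of `universe`).
#' @param universe all detected KO ids.
#' @param pathway_map data.frame `pathway_id`, `ko`.
#' @return data.frame `pathway_id`, `overlap`, `pathway_size`, `p`, `q`,
#'   `flagged_empty` (pathway disjoint from the universe).
#' @export
pathway_enrichment <- function(da_kos, universe, pathway_map) {
  if (!all(da_kos %in% universe)) stop("da_kos must be a subset of universe")
  N <- length(universe)
  k <- length(da_kos)
  rows <- lapply(unique(pathway_map$pathway_id), function(pw) {
    in_pw <- intersect(pathway_map$ko[pathway_map$pathway_id == pw],
                       universe)
    m <- length(in_pw)
    ov <- length(intersect(in_pw, da_kos))
    if (m == 0) {
      return(data.frame(pathway_id = pw, overlap = 0L, pathway_size = 0L,
                        p = 1, flagged_empty = TRUE,
                        stringsAsFactors = FALSE))
    }
    p <- phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(pathway_id = pw, overlap = ov, pathway_size = m, p = p,
               flagged_empty = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- adjust_fdr(res$p)
  res
}

#' Genome-level enrichment of differentially abundant functions
#'
#' Fisher's exact test (two-sided, the sum of hypergeometric probabilities
#' not exceeding the observed table's) on the 2x2 table crossing membership
#' in a genome's KO repertoire with membership in the differentially
#' abundant set, over the KO universe. The sample odds ratio `ad / bc` is
#' reported; a zero cell triggers the Haldane 0.5 correction (flagged).
#'
#' @param bin_kos KO set of the genome reconstruction.
#' @param da_set differentially abundant KO set.
#' @param universe KO universe.
#' @return list with `odds_ratio`, `p`, `table`, `haldane` (logical),
#'   `degenerate` (logical; OR undefined, p = 1).
#' @export
genome_function_enrichment <- function(bin_kos, da_set, universe) {
  if (!all(bin_kos %in% universe) || !all(da_set %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  a <- length(intersect(bin_kos, da_set))
  b <- length(setdiff(bin_kos, da_set))
  cc <- length(setdiff(da_set, bin_kos))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(c("in_bin", "not_in_bin"),
                                c("da", "not_da")))
  if ((a + b == 0) || (cc + d == 0) || (a + cc == 0) || (b + d == 0)) {
    return(list(odds_ratio = NA_real_, p = 1, table = tab,
                haldane = FALSE, degenerate = TRUE))
  }
  haldane <- any(tab == 0)
  orv <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  p <- fisher.test(tab)$p.value
  list(odds_ratio = orv, p = p, table = tab, haldane = haldane,
       degenerate = FALSE)
}

#' Cumulative relative abundance of a pathway
#'
#' Sum of the relative abundances of a pathway's KOs present in a sample's
#' profile.
#'
#' @param profile named relative-abundance vector (sums to 1).
#' @param pathway_kos KO ids of the pathway.
#' @return fraction in `[0, 1]`.
#' @export
cumulative_pathway_abundance <- function(profile, pathway_kos) {
  sum(profile[names(profile) %in% pathway_kos])
}

#' Gram-stain fractions of a taxonomic profile
#'
#' Sums relative abundances per Gram label. Genera missing from the table
#' are counted as unknown (and reported); the unknown fraction is never
#' folded into the labelled fractions.
#'
#' @param taxon_abundance named (by genus) relative-abundance vector.
#' @param gram_table data.frame `genus`, `gram` in
#'   {negative, positive, unknown}.
#' @return list with `fractions` (named: negative, positive, unknown) and
#'   `missing_genera`.
#' @export
gram_fraction <- function(taxon_abundance, gram_table) {
  labels <- setNames(gram_table$gram, gram_table$genus)
  genus <- names(taxon_abundance)
  lab <- labels[genus]
  missing <- genus[is.na(lab)]
  if (length(missing)) {
    message("genera without Gram label counted as unknown: ",
            paste(missing, collapse = ", "))
    lab[is.na(lab)] <- "unknown"
  }
  fr <- vapply(c("negative", "positive", "unknown"), function(l) {
    sum(taxon_abundance[lab == l])
  }, 0)
  list(fractions = fr, missing_genera = missing)
}

#' Alpha-diversity indices of a profile
#'
#' Richness (non-zero taxa), Shannon diversity (natural logarithm, the
#' vegan convention) and Pielou evenness (`H / ln(richness)`, undefined for
#' a single taxon).
#'
#' @param profile non-negative abundance vector.
#' @return list with `richness`, `shannon`, `pielou` (NA when undefined).
#' @export
diversity_indices <- function(profile) {
  if (all(profile == 0)) {
    return(list(richness = NA_integer_, shannon = NA_real_,
                pielou = NA_real_))
  }
  richness <- sum(profile > 0)
  shannon <- vegan::diversity(profile, index = "shannon")
  pielou <- if (richness > 1) shannon / log(richness) else NA_real_
  list(richness = richness, shannon = unname(shannon), pielou = pielou)
}
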