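#' Bin curated contigs of one sample into genome reconstructions
#'
#' Density-based clustering in a feature space combining the 2-D composition
#' embedding (kept in its native centered-log-ratio units) with log10 depth
#' of coverage scaled by `coverage_weight`, so that genomes with similar
#' composition but different abundance separate on the coverage axis. Bins
#' below the minimum total length are discarded.
#'
#' @param contigs curated contigs of one sample (`contig_id`, `sample_id`,
#'   `sequence`, `length`, `coverage`).
#' @param eps DBSCAN radius; `NULL` uses the `eps_quantile` percentile of
#'   4-nearest-neighbour distances.
#' @param eps_quantile quantile of 4-NN distances for the eps heuristic;
#'   slightly lower than in the joint decontamination binning because
#'   per-genome clusters are smaller here.
#' @param min_points DBSCAN core-point threshold (contigs per genome are
#'   fewer than in the joint decontamination step, hence the lower default).
#' @param min_bin_length discard bins whose total contig length (bp) falls
#'   below this; 100 kb is a sensible floor for real prokaryote assemblies
#'   and should be scaled down for small simulated genomes.
#' @param coverage_weight CLR units per decade of coverage: how strongly a
#'   10-fold coverage difference separates contigs relative to composition.
#' @return list of genome bins: `bin_id`, `sample_id`, `members` (contig
#'   ids), `total_length`, `median_coverage`.
#' @export
bin_sample <- function(contigs, eps = NULL, eps_quantile = 0.90,
                       min_points = 3, min_bin_length = 1e5,
                       coverage_weight = 5) {
  if (!nrow(contigs)) return(list())
  sid <- contigs$sample_id[1]
  if (nrow(contigs) < 3) return(list())
  emb <- embed_contigs(contigs)
  feat <- cbind(emb$x, emb$y,
                coverage_weight * log10(pmax(contigs$coverage, 1e-6)))
  if (is.null(eps)) {
    eps <- knn_dist_quantile(feat, k = 4, prob = eps_quantile)
  }
  labels <- dbscan_cluster(feat, eps = eps, min_points = min_points)
  bins <- list()
  for (b in sort(unique(labels[labels > 0]))) {
    sel <- labels == b
    total <- sum(contigs$length[sel])
    if (total < min_bin_length) next
    bins[[length(bins) + 1]] <- list(
      bin_id = sprintf("%s_bin%02d", sid, length(bins) + 1),
      sample_id = sid,
      members = contigs$contig_id[sel],
      total_length = total,
      median_coverage = median(contigs$coverage[sel])
    )
  }
  bins
}

#' Estimate bin completeness from single-copy marker families
#'
#' Completeness is the fraction of the marker-gene families (35 by default)
#' with at least one hit among the bin's contigs.
#'
#' @param bin a genome bin from [bin_sample()].
#' @param contig_markers data.frame of marker hits (`contig_id`, `family`).
#' @param n_families size of the marker catalogue.
#' @return completeness fraction in `[0, 1]`.
#' @export
estimate_completeness <- function(bin, contig_markers, n_families = 35) {
  fams <- unique(contig_markers$family[
    contig_markers$contig_id %in% bin$members])
  length(fams) / n_families
}

# Pairwise identity of two protein sequences: matches / alignment length,
# with gaps counted as mismatches. Equal-length sequences compare
# position-wise; unequal lengths go through a global alignment.
protein_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    return(sum(ca == cb) / length(ca))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = NULL, gapOpening = 10, gapExtension = 0.5
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  sum(pa == ps & pa != "-") / length(pa)
}

#' Cluster marker proteins by greedy incremental identity clustering
#'
#' CD-HIT-style clustering: sequences are sorted by length (descending;
#' ties by identifier) and each sequence joins the first existing cluster
#' whose representative it matches at `identity >= threshold` (identity is
#' matches over alignment length, gaps counting as mismatches), otherwise it
#' founds a new cluster. Clustering is performed within each marker family
#' (cross-family identities between single-copy markers are far below any
#' useful threshold).
#'
#' @param markers data.frame with `protein_id`, `family`, `aa_seq` and any
#'   carrier columns (e.g. `bin_id`).
#' @param identity_threshold inclusive identity threshold (default 0.975).
#' @return data.frame `cluster_id`, `protein_id`, `representative`, plus the
#'   input columns.
#' @export
cluster_marker_proteins <- function(markers, identity_threshold = 0.975) {
  if (!nrow(markers)) {
    return(cbind(markers, data.frame(cluster_id = character(0),
                                     representative = character(0))))
  }
  out <- vector("list", length(unique(markers$family)))
  ci <- 0
  for (fam in sort(unique(markers$family))) {
    sub <- markers[markers$family == fam, , drop = FALSE]
    ord <- order(-nchar(sub$aa_seq), sub$protein_id)
    sub <- sub[ord, , drop = FALSE]
    # equal-length sequences (the common case) compare as rows of one
    # character matrix; mixed lengths fall back to pairwise alignment
    equal_len <- length(unique(nchar(sub$aa_seq))) == 1
    chmat <- if (equal_len) {
      matrix(unlist(strsplit(sub$aa_seq, "")), nrow = nrow(sub),
             byrow = TRUE)
    } else {
      NULL
    }
    reps <- integer(0)        # row indices of cluster representatives
    assign <- integer(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      hit <- 0L
      for (j in seq_along(reps)) {
        ident <- if (equal_len) {
          mean(chmat[i, ] == chmat[reps[j], ])
        } else {
          protein_identity(sub$aa_seq[i], sub$aa_seq[reps[j]])
        }
        if (ident >= identity_threshold) {
          hit <- j
          break
        }
      }
      if (hit == 0L) {
        reps <- c(reps, i)
        hit <- length(reps)
      }
      assign[i] <- hit
    }
    sub$cluster_id <- sprintf("f%02d_cl%03d", fam, assign)
    sub$representative <- sub$protein_id[reps][assign]
    out[[ci <- ci + 1]] <- sub
  }
  res <- do.call(rbind, out[seq_len(ci)])
  rownames(res) <- NULL
  res
}

#' Build the genome-link graph from shared marker clusters
#'
#' Nodes are genome bins; an undirected edge joins two bins with weight
#' equal to the number of marker clusters containing proteins from both.
#'
#' @param bin_ids character vector of all bin ids to include as nodes
#'   (isolated bins are kept as singleton nodes).
#' @param clusters clustered markers from [cluster_marker_proteins()] with a
#'   `bin_id` column.
#' @return an [igraph::graph] with integer `weight` edge attributes and no
#'   self-loops.
#' @export
build_link_graph <- function(bin_ids, clusters) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(bin_ids), name = bin_ids)
  if (nrow(clusters)) {
    pair_counts <- new.env(parent = emptyenv())
    for (cl in unique(clusters$cluster_id)) {
      bins <- unique(clusters$bin_id[clusters$cluster_id == cl])
      bins <- bins[!is.na(bins)]
      if (length(bins) < 2) next
      bins <- sort(bins)
      for (i in seq_len(length(bins) - 1)) {
        for (j in seq(i + 1, length(bins))) {
          key <- paste(bins[i], bins[j], sep = "\r")
          pair_counts[[key]] <- (pair_counts[[key]] %||% 0L) + 1L
        }
      }
    }
    keys <- ls(pair_counts)
    if (length(keys)) {
      parts <- strsplit(keys, "\r", fixed = TRUE)
      edges <- rbind(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2))
      g <- igraph::add_edges(g, as.vector(edges))
      igraph::E(g)$weight <- vapply(keys, function(k) pair_counts[[k]], 0L)
    }
  }
  g
}

#' Detect linked genome communities
#'
#' Greedy modularity maximization (fast-greedy) on the weighted link graph;
#' each community is one putative cross-sample genome. Isolated bins form
#' singleton communities. Communities containing more than one bin from the
#' same sample are reported as ambiguous (the automated counterpart of
#' manual inspection).
#'
#' @param graph link graph from [build_link_graph()].
#' @param bin_samples optional named character vector bin_id -> sample_id
#'   used for the ambiguity report.
#' @return list with `membership` (named integer vector), `communities`
#'   (list of bin-id vectors) and `ambiguous` (indices of communities with
#'   >1 bin from one sample).
#' @export
detect_communities <- function(graph, bin_samples = NULL) {
  w <- if (igraph::ecount(graph)) igraph::E(graph)$weight else NULL
  fg <- igraph::cluster_fast_greedy(graph, weights = w)
  membership <- igraph::membership(fg)
  # the greedy cut can score below even the trivial one-community
  # partition (e.g. on a clique); never return a worse partition
  if (igraph::ecount(graph)) {
    single <- setNames(rep(1L, igraph::vcount(graph)),
                       igraph::V(graph)$name)
    if (igraph::modularity(graph, membership, weights = w) <
        igraph::modularity(graph, single, weights = w)) {
      membership <- single
    }
  }
  comm <- split(names(membership), as.integer(membership))
  ambiguous <- integer(0)
  if (!is.null(bin_samples)) {
    ambiguous <- which(vapply(comm, function(b) {
      anyDuplicated(bin_samples[b]) > 0
    }, TRUE))
  }
  list(membership = membership, communities = unname(comm),
       ambiguous = ambiguous)
}

# Contamination-aware bin refinement. Single-copy marker families should
# occur once per genome bin; a bin in which several families each carry two
# markers falling into *different* identity clusters is a composite of two
# populations (a chimera from overlapping composition clusters). Such bins
# are split by marker evidence: communities are first detected on the
# unambiguous bins, each marker cluster is mapped to its majority
# community, and the chimeric bin's contigs follow their markers'
# communities (marker-less contigs follow the largest split group).
split_chimeric_bins <- function(bins, markers, contigs,
                                min_dup_families = 3) {
  dup_count <- function(b) {
    mk <- markers[markers$bin_id == b, , drop = FALSE]
    if (!nrow(mk)) return(0L)
    sum(tapply(mk$cluster_id, mk$family,
               function(x) length(unique(x))) >= 2, na.rm = TRUE)
  }
  chim <- names(bins)[vapply(names(bins), dup_count, 0L) >=
                        min_dup_families]
  if (!length(chim)) return(list(bins = bins, markers = markers))
  clean <- setdiff(names(bins), chim)
  clean_mk <- markers[markers$bin_id %in% clean, , drop = FALSE]
  memb <- detect_communities(build_link_graph(clean, clean_mk))$membership
  cl_comm <- tapply(clean_mk$bin_id, clean_mk$cluster_id, function(bs) {
    as.integer(names(sort(table(memb[bs]), decreasing = TRUE))[1])
  })
  len_of <- setNames(contigs$length, contigs$contig_id)
  for (b in chim) {
    bin <- bins[[b]]
    mk <- markers[markers$bin_id == b, , drop = FALSE]
    contig_comm <- vapply(unique(mk$contig_id), function(ct) {
      cc <- cl_comm[mk$cluster_id[mk$contig_id == ct]]
      cc <- cc[!is.na(cc)]
      if (!length(cc)) NA_integer_ else
        as.integer(names(sort(table(cc), decreasing = TRUE))[1])
    }, 0L)
    groups <- split(names(contig_comm), contig_comm)  # drops NA keys
    if (length(groups) < 2) next                      # nothing to split
    stray <- setdiff(bin$members, names(contig_comm)[!is.na(contig_comm)])
    glens <- vapply(groups, function(m) sum(len_of[m]), 0)
    groups[[which.max(glens)]] <- c(groups[[which.max(glens)]], stray)
    bins[[b]] <- NULL
    markers <- markers[markers$bin_id != b, , drop = FALSE]
    for (k in seq_along(groups)) {
      nb <- bin
      nb$bin_id <- sprintf("%s.%d", bin$bin_id, k)
      nb$members <- groups[[k]]
      nb$total_length <- sum(len_of[groups[[k]]])
      nb$median_coverage <- median(
        contigs$coverage[match(groups[[k]], contigs$contig_id)]
      )
      bins[[nb$bin_id]] <- nb
      sel <- mk$contig_id %in% groups[[k]]
      if (any(sel)) {
        add <- mk[sel, , drop = FALSE]
        add$bin_id <- nb$bin_id
        markers <- rbind(markers, add)
      }
    }
  }
  list(bins = bins, markers = markers)
}

#' Bin and link all samples of a curated contig table
#'
#' Runs [bin_sample()] per sample, attaches marker hits and completeness,
#' clusters all marker proteins, splits bins whose duplicated single-copy
#' families reveal them as composites of two populations, and detects
#' cross-sample genome communities on the global link graph. For the
#' within-pair linking of the original workflow, restrict `contigs` to one
#' mother-neonate pair.
#'
#' @param contigs curated contig table (several samples).
#' @param contig_markers marker hits (`contig_id`, `family`, `protein_id`,
#'   `aa_seq`).
#' @param n_families marker catalogue size.
#' @param identity_threshold marker clustering identity.
#' @param min_bin_length,min_points passed to [bin_sample()].
#' @return list with `bins`, `markers` (clustered, with `bin_id`), `graph`,
#'   `communities`.
#' @export
link_genomes <- function(contigs, contig_markers, n_families = 35,
                         identity_threshold = 0.975,
                         min_bin_length = 1e5, min_points = 3) {
  bins <- list()
  for (sid in unique(contigs$sample_id)) {
    sb <- bin_sample(contigs[contigs$sample_id == sid, , drop = FALSE],
                     min_points = min_points,
                     min_bin_length = min_bin_length)
    bins <- c(bins, sb)
  }
  names(bins) <- vapply(bins, `[[`, "", "bin_id")
  for (i in seq_along(bins)) {
    bins[[i]]$completeness <- estimate_completeness(bins[[i]],
                                                    contig_markers,
                                                    n_families)
  }
  # markers of binned contigs, tagged with their bin
  contig_bin <- setNames(
    rep(names(bins), vapply(bins, function(b) length(b$members), 0L)),
    unlist(lapply(bins, `[[`, "members"))
  )
  mk <- contig_markers[contig_markers$contig_id %in% names(contig_bin), ,
                       drop = FALSE]
  mk$bin_id <- unname(contig_bin[mk$contig_id])
  clustered <- cluster_marker_proteins(mk, identity_threshold)
  refined <- split_chimeric_bins(bins, clustered, contigs)
  bins <- refined$bins
  clustered <- refined$markers
  for (i in seq_along(bins)) {
    bins[[i]]$completeness <- estimate_completeness(bins[[i]],
                                                    contig_markers,
                                                    n_families)
  }
  graph <- build_link_graph(names(bins), clustered)
  comm <- detect_communities(
    graph,
    bin_samples = vapply(bins, `[[`, "", "sample_id")
  )
  list(bins = bins, markers = clustered, graph = graph, communities = comm)
}
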