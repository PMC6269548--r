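#' p-distance between two marker sequences
#'
#' Fraction of aligned positions that differ. Equal-length sequences are
#' compared position-wise; unequal-length sequences are globally aligned
#' first. Positions where either sequence has a gap are excluded from both
#' numerator and denominator.
#'
#' @param seq_a,seq_b character sequences (amino-acid or nucleotide).
#' @return p-distance in `[0, 1]`.
#' @export
marker_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) == nchar(seq_b)) {
    ca <- strsplit(seq_a, "")[[1]]
    cb <- strsplit(seq_b, "")[[1]]
    keep <- ca != "-" & cb != "-"
    if (!any(keep)) stop("no overlapping aligned positions")
    return(sum(ca[keep] != cb[keep]) / sum(keep))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", gapOpening = 10, gapExtension = 0.5
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- pa != "-" & ps != "-"
  if (!any(keep)) stop("no overlapping aligned positions")
  sum(pa[keep] != ps[keep]) / sum(keep)
}

# Distance between two marker repertoires (named family -> sequence):
# total mismatches over total compared sites across shared families.
# NA when no family is shared. Repertoires may be pre-split (lists of
# character vectors) to avoid repeated strsplit calls.
repertoire_distance <- function(rep_a, rep_b) {
  fams <- intersect(names(rep_a), names(rep_b))
  if (!length(fams)) return(NA_real_)
  mism <- 0
  sites <- 0
  for (f in fams) {
    a <- rep_a[[f]]
    b <- rep_b[[f]]
    if (length(a) == 1) a <- strsplit(a, "")[[1]]
    if (length(b) == 1) b <- strsplit(b, "")[[1]]
    n <- min(length(a), length(b))
    mism <- mism + sum(a[seq_len(n)] != b[seq_len(n)])
    sites <- sites + n
  }
  mism / sites
}

# Pre-split a repertoire's sequences into character vectors.
split_repertoire <- function(rep) {
  lapply(rep, function(s) strsplit(s, "")[[1]])
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour-joining with deterministic input ordering. Negative
#' branch lengths (which NJ can produce on non-additive matrices) are
#' clamped to zero with the deficit moved to the sister branch, preserving
#' path lengths through the parent node.
#'
#' @param d symmetric numeric matrix with zero diagonal and >= 3 labels.
#' @return an [ape::phylo] tree.
#' @export
build_nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 labels")
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  tree <- ape::nj(stats::as.dist(d))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sisters <- which(tree$edge[, 1] == parent)
    sisters <- setdiff(sisters, e)
    if (length(sisters)) {
      tree$edge.length[sisters[1]] <- tree$edge.length[sisters[1]] + deficit
    }
  }
  tree
}

#' Cophenetic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' leaves i and j.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return symmetric matrix with row/column names equal to the leaf labels.
#' @export
cophenetic_matrix <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Call mother-to-neonate strain sharing
#'
#' A neonate shares a strain with its mother when the cophenetic distance
#' between the neonatal and maternal markers is strictly less than the
#' distance to the markers of any other individual; ties are called not
#' shared. When an individual contributes several samples (or bins), the
#' minimum distance over that individual's labels represents the individual.
#'
#' @param coph cophenetic (or direct) distance matrix with all labels.
#' @param neonate_labels labels belonging to the neonate.
#' @param mother_labels labels belonging to the mother.
#' @param other_individuals named list: individual id -> its labels. Must be
#'   non-empty (the criterion is undefined without other individuals).
#' @param evidence `"genome_based"` or `"read_based"` (recorded on the
#'   call).
#' @return object of class `sharing_call`: list with `shared`,
#'   `mother_distance`, `min_other_distance`, `margin`
#'   (`min_other - mother`), `nearest_other`, `evidence`.
#' @export
call_strain_sharing <- function(coph, neonate_labels, mother_labels,
                                other_individuals,
                                evidence = "genome_based") {
  labs <- rownames(coph)
  need <- c(neonate_labels, mother_labels, unlist(other_individuals))
  if (!all(need %in% labs)) {
    stop("labels missing from the distance matrix: ",
         paste(setdiff(need, labs), collapse = ", "))
  }
  if (!length(other_individuals)) {
    stop("sharing criterion undefined without other individuals")
  }
  d_mother <- min(coph[neonate_labels, mother_labels, drop = FALSE])
  d_other <- vapply(other_individuals, function(l) {
    min(coph[neonate_labels, l, drop = FALSE])
  }, 0)
  min_other <- min(d_other)
  structure(
    list(shared = d_mother < min_other,
         mother_distance = d_mother,
         min_other_distance = min_other,
         margin = min_other - d_mother,
         nearest_other = names(d_other)[which.min(d_other)],
         evidence = evidence),
    class = "sharing_call"
  )
}

#' @export
print.sharing_call <- function(x, ...) {
  cat(sprintf("sharing_call: %s (mother %.4g vs nearest other %.4g, margin %.4g, %s)\n",
              if (x$shared) "SHARED" else "not shared",
              x$mother_distance, x$min_other_distance, x$margin, x$evidence))
  invisible(x)
}

# Marker repertoire of one bin: named family -> one amino-acid sequence
# (deterministically the lexicographically first protein per family).
bin_repertoire <- function(bin, markers) {
  mk <- markers[markers$bin_id %in% bin$bin_id, , drop = FALSE]
  mk <- mk[order(mk$family, mk$protein_id), , drop = FALSE]
  mk <- mk[!duplicated(mk$family), , drop = FALSE]
  setNames(as.list(mk$aa_seq), as.character(mk$family))
}

#' Strain-sharing analysis over linked genome communities
#'
#' For each genome community (clade) from [link_genomes()], builds a
#' distance matrix from concatenated shared-family marker distances, a
#' neighbour-joining tree and its cophenetic matrix, and calls
#' mother-to-neonate sharing for every pair represented in the clade.
#'
#' Two evidence modes: `genome_based` uses one marker repertoire per genome
#' bin; `read_based` pools all of a clade's markers per sample (including
#' markers on unbinned contigs), one repertoire per sample, mirroring the
#' distinction between reconstructed-genome-based and read-based marker
#' evidence.
#'
#' @param link result of [link_genomes()].
#' @param samples sample metadata (`sample_id`, `individual_id`, `pair_id`,
#'   `role`).
#' @param contig_markers full marker table (used in `read_based` mode to
#'   recover markers on unbinned contigs).
#' @param evidence `"genome_based"` (default) or `"read_based"`.
#' @return data.frame of calls: `pair_id`, `clade`, `shared`, `evidence`,
#'   `margin`, `mother_distance`, `min_other_distance`.
#' @export
strain_sharing_analysis <- function(link, samples,
                                    contig_markers = NULL,
                                    evidence = c("genome_based",
                                                 "read_based")) {
  evidence <- match.arg(evidence)
  comm <- link$communities$communities
  bins <- link$bins
  ind_of_sample <- setNames(samples$individual_id, samples$sample_id)
  role_of_ind <- setNames(samples$role, samples$individual_id)
  pair_of_ind <- setNames(samples$pair_id, samples$individual_id)
  calls <- list()
  for (ci in seq_along(comm)) {
    members <- comm[[ci]]
    if (evidence == "genome_based") {
      reps <- lapply(members, function(b) bin_repertoire(bins[[b]],
                                                         link$markers))
      names(reps) <- members
      entity_ind <- vapply(members, function(b) {
        unname(ind_of_sample[bins[[b]]$sample_id])
      }, "")
    } else {
      if (is.null(contig_markers)) {
        stop("read_based evidence requires contig_markers")
      }
      # clusters belonging to this community: clusters whose bin members
      # mostly sit in this community
      cl_comm <- tapply(link$markers$bin_id, link$markers$cluster_id,
                        function(b) {
                          m <- link$communities$membership[b]
                          as.integer(names(sort(table(m),
                                                decreasing = TRUE))[1])
                        })
      clade_clusters <- names(cl_comm)[cl_comm == ci]
      mk <- link$markers[link$markers$cluster_id %in% clade_clusters, ,
                         drop = FALSE]
      # pull equivalent unbinned markers by protein identity of cluster
      # representatives is out of reach without re-clustering; pool by
      # sample over the clade's clustered markers
      pooled <- split(mk, mk$sample_id)
      reps <- lapply(pooled, function(m) {
        m <- m[order(m$family, m$protein_id), , drop = FALSE]
        m <- m[!duplicated(m$family), , drop = FALSE]
        setNames(as.list(m$aa_seq), as.character(m$family))
      })
      members <- names(reps)
      entity_ind <- unname(ind_of_sample[members])
      names(reps) <- members
    }
    if (length(members) < 3) next
    n <- length(members)
    reps <- lapply(reps, split_repertoire)
    d <- matrix(0, n, n, dimnames = list(members, members))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- repertoire_distance(reps[[i]], reps[[j]])
      }
    }
    if (anyNA(d)) {
      mx <- max(d, na.rm = TRUE)
      d[is.na(d)] <- mx * 1.5 + 1e-6  # disjoint repertoires: push apart
    }
    tree <- build_nj_tree(d)
    coph <- cophenetic_matrix(tree)
    inds <- unique(entity_ind)
    neonate_inds <- inds[role_of_ind[inds] == "neonate"]
    for (ni in neonate_inds) {
      pid <- pair_of_ind[ni]
      mother_ind <- samples$individual_id[samples$pair_id == pid &
                                          samples$role == "mother"][1]
      if (is.na(mother_ind) || !(mother_ind %in% inds)) next
      others <- setdiff(inds, c(ni, mother_ind))
      if (!length(others)) next
      other_labels <- lapply(others, function(o) {
        members[entity_ind == o]
      })
      names(other_labels) <- others
      call <- call_strain_sharing(
        coph,
        neonate_labels = members[entity_ind == ni],
        mother_labels = members[entity_ind == mother_ind],
        other_individuals = other_labels,
        evidence = evidence
      )
      calls[[length(calls) + 1]] <- data.frame(
        pair_id = unname(pid), clade = ci, shared = call$shared,
        evidence = evidence, margin = call$margin,
        mother_distance = call$mother_distance,
        min_other_distance = call$min_other_distance,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, calls) %||%
    data.frame(pair_id = character(0), clade = integer(0),
               shared = logical(0), evidence = character(0),
               margin = numeric(0), mother_distance = numeric(0),
               min_other_distance = numeric(0))
  rownames(res) <- NULL
  res
}

#' Map genome communities to ground-truth genomes
#'
#' Evaluation helper: assigns each community the source genome carried by
#' the majority of its member contigs.
#'
#' @param link result of [link_genomes()].
#' @param contig_sources truth table (`contig_id`, `genome_id`).
#' @return character vector, one genome id (or `NA`) per community.
#' @export
community_truth_genome <- function(link, contig_sources) {
  src <- setNames(contig_sources$genome_id, contig_sources$contig_id)
  vapply(link$communities$communities, function(members) {
    contigs <- unlist(lapply(members, function(b) link$bins[[b]]$members))
    g <- src[contigs]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_character_)
    names(sort(table(g), decreasing = TRUE))[1]
  }, "")
}
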