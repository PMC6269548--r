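#' @importFrom stats complete.cases cor dist fisher.test mad median na.omit
#'   p.adjust phyper prcomp quantile rbeta rbinom rlnorm rmultinom rnorm
#'   rpois runif setNames wilcox.test cophenetic plogis qlogis
#' @importFrom utils head read.delim write.table packageVersion
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions do not disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed from a base seed and a character tag.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435 + h * 97 + 1) %% 2147483629)
}

# Random DNA string of length n with the given GC fraction (iid model).
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_ALPHABET, n, replace = TRUE, prob = p), collapse = "")
}

# Random DNA via an order-1 Markov chain. `trans` is a 4x4 row-stochastic
# matrix over A,C,G,T. Genome-specific transition biases give each genome a
# distinct oligonucleotide signature, which is what composition-based
# binning exploits in real assemblies.
random_dna_markov <- function(n, trans) {
  stopifnot(nrow(trans) == 4, ncol(trans) == 4)
  cum <- t(apply(trans, 1, cumsum))
  s <- integer(n)
  s[1] <- sample.int(4, 1)
  u <- runif(n)
  for (i in 2:n) {
    s[i] <- findInterval(u[i], cum[s[i - 1], ]) + 1L
  }
  paste(DNA_ALPHABET[s], collapse = "")
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# Substitute characters of `x` at `positions` (1-based) with random symbols
# from `alphabet` different from the original. Returns the new string and the
# substitution table.
substitute_sites <- function(x, positions, alphabet = DNA_ALPHABET) {
  chars <- strsplit(x, "")[[1]]
  old <- chars[positions]
  new <- vapply(old, function(b) sample(setdiff(alphabet, b), 1), "")
  chars[positions] <- new
  list(
    sequence = paste(chars, collapse = ""),
    substitutions = data.frame(
      position = positions, ref = old, alt = unname(new),
      stringsAsFactors = FALSE
    )
  )
}

# Reverse-complement for plain character vectors of DNA strings.
revcomp_chr <- function(x) {
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

# Canonical k-mer set of one sequence: each k-mer is represented by the
# lexicographic minimum of itself and its reverse complement.
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  km <- substring(seq, starts, starts + k - 1L)
  rc <- revcomp_chr(km)
  unique(ifelse(km <= rc, km, rc))
}

#' Density-based clustering (DBSCAN)
#'
#' Plain O(n^2) DBSCAN on a coordinate matrix. Written in-package because no
#' DBSCAN implementation ships with the supported dependency set; the
#' problem sizes here (hundreds of contigs) do not need an index structure.
#'
#' @param x numeric matrix, one row per point.
#' @param eps neighbourhood radius (> 0).
#' @param min_points minimum number of points (including the point itself)
#'   in an eps-ball for a core point.
#' @return integer vector of cluster labels, 0 = noise.
#' @export
dbscan_cluster <- function(x, eps, min_points = 5) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (eps <= 0) stop("eps must be > 0")
  n <- nrow(x)
  d <- as.matrix(dist(x))
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  is_core <- vapply(neighbours, length, 0L) >= min_points
  labels <- integer(n) # 0 = unvisited/noise
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    cluster <- cluster + 1L
    queue <- i
    labels[i] <- cluster
    while (length(queue) > 0) {
      p <- queue[1]
      queue <- queue[-1]
      for (q in neighbours[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cluster
          if (is_core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# 95th percentile of k-nearest-neighbour distances; the default eps
# heuristic for the binning stages.
knn_dist_quantile <- function(x, k = 4, prob = 0.95) {
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- nrow(x)
  if (n <= k) return(max(dist(x)) + 1e-9)
  d <- as.matrix(dist(x))
  knn <- apply(d, 1, function(r) sort(r)[k + 1L]) # +1: self at distance 0
  as.numeric(quantile(knn, prob))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
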