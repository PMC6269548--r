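# Internal generator utilities used to build fixtures in code.
with_seed <- strainrelay:::with_seed
random_dna <- strainrelay:::random_dna
random_protein <- strainrelay:::random_protein

# Independent brute-force oracles used by the unit and acceptance tests.
# These enumerate the underlying definitions directly and never call the
# package's own estimators.

# Nucleotide diversity of one pileup column by explicit read-pair
# enumeration. counts: named integer vector over A,C,G,T.
oracle_column_pi <- function(counts, mode) {
  reads <- rep(names(counts), counts)
  n <- length(reads)
  diff_pairs <- 0
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (mode == "plugin") {
        # with replacement: all ordered pairs including i == j
        total <- total + 1
        if (reads[i] != reads[j]) diff_pairs <- diff_pairs + 1
      } else if (i != j) {
        total <- total + 1
        if (reads[i] != reads[j]) diff_pairs <- diff_pairs + 1
      }
    }
  }
  diff_pairs / total
}

# Upper-tail hypergeometric probability P(X >= ov) by direct summation of
# the counting formula.
oracle_hyper_upper <- function(ov, m, N, k) {
  js <- ov:min(m, k)
  sum(choose(m, js) * choose(N - m, k - js)) / choose(N, k)
}

# Two-sided Fisher exact p by enumerating every 2x2 table with the observed
# margins and summing the probabilities not exceeding the observed table's
# (with the standard relative guard against floating-point ties).
oracle_fisher_two_sided <- function(a, b, cc, d) {
  r1 <- a + b
  r2 <- cc + d
  c1 <- a + cc
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  }, 0)
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# All set partitions of 1..n as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (b in seq_len(k + 1)) rec(c(assign, b), max(k, b))
  }
  rec(integer(0), 0)
  out
}

# Maximum modularity over all partitions of a (small) weighted graph.
oracle_max_modularity <- function(graph) {
  n <- igraph::vcount(graph)
  best <- -Inf
  for (p in all_partitions(n)) {
    m <- igraph::modularity(graph, p,
                            weights = if (igraph::ecount(graph))
                              igraph::E(graph)$weight else NULL)
    if (m > best) best <- m
  }
  best
}

# Small cohort configuration for fast module-level tests.
small_config <- function(seed = 1, genome_length = 15000, ...) {
  cohort_config(
    n_pairs_per_group = c(VD = 2, CSD = 1, CSD_SGA = 1),
    n_genomes = 8,
    class_counts = c(enteric_gramneg = 3, enteric_grampos = 2,
                     skin_firmicute = 1, contaminant = 2),
    genome_length = genome_length,
    seed = seed, ...
  )
}
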