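mk_pileup <- function(counts, pos = NULL, genome_length = 1000L) {
  cnt <- matrix(as.integer(counts), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  if (is.null(pos)) pos <- seq_len(nrow(cnt)) - 1L
  strainrelay:::new_pileup("g", "s", as.integer(pos), cnt, genome_length)
}

test_that("genome-sample qualification applies the three gates", {
  s <- function(med, br, cmp) {
    list(genome_id = "g", sample_id = "s", median_depth = med,
         breadth = br, completeness = cmp)
  }
  expect_false(qualify_genome_sample(s(19, 0.50, 0.8))$include)
  expect_identical(qualify_genome_sample(s(19, 0.50, 0.8))$reasons,
                   "coverage")
  expect_false(qualify_genome_sample(s(25, 0.39, 0.8))$include)
  expect_identical(qualify_genome_sample(s(25, 0.39, 0.8))$reasons,
                   "breadth")
  expect_true(qualify_genome_sample(s(25, 0.50, 0.70))$include)
  expect_true(qualify_genome_sample(s(20, 0.40, 0.66))$include)
  # completeness gate is strict; 22/35 fails, 23/35 passes
  expect_false(qualify_genome_sample(s(25, 0.50, 22 / 35))$include)
  expect_true(qualify_genome_sample(s(25, 0.50, 23 / 35))$include)
  multi <- qualify_genome_sample(s(10, 0.2, 0.5))
  expect_setequal(multi$reasons, c("coverage", "breadth", "completeness"))
})

test_that("downsampling thins to the target median and drops empty columns", {
  cons <- with_seed(1, random_dna(1000, 0.5))
  empty_poly <- data.frame(pos = integer(0), alt = character(0),
                           freq = numeric(0))
  p20 <- with_seed(2, simulate_pileup("g", "s", cons, empty_poly, 20))
  expect_identical(downsample_to_median(p20, target = 20, seed = 1), p20)
  p40 <- with_seed(3, simulate_pileup("g", "s", cons, empty_poly, 40))
  meds <- vapply(1:200, function(s) {
    median(rowSums(downsample_to_median(p40, target = 20, seed = s)$counts))
  }, 0)
  expect_lt(abs(mean(meds) - 20), 1)
  # a depth-1 column with thinning probability 1/2 vanishes about half the time
  one <- mk_pileup(matrix(c(1L, 0L, 0L, 0L), 1))
  # median is 1, so force thinning via a 0.5-probability construction:
  # two columns with depths 1 and 3 -> median 2, p = 1/2 at target 1
  two <- mk_pileup(rbind(c(1, 0, 0, 0), c(0, 3, 0, 0)))
  dropped <- vapply(1:400, function(s) {
    ds <- downsample_to_median(two, target = 1, seed = s)
    !(0L %in% ds$pos)
  }, TRUE)
  expect_lt(abs(mean(dropped) - 0.5), 0.08)
  expect_error(downsample_to_median(one, target = 0), "target")
})

test_that("SNV filters honour the inclusive support and frequency bounds", {
  # support 3 < 4: monomorphic
  expect_identical(nrow(call_snvs(mk_pileup(c(96, 3, 0, 0)))), 0L)
  # frequency 0.5% < 1%: monomorphic
  expect_identical(nrow(call_snvs(mk_pileup(c(995, 5, 0, 0)))), 0L)
  # support 4 and frequency 4%: retained (both bounds inclusive)
  snv <- call_snvs(mk_pileup(c(96, 4, 0, 0)))
  expect_identical(nrow(snv), 1L)
  expect_identical(snv$allele, "C")
  expect_identical(snv$major, "A")
  expect_equal(snv$freq, 0.04)
  # exactly 1% with support >= 4: retained
  expect_identical(nrow(call_snvs(mk_pileup(c(396, 4, 0, 0)))), 1L)
})

test_that("locus intersection is a plain set intersection", {
  pa <- mk_pileup(matrix(rep(c(10L, 0L, 0L, 0L), 100), ncol = 4,
                         byrow = TRUE), pos = 0:99)
  pb <- mk_pileup(matrix(rep(c(10L, 0L, 0L, 0L), 100), ncol = 4,
                         byrow = TRUE), pos = 50:149)
  expect_identical(intersect_loci(list(pa, pb)), 50:99)
  expect_identical(intersect_loci(list(pa, pa)), 0:99)
  pc <- mk_pileup(matrix(rep(c(10L, 0L, 0L, 0L), 10), ncol = 4,
                         byrow = TRUE), pos = 200:209)
  expect_error(intersect_loci(list(pa, pc)), "skipped")
})

test_that("pi matches hand-computed cases", {
  # {A:2, C:2}: plugin 0.5, unbiased 2/3
  p <- mk_pileup(c(2, 2, 0, 0))
  expect_equal(compute_pi(p, mode = "plugin"), 0.5)
  expect_equal(compute_pi(p, mode = "unbiased"), 2 / 3)
  # loci {A:3,G:1} and {A:4}: plugin mean (0.375 + 0) / 2
  p2 <- mk_pileup(rbind(c(3, 0, 1, 0), c(4, 0, 0, 0)))
  expect_equal(compute_pi(p2, mode = "plugin"), 0.1875)
})

test_that("pi equals exhaustive read-pair enumeration on random columns", {
  set.seed(7)
  for (rep in 1:40) {
    n_loci <- sample(1:10, 1)
    cnt <- t(vapply(seq_len(n_loci), function(i) {
      x <- as.integer(rmultinom(1, sample(2:20, 1), runif(4)))
      x
    }, integer(4)))
    p <- mk_pileup(cnt)
    for (mode in c("plugin", "unbiased")) {
      oracle <- mean(vapply(seq_len(n_loci), function(l) {
        oracle_column_pi(setNames(cnt[l, ], c("A", "C", "G", "T")), mode)
      }, 0))
      expect_lt(abs(compute_pi(p, mode = mode) - oracle), 1e-12)
    }
  }
})

test_that("pi is invariant to allele labels and locus order, monotone in monomorphic padding", {
  cnt <- rbind(c(5, 3, 0, 0), c(2, 2, 2, 0), c(9, 1, 0, 0))
  p <- mk_pileup(cnt)
  relabeled <- mk_pileup(cnt[, c(3, 4, 1, 2)])
  expect_equal(compute_pi(p), compute_pi(relabeled))
  shuffled <- mk_pileup(cnt[c(3, 1, 2), ], pos = c(0L, 1L, 2L))
  expect_equal(compute_pi(p), compute_pi(shuffled))
  padded <- mk_pileup(rbind(cnt, c(10, 0, 0, 0)))
  expect_lt(compute_pi(padded), compute_pi(p))
})

test_that("F_ST reproduces its closed-form cases", {
  # identical allele counts: plugin F_ST is exactly 0
  a <- mk_pileup(rbind(c(6, 2, 0, 0), c(5, 0, 5, 0)))
  r0 <- compute_fst(a, a, loci = a$pos, mode = "plugin")
  expect_equal(r0$fst, 0)
  # fixed difference: F_ST = 1
  f1 <- mk_pileup(c(10, 0, 0, 0))
  f2 <- mk_pileup(c(0, 10, 0, 0))
  expect_equal(compute_fst(f1, f2, loci = 0L)$fst, 1)
  # worked example {A:3,C:1} vs {A:1,C:3} -> 0.4 exactly
  w1 <- mk_pileup(c(3, 1, 0, 0))
  w2 <- mk_pileup(c(1, 3, 0, 0))
  r <- compute_fst(w1, w2, loci = 0L)
  expect_equal(r$fst, 0.4, tolerance = 1e-12)
  expect_equal(r$pi_intra, c(0.375, 0.375))
  expect_equal(r$pi_between, 0.625)
  # symmetry
  expect_equal(compute_fst(w1, w2, loci = 0L)$fst,
               compute_fst(w2, w1, loci = 0L)$fst)
})

test_that("one-locus F_ST increases monotonically with frequency divergence", {
  fst_at <- function(delta) {
    n <- 1000L
    f1 <- 0.5 - delta / 2
    f2 <- 0.5 + delta / 2
    p1 <- mk_pileup(c(round(n * f1), n - round(n * f1), 0, 0))
    p2 <- mk_pileup(c(round(n * f2), n - round(n * f2), 0, 0))
    compute_fst(p1, p2, loci = 0L)$fst
  }
  path <- vapply(seq(0, 0.9, by = 0.1), fst_at, 0)
  expect_true(all(diff(path) > 0))
})

test_that("estimated pi recovers the generator's truth at depth 100", {
  errs <- vapply(1:20, function(s) {
    with_seed(s, {
      L <- 1000L
      cons <- random_dna(L, 0.5)
      n_poly <- 30L
      pos <- sort(sample(L, n_poly))
      alt <- vapply(substring(cons, pos, pos), function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, "")
      freq <- pmin(rbeta(n_poly, 1.5, 8), 0.5)
      poly <- data.frame(pos = pos, alt = unname(alt), freq = freq)
      true_pi <- sum(2 * freq * (1 - freq)) / L
      p <- simulate_pileup("g", "s", cons, poly, 100)
      est <- compute_pi(p, mode = "plugin")
      c(abs(est - true_pi), 0.1 * true_pi + 0.002)
    })
  }, c(0, 0))
  expect_true(all(errs[1, ] <= errs[2, ]))
})
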