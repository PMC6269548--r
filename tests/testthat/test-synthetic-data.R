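test_that("cohort generation is deterministic for a fixed configuration", {
  cfg <- small_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("configuration invariants are validated with the field named", {
  expect_error(cohort_config(genome_length = 5000), "genome_length")
  expect_error(cohort_config(days = c(3, 1)), "days")
  expect_error(cohort_config(gc_by_class = c(
    enteric_gramneg = 0.4, enteric_grampos = 0.5,
    skin_firmicute = 1.2, contaminant = 0.6
  )), "gc_by_class")
  tp <- default_transmission_prob()
  tp["VD", 1] <- 1.5
  expect_error(cohort_config(transmission_prob = tp), "transmission_prob")
  expect_error(cohort_config(n_genomes = 5), "class_counts")
})

test_that("certain transmission puts every Gram-negative genome in the truth", {
  tp <- default_transmission_prob()
  tp["VD", "enteric_gramneg"] <- 1
  co <- generate_cohort(small_config(seed = 2, transmission_prob = tp),
                        contigs = FALSE, pileups = FALSE)
  gneg <- co$genomes$genome_id[co$genomes$class == "enteric_gramneg"]
  vd_pairs <- unique(co$samples$pair_id[
    co$samples$group == "VD" & !is.na(co$samples$group)])
  for (p in vd_pairs) {
    got <- co$truth$transmitted$genome_id[co$truth$transmitted$pair_id == p]
    expect_true(all(gneg %in% got))
  }
})

test_that("zero contaminant load leaves no contaminant contigs in study samples", {
  co <- generate_cohort(small_config(seed = 3, contaminant_load = 0),
                        pileups = FALSE)
  expect_length(co$truth$contaminant_contigs, 0)
})

test_that("mutate_strain matches its substitution list and boundary rates", {
  ref <- with_seed(1, random_dna(2000, 0.5))
  r0 <- mutate_strain(ref, 0, seed = 5)
  expect_identical(r0$sequence, ref)
  expect_identical(nrow(r0$substitutions), 0L)
  r1 <- mutate_strain(ref, 1, seed = 5)
  expect_true(all(strsplit(r1$sequence, "")[[1]] !=
                  strsplit(ref, "")[[1]]))
  # returned list equals the diff of the sequences
  rm <- mutate_strain(ref, 0.02, seed = 9)
  ca <- strsplit(ref, "")[[1]]
  cb <- strsplit(rm$sequence, "")[[1]]
  expect_identical(which(ca != cb), as.integer(rm$substitutions$position))
  expect_identical(ca[rm$substitutions$position], rm$substitutions$ref)
  expect_identical(cb[rm$substitutions$position], rm$substitutions$alt)
  expect_error(mutate_strain("ACGN", 0.1), "A, C, G, T")
  expect_error(mutate_strain(ref, 1.2), "rate")
})

test_that("substitution counts follow the binomial model", {
  ref <- with_seed(42, random_dna(10000, 0.5))
  n_subs <- vapply(1:200, function(s) {
    nrow(mutate_strain(ref, 0.01, seed = s)$substitutions)
  }, 0)
  # binomial mean 100, sd sqrt(99); the mean of 200 draws sits comfortably
  # within a 3-sd band for single draws
  expect_lt(abs(mean(n_subs) - 100), 3 * sqrt(99))
})

test_that("emitted contigs are substrings of their source genomes", {
  co <- generate_cohort(small_config(seed = 4), pileups = FALSE)
  src <- co$truth$contig_sources
  idx <- match(src$contig_id, co$contigs$contig_id)
  for (i in sample(nrow(src), 50)) {
    sm <- co$samples[co$samples$sample_id == src$sample_id[i], ]
    genome_seq <- strainrelay:::strain_sequence(co, src$genome_id[i],
                                                sm$individual_id)
    expect_identical(co$contigs$sequence[idx[i]],
                     substring(genome_seq, src$start[i], src$end[i]))
  }
  expect_true(all(co$contigs$length >= 500))
  ctrl_src <- src$genome_id[src$sample_id == "CTRL"]
  contam <- co$genomes$genome_id[co$genomes$class == "contaminant"]
  expect_true(all(ctrl_src %in% contam))
})

test_that("contig FASTA bytes are reproducible for a fixed seed", {
  co <- generate_cohort(small_config(seed = 5), pileups = FALSE)
  d1 <- file.path(tempdir(), "fasta1")
  d2 <- file.path(tempdir(), "fasta2")
  write_contig_fasta(co$contigs, d1)
  co2 <- generate_cohort(small_config(seed = 5), pileups = FALSE)
  write_contig_fasta(co2$contigs, d2)
  f <- list.files(d1)
  expect_identical(
    lapply(file.path(d1, f), readLines),
    lapply(file.path(d2, f), readLines)
  )
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("pileup depth follows the Poisson coverage model", {
  cons <- with_seed(7, random_dna(1000, 0.5))
  empty_poly <- data.frame(pos = integer(0), alt = character(0),
                           freq = numeric(0))
  # depth 0: empty pileup, breadth 0
  p0 <- with_seed(1, simulate_pileup("g", "s", cons, empty_poly, 0))
  expect_length(p0$pos, 0)
  # monomorphic truth: single-allele columns only
  p1 <- with_seed(1, simulate_pileup("g", "s", cons, empty_poly, 30))
  expect_true(all(rowSums(p1$counts > 0) == 1))
  # realized median depth near the mean for most seeds
  meds <- vapply(1:100, function(s) {
    p <- with_seed(s, simulate_pileup("g", "s", cons, empty_poly, 50))
    median(rowSums(p$counts))
  }, 0)
  expect_gte(mean(meds >= 40 & meds <= 60), 0.95)
})

test_that("empirical allele frequencies converge to the truth at high depth", {
  cons <- with_seed(8, random_dna(500, 0.5))
  poly <- data.frame(pos = c(10L, 100L, 400L),
                     alt = vapply(substring(cons, c(10, 100, 400),
                                            c(10, 100, 400)),
                                  function(b) setdiff(c("A", "C", "G", "T"),
                                                      b)[1], ""),
                     freq = c(0.1, 0.35, 0.48))
  p <- with_seed(3, simulate_pileup("g", "s", cons, poly, 10000))
  for (i in 1:3) {
    row <- match(poly$pos[i] - 1L, p$pos)
    est <- p$counts[row, poly$alt[i]] / sum(p$counts[row, ])
    expect_lt(abs(est - poly$freq[i]), 0.02)
  }
})

test_that("low-biomass samples are contaminant-enriched and VD neonates Gram-negative-enriched", {
  diffs <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(seed = s), contigs = FALSE,
                          pileups = FALSE)
    ab <- co$abundance
    sm <- co$samples
    contam <- co$genomes$genome_id[co$genomes$class == "contaminant"]
    gneg <- co$genomes$genome_id[co$genomes$class == "enteric_gramneg"]
    neo3 <- sm$sample_id[sm$role == "neonate" & sm$day == 3]
    vd <- intersect(neo3, sm$sample_id[sm$group == "VD"])
    csd <- intersect(neo3, sm$sample_id[sm$group == "CSD"])
    mo <- sm$sample_id[sm$role == "mother"]
    c(contaminant = mean(rowSums(ab[neo3, contam, drop = FALSE])) -
        mean(rowSums(ab[mo, contam, drop = FALSE])),
      gramneg = mean(rowSums(ab[vd, gneg, drop = FALSE])) -
        mean(rowSums(ab[csd, gneg, drop = FALSE])))
  }, c(contaminant = 0, gramneg = 0))
  expect_true(all(diffs["contaminant", ] > 0))
  # direction check over 20 seeds: VD day-3 Gram-negative abundance higher
  expect_true(all(diffs["gramneg", ] > 0))
})
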