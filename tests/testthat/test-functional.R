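test_that("best-KO assignment applies the bit-score threshold strictly", {
  hits <- data.frame(ko = c("K00001", "K00002"), bit_score = c(12, 11))
  expect_identical(assign_best_ko(hits, 1024), "K00001")
  low <- data.frame(ko = "K00001", bit_score = 9.5)
  expect_identical(assign_best_ko(low, 1024), NA_character_)
  # exactly at the threshold is rejected (strictly greater required)
  at <- data.frame(ko = "K00001", bit_score = 10)
  expect_identical(assign_best_ko(at, 1024), NA_character_)
  expect_identical(assign_best_ko(NULL, 10), NA_character_)
  # score ties break to the smallest KO id
  tie <- data.frame(ko = c("K00009", "K00002"), bit_score = c(50, 50))
  expect_identical(assign_best_ko(tie, 16), "K00002")
})

test_that("KO aggregation sums reads and flags empty samples", {
  gh <- data.frame(sample_id = c("s1", "s1", "s1", "s2"),
                   gene_id = c("g1", "g2", "g3", "g4"),
                   read_count = c(10, 5, 7, 3))
  cand <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     ko = c("K00001", "K00001", "K00002", "K00009"),
                     bit_score = c(100, 90, 80, 1))
  res <- aggregate_ko_counts(gh, cand, n_target_genes = 16)
  expect_equal(res$counts["s1", "K00001"], 15)
  expect_equal(res$counts["s1", "K00002"], 7)
  # gene below threshold leaves its sample empty and flagged
  expect_identical(res$empty_samples, "s2")
  expect_true(all(is.na(res$relative["s2", ])))
  expect_equal(sum(res$relative["s1", ]), 1)
  expect_identical(res$unassigned, "g4")
  # permutation invariance
  perm <- sample(nrow(gh))
  res2 <- aggregate_ko_counts(gh[perm, ], cand, n_target_genes = 16)
  expect_equal(res2$counts[rownames(res$counts), colnames(res$counts)],
               res$counts)
})

test_that("Jensen-Shannon divergence matches hand-computed values", {
  expect_equal(jensen_shannon(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jensen_shannon(c(1, 0), c(0, 1)), 1)
  # p=(1,0), q=(1/2,1/2) against mixture (3/4,1/4)
  d <- jensen_shannon(c(1, 0), c(0.5, 0.5))
  hand <- (log2(4 / 3) + 0.5 * log2(2 / 3) + 0.5 * log2(2)) / 2
  expect_equal(d, hand, tolerance = 1e-12)
  expect_equal(round(d, 4), 0.3113)
  expect_equal(jensen_shannon(c(1, 0), c(0.5, 0.5), sqrt_distance = TRUE),
               sqrt(hand))
  expect_error(jensen_shannon(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
  # symmetry, non-negativity and the base-2 upper bound on random pairs
  set.seed(1)
  for (i in 1:25) {
    p <- runif(6)
    p <- p / sum(p)
    q <- runif(6)
    q <- q / sum(q)
    d1 <- jensen_shannon(p, q)
    expect_equal(d1, jensen_shannon(q, p))
    expect_gte(d1, 0)
    expect_lte(d1, 1)
  }
})

test_that("profile Spearman correlation uses average ranks over the union", {
  p <- c(K1 = 0.5, K2 = 0.3, K3 = 0.2)
  expect_equal(spearman_profile_correlation(p, p), 1)
  x <- c(K1 = 1, K2 = 2, K3 = 3)
  y <- c(K1 = 3, K2 = 1, K3 = 2)
  expect_equal(spearman_profile_correlation(x, y), -0.5)
  expect_equal(spearman_profile_correlation(x, rev(setNames(x, names(x)))
               ), 1) # names drive alignment, not order
  expect_equal(spearman_profile_correlation(x, setNames(rev(unname(x)),
                                                        names(x))), -1)
  expect_warning(r <- spearman_profile_correlation(c(K1 = 1, K2 = 1),
                                                   c(K1 = 1, K2 = 2)),
                 "zero-variance")
  expect_true(is.na(r))
  # absent KOs count as zero abundance
  expect_equal(spearman_profile_correlation(c(K1 = 1), c(K2 = 1)), -1)
})

test_that("Wilcoxon tests reproduce exact enumeration values", {
  expect_equal(wilcoxon_groups(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(wilcoxon_groups(1:10, 11:20), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_warning(p <- wilcoxon_groups(c(1, 1), c(1, 1)), "tied")
  expect_equal(p, 1)
  # identical multisets: p = 1
  expect_equal(suppressWarnings(wilcoxon_groups(c(1, 2, 3), c(1, 2, 3))), 1)
  # paired mode is the signed-rank test (distinct differences: exact)
  x <- c(1, 2, 3, 4, 5, 6)
  y <- x + c(0.5, 1.5, -0.7, 2.2, -1.9, 3.1)
  expect_equal(wilcoxon_groups(x, y, paired = TRUE),
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
})

test_that("BH adjustment reproduces the step-up hand case", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.03, 0.001, 0.4)
  expect_equal(adjust_fdr(p), p.adjust(p, "BH"))
  expect_error(adjust_fdr(c(0.5, 1.2)), "p-values")
})

test_that("hypergeometric enrichment matches the counting formula", {
  pw <- data.frame(pathway_id = "pw", ko = sprintf("K%02d", 1:4))
  res <- pathway_enrichment(sprintf("K%02d", c(1:4, 9)),
                            sprintf("K%02d", 1:10), pw)
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)
  # empty draw set: overlap 0, p = 1
  res0 <- pathway_enrichment(character(0), sprintf("K%02d", 1:10), pw)
  expect_equal(res0$p, 1)
  # pathway covering the whole universe: the overlap is certain
  pw_all <- data.frame(pathway_id = "pw", ko = sprintf("K%02d", 1:10))
  res1 <- pathway_enrichment(sprintf("K%02d", 1:5),
                             sprintf("K%02d", 1:10), pw_all)
  expect_equal(res1$p, 1)
  # pathway disjoint from the universe: p = 1, flagged
  pw_out <- data.frame(pathway_id = "pw", ko = c("X1", "X2"))
  res2 <- pathway_enrichment("K01", sprintf("K%02d", 1:10), pw_out)
  expect_true(res2$flagged_empty)
  expect_equal(res2$p, 1)
  expect_error(pathway_enrichment("Z9", "K01", pw), "subset")
})

test_that("enrichment p-values match brute-force enumeration up to universe 40", {
  set.seed(11)
  for (i in 1:30) {
    N <- sample(5:40, 1)
    uni <- sprintf("K%02d", seq_len(N))
    m <- sample(1:N, 1)
    k <- sample(1:N, 1)
    pw_kos <- sample(uni, m)
    da <- sample(uni, k)
    ov <- length(intersect(pw_kos, da))
    res <- pathway_enrichment(da, uni,
                              data.frame(pathway_id = "pw", ko = pw_kos))
    expect_lt(abs(res$p - oracle_hyper_upper(ov, m, N, k)), 1e-12)
    # Fisher on the corresponding 2x2
    bin <- sample(uni, sample(1:N, 1))
    fe <- genome_function_enrichment(bin, da, uni)
    a <- length(intersect(bin, da))
    b <- length(setdiff(bin, da))
    cc <- length(setdiff(da, bin))
    d <- N - a - b - cc
    if (!fe$degenerate) {
      expect_lt(abs(fe$p - oracle_fisher_two_sided(a, b, cc, d)), 1e-12)
    }
  }
})

test_that("genome enrichment odds ratios match the cross-product", {
  uni <- sprintf("K%02d", 1:25)
  bin <- uni[1:15]            # a = 10, b = 5
  da <- uni[c(1:10, 16:17)]   # c = 2, d = 8
  r <- genome_function_enrichment(bin, da, uni)
  expect_equal(r$odds_ratio, (10 * 8) / (5 * 2))
  expect_false(r$haldane)
  # independent table: OR 1, p 1
  uni2 <- sprintf("K%02d", 1:20)
  r2 <- genome_function_enrichment(uni2[1:10], uni2[c(1:5, 11:15)], uni2)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p, 1)
  # zero cell: Haldane correction, flagged
  r3 <- genome_function_enrichment(uni2[1:5], uni2[1:5], uni2)
  expect_true(r3$haldane)
  expect_true(is.finite(r3$odds_ratio))
  # degenerate margin
  r4 <- genome_function_enrichment(character(0), uni2[1:5], uni2)
  expect_true(r4$degenerate)
  expect_equal(r4$p, 1)
})

test_that("cumulative pathway abundance sums member KOs", {
  prof <- c(K1 = 0.2, K2 = 0.3, K3 = 0.5)
  expect_equal(cumulative_pathway_abundance(prof, c("K1", "K3")), 0.7)
  expect_equal(cumulative_pathway_abundance(prof, names(prof)), 1)
  expect_equal(cumulative_pathway_abundance(prof, "K9"), 0)
})

test_that("Gram fractions keep unknowns separate", {
  tab <- data.frame(genus = c("Bacteroides", "Staphylococcus"),
                    gram = c("negative", "positive"))
  r <- gram_fraction(c(Bacteroides = 0.6, Staphylococcus = 0.4), tab)
  expect_equal(unname(r$fractions["negative"]), 0.6)
  expect_equal(unname(r$fractions["positive"]), 0.4)
  expect_equal(unname(r$fractions["unknown"]), 0)
  all_neg <- gram_fraction(c(Bacteroides = 1), tab)
  expect_equal(unname(all_neg$fractions["negative"]), 1)
  expect_message(
    r2 <- gram_fraction(c(Bacteroides = 0.9, Mystery = 0.1), tab),
    "Mystery"
  )
  expect_equal(unname(r2$fractions["unknown"]), 0.1)
  expect_identical(r2$missing_genera, "Mystery")
})

test_that("diversity indices follow the vegan conventions", {
  r <- diversity_indices(c(0.5, 0.5))
  expect_equal(r$shannon, log(2), tolerance = 1e-12)
  expect_equal(r$pielou, 1)
  expect_identical(r$richness, 2L)
  single <- diversity_indices(c(1, 0, 0))
  expect_equal(single$shannon, 0)
  expect_true(is.na(single$pielou))
  unif <- diversity_indices(rep(0.125, 8))
  expect_equal(unif$pielou, 1)
  zero <- diversity_indices(c(0, 0))
  expect_true(is.na(zero$shannon))
})

test_that("the differential KO rule requires agreeing directions", {
  # 4 samples per group at days 3 and 5, strong VD-up signal in K1,
  # opposite directions in K2, null K3
  set.seed(2)
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:12),
    role = "neonate",
    day = rep(c(3, 5), 6),
    group = rep(c("VD", "CSD", "CSD_SGA"), each = 4)
  )
  rel <- matrix(0, 12, 3, dimnames = list(samples$sample_id,
                                          c("K1", "K2", "K3")))
  vd <- samples$group == "VD"
  csd <- samples$group == "CSD"
  sga <- samples$group == "CSD_SGA"
  rel[vd, "K1"] <- runif(4, 0.8, 0.9)
  rel[!vd, "K1"] <- runif(8, 0.1, 0.2)
  rel[vd, "K2"] <- runif(4, 0.4, 0.5)
  rel[csd, "K2"] <- runif(4, 0.8, 0.9)   # VD < CSD
  rel[sga, "K2"] <- runif(4, 0.0, 0.1)   # VD > CSD_SGA: opposite
  rel[, "K3"] <- runif(12, 0.2, 0.3)
  res <- differential_kos(rel, samples, days = c(3, 5), alpha = 0.3)
  expect_true(res$da[res$ko == "K1"])
  expect_false(res$da[res$ko == "K2"])  # directions disagree
  expect_false(res$da[res$ko == "K3"])
  expect_equal(res$dir_csd[res$ko == "K1"], 1)
  expect_equal(res$dir_sga[res$ko == "K1"], 1)
})
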