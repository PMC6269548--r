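make_contigs <- function(seqs, sample_id = "S1", prefix = "c") {
  data.frame(contig_id = sprintf("%s%02d", prefix, seq_along(seqs)),
             sample_id = sample_id, sequence = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

test_that("k-mer screening removes copies and keeps unrelated contigs", {
  ctrl_seq <- with_seed(1, random_dna(3000, 0.6))
  unrelated <- with_seed(2, random_dna(3000, 0.4))
  half <- paste0(substring(ctrl_seq, 1, 1500),
                 with_seed(3, random_dna(1500, 0.4)))
  ctrl <- make_contigs(ctrl_seq, "CTRL", "ctl")
  smp <- make_contigs(c(ctrl_seq, unrelated, half), "S1")
  res <- screen_against_control(smp, ctrl)
  expect_identical(res$removed, "c01")            # exact copy
  expect_setequal(res$kept, c("c02", "c03"))
  expect_equal(unname(res$containment["c01"]), 1)
  expect_equal(unname(res$containment["c02"]), 0)
  # half-copied contig: containment near 0.5, below the 0.9 cutoff
  expect_lt(abs(res$containment[["c03"]] - 0.5), 0.05)
})

test_that("contigs shorter than k are kept with a warning", {
  ctrl <- make_contigs(with_seed(1, random_dna(2000, 0.5)), "CTRL", "ctl")
  smp <- make_contigs(c("ACGTACGTAC", with_seed(2, random_dna(500, 0.5))),
                      "S1")
  expect_warning(res <- screen_against_control(smp, ctrl), "shorter than")
  expect_true("c01" %in% res$kept)
})

test_that("screening is monotone in the control set", {
  set.seed(10)
  smp <- make_contigs(replicate(20, random_dna(1500, 0.5)), "S1")
  ctrl_a <- make_contigs(smp$sequence[1:5], "CTRL", "ctlA")
  ctrl_ab <- make_contigs(smp$sequence[1:10], "CTRL", "ctlB")
  rem_a <- screen_against_control(smp, ctrl_a)$removed
  rem_ab <- screen_against_control(smp, ctrl_ab)$removed
  expect_true(all(rem_a %in% rem_ab))
})

test_that("composition embedding is deterministic and separates GC classes", {
  set.seed(4)
  lo <- replicate(12, random_dna(4000, 0.35))
  hi <- replicate(12, random_dna(4000, 0.65))
  contigs <- make_contigs(c(lo, hi))
  e1 <- embed_contigs(contigs)
  e2 <- embed_contigs(contigs)
  expect_identical(e1, e2)
  lab <- rep(1:2, each = 12)
  sil <- cluster::silhouette(lab, dist(as.matrix(e1[, c("x", "y")])))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  # identical sequences embed at identical coordinates
  twin <- make_contigs(rep(lo[1], 2))
  twin <- rbind(twin, contigs[3, ])
  e3 <- embed_contigs(twin)
  expect_equal(e3[1, c("x", "y")], e3[2, c("x", "y")],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("joint binning follows DBSCAN geometry", {
  # two well-separated point clouds -> exactly two bins
  emb <- data.frame(
    contig_id = sprintf("c%02d", 1:12),
    x = c(rnorm(6, 0, 0.01), rnorm(6, 100, 0.01)),
    y = c(rnorm(6, 0, 0.01), rnorm(6, 0, 0.01))
  )
  info <- data.frame(contig_id = emb$contig_id, sample_id = "S1",
                     length = 1000)
  bins <- joint_bin(emb, info, eps = 1, min_points = 5)
  expect_length(bins$bins, 2)
  expect_length(bins$noise, 0)
  # an isolated point is noise
  emb2 <- rbind(emb, data.frame(contig_id = "far", x = 50, y = 50))
  info2 <- rbind(info, data.frame(contig_id = "far", sample_id = "S1",
                                  length = 1000))
  bins2 <- joint_bin(emb2, info2, eps = 1, min_points = 5)
  expect_identical(bins2$noise, "far")
  # all points coincident -> one bin containing all
  emb3 <- data.frame(contig_id = sprintf("c%d", 1:6), x = 0, y = 0)
  info3 <- data.frame(contig_id = emb3$contig_id, sample_id = "S1",
                      length = 1000)
  bins3 <- joint_bin(emb3, info3, eps = 0.5, min_points = 5)
  expect_length(bins3$bins, 1)
  expect_length(bins3$bins[[1]]$members, 6)
  expect_error(joint_bin(emb, info, eps = -1), "eps")
})

test_that("artefact flagging applies the <10 Mbp and >0.01% rule strictly", {
  mk_bin <- function(total, ctrl) {
    list(bin_id = "b", members = character(0), total_length = total,
         control_length = ctrl)
  }
  ctl_total <- 1e7
  # 2 Mbp bin holding 0.02% of the control -> flagged
  expect_identical(
    flag_artefact_bins(list(mk_bin(2e6, 2e-4 * ctl_total)), ctl_total), "b")
  # 12 Mbp bin: above the length bound, never flagged
  expect_length(
    flag_artefact_bins(list(mk_bin(1.2e7, 0.5 * ctl_total)), ctl_total), 0)
  # no control content -> not flagged
  expect_length(flag_artefact_bins(list(mk_bin(2e6, 0)), ctl_total), 0)
  # both bounds are strict
  expect_length(
    flag_artefact_bins(list(mk_bin(1e7, 0.5 * ctl_total)), ctl_total), 0)
  expect_length(
    flag_artefact_bins(list(mk_bin(2e6, 1e-4 * ctl_total)), ctl_total), 0)
  expect_error(flag_artefact_bins(list(), 0), "control_total_length")
})

test_that("decontamination bookkeeping partitions the input", {
  smp <- make_contigs(with_seed(5, replicate(6, random_dna(1000, 0.5))),
                      "S1")
  # no flags, no screens: curated = input
  r0 <- apply_decontamination(smp)
  expect_identical(r0$curated, smp)
  expect_identical(nrow(r0$report), 0L)
  # screen takes precedence over bin membership
  bins <- list(list(bin_id = "b1", members = c("c01", "c02"),
                    total_length = 2000, control_length = 100))
  r1 <- apply_decontamination(smp, bins, flagged_bin_ids = "b1",
                              screened_ids = "c01")
  expect_identical(r1$report$reason[r1$report$contig_id == "c01"], "screen")
  expect_identical(r1$report$reason[r1$report$contig_id == "c02"], "bin")
  expect_identical(sum(r1$report$contig_id == "c01"), 1L)
  # curated and removed partition the input set
  expect_setequal(c(r1$curated$contig_id, r1$report$contig_id),
                  smp$contig_id)
  expect_length(intersect(r1$curated$contig_id, r1$report$contig_id), 0)
})

test_that("synthetic contaminants cluster with the control and are removed", {
  co <- generate_cohort(small_config(seed = 6), pileups = FALSE)
  res <- decontaminate_cohort(co$contigs)
  truth <- co$truth$contaminant_contigs
  expect_gt(sum(res$report$contig_id %in% truth) / length(truth), 0.95)
  expect_false(any(res$curated$contig_id %in% res$report$contig_id))
})
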