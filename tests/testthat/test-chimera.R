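# Chimera calling: preprocessing order, hybrid detection with rejection
# reasons, per-total-hybrid normalization and binding-site clustering.

test_that("preprocessing follows trim -> collapse -> UMI -> length order", {
  adapter <- DEFAULT_ADAPTER3
  insert30 <- paste(rep("ACGU", 8), collapse = "")  # 32 nt
  insert30 <- substr(insert30, 1, 30)
  read <- paste0(insert30, adapter, "GGGG")
  pr <- preprocessReads(rep(read, 5), adapter3 = adapter)
  # 5 duplicates collapse to one; 30 - 2*4 = 22 nt survive
  expect_length(pr$reads, 1L)
  expect_equal(unname(nchar(pr$reads)), 22L)
  expect_equal(pr$multiplicity, 5L)
  expect_equal(unname(pr$log),
               c(5L, 5L, 1L, 1L, 1L))

  # 25 nt after adapter trim -> 25 - 8 = 17 < 18 -> dropped
  short <- paste0(substr(insert30, 1, 25), adapter)
  pr2 <- preprocessReads(short, adapter3 = adapter)
  expect_length(pr2$reads, 0L)

  # logged counts never increase across collapse/UMI/length steps
  fix <- smallFixture()
  sim <- simulateChimericReads(fix$cfg, fix$fam, fix$transcripts, fix$truth,
                               "wild_type", 2)
  lg <- preprocessReads(sim$reads)$log
  expect_true(all(diff(lg[c("adapter_trimmed", "collapsed", "umi_removed",
                            "length_filtered")]) <= 0))
  expect_error(preprocessReads("ACGU", adapter3 = ""), "adapter3")
})

test_that("UMI-aware collapse recovers the unique molecule count", {
  cfg <- smallConfig(61, pcr_duplication_mean = 2, hybrid_depth = 2000)
  fam <- makeMirnaFamily(cfg); tr <- makeTranscriptome(cfg, fam)
  sim <- simulateChimericReads(cfg, fam, tr$transcripts, tr$truth,
                               "wild_type", 1)
  expect_gt(nrow(sim$reads), nrow(sim$molecules))  # duplication happened
  pr <- preprocessReads(sim$reads)
  expect_equal(unname(pr$log[["collapsed"]]), nrow(sim$molecules))
})

test_that("malformed FASTQ raises a parse error naming the record", {
  tf <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "r2-missing-at", "ACGT", "+", "IIII"), tf)
  expect_error(readFastq(tf), "record 2")
  writeLines(c("@r1", "ACGT", "+"), tf)
  expect_error(readFastq(tf), "truncated")
  # round trip through the gzip writer
  fix <- smallFixture()
  sim <- simulateChimericReads(fix$cfg, fix$fam, fix$transcripts, fix$truth,
                               "wild_type", 3)
  gz <- tempfile(fileext = ".fastq.gz")
  writeChimericFastq(sim, gz)
  back <- readFastq(gz)
  expect_identical(unname(back), sim$reads$seq)
})

test_that("hybrid detection resolves constructed reads and rejection reasons", {
  fix <- smallFixture()
  g <- guideRecords(fix$fam)
  tx_id <- names(fix$transcripts)[2]
  tx <- fix$transcripts[[tx_id]]

  # miRNA arm followed by 25 nt of transcript at offset 100
  frag <- substr(tx, 101, 125)
  det <- detectHybrids(paste0(g$sequence[1], frag), fix$fam, fix$transcripts)
  expect_equal(det$status, "accepted")
  expect_equal(det$mirna_id, g$id[1])
  expect_equal(det$transcript_id, tx_id)
  expect_equal(det$target_start, 100L)
  expect_equal(det$target_end, 125L)
  expect_equal(det$arm_order, "mirna_first")

  # target-first arm order
  det2 <- detectHybrids(paste0(frag, g$sequence[1]), fix$fam, fix$transcripts)
  expect_equal(det2$status, "accepted")
  expect_equal(det2$arm_order, "target_first")

  # target-only read
  expect_equal(detectHybrids(substr(tx, 101, 140), fix$fam,
                             fix$transcripts)$status, "no_mirna_arm")
  # two disjoint miRNA arms
  expect_equal(detectHybrids(paste0(g$sequence[1], g$sequence[2]), fix$fam,
                             fix$transcripts)$status, "multiple_mirna_arms")
  # flank below the minimum target length
  expect_equal(detectHybrids(paste0(g$sequence[1], substr(tx, 101, 110)),
                             fix$fam, fix$transcripts)$status,
               "target_too_short")
  # a flank present in two transcripts cannot map uniquely
  dup_tx <- c(fix$transcripts, copy_tx = unname(fix$transcripts[tx_id]))
  expect_equal(detectHybrids(paste0(g$sequence[1], frag), fix$fam,
                             dup_tx)$status, "ambiguous_target")
  # configuration error on an empty database
  empty <- new("MiRNASet", records = guideRecords(fix$fam)[0, ])
  expect_error(detectHybrids("ACGU", empty, fix$transcripts), "empty miRNA")
})

test_that("detection on error-free synthetic reads matches the planted labels", {
  cfg <- smallConfig(62, hybrid_depth = 1e4)
  fam <- makeMirnaFamily(cfg); tr <- makeTranscriptome(cfg, fam)
  sim <- simulateChimericReads(cfg, fam, tr$transcripts, tr$truth,
                               "wild_type", 1)
  pp <- preprocessReads(sim$reads)
  det <- detectHybrids(pp$reads, fam, tr$transcripts)
  mol <- as.data.frame(sim$molecules)
  # read ids of representatives map back to molecules
  rid <- sim$reads$molecule_id[match(names(pp$reads), sim$reads$read_id)]
  truth_mir <- mol$mirna_id[rid]
  truth_tx <- mol$transcript_id[rid]
  is_hyb <- mol$type[rid] == "hybrid"
  acc <- det$status == "accepted"
  # >= 99% of true hybrids recovered with the right miRNA and transcript
  ok <- acc & det$mirna_id == truth_mir & det$transcript_id == truth_tx &
    det$target_start == mol$target_start[rid] &
    det$target_end == mol$target_end[rid]
  expect_gte(mean(ok[is_hyb]), 0.99)
  # no accepted hybrid on a wrong transcript
  expect_equal(sum(acc[is_hyb] &
                     det$transcript_id[is_hyb] != truth_tx[is_hyb]), 0L)
  # background reads are rejected for lack of a miRNA arm
  expect_true(all(det$status[!is_hyb] == "no_mirna_arm"))
})

test_that("tabulation normalizes to reads per million total hybrids", {
  h <- S4Vectors::DataFrame(
    read_id = paste0("r", 1:4), status = "accepted",
    mirna_id = c("A", "B", "B", "B"), mirna_start = 0L, mirna_end = 22L,
    transcript_id = "tx1", target_start = c(10L, 50L, 50L, 50L),
    target_end = c(40L, 80L, 80L, 80L), arm_order = "mirna_first")
  tab <- tabulateHybrids(h, "s1")
  p <- hybridPairs(tab)
  expect_equal(p$rpm[p$mirna_id == "A"], 250000)
  expect_equal(p$rpm[p$mirna_id == "B"], 750000)
  expect_equal(sum(p$rpm), 1e6)
  expect_equal(totalHybrids(tab), 4L)
  # a single pair carries the whole million
  expect_equal(hybridPairs(tabulateHybrids(h[1, ], "s1"))$rpm, 1e6)
  expect_error(tabulateHybrids(h[0, ], "s1"), "empty-table")

  # normalization identity on a simulated library
  fix <- smallFixture()
  sim <- simulateChimericReads(fix$cfg, fix$fam, fix$transcripts, fix$truth,
                               "decay_null", 1)
  det <- detectHybrids(preprocessReads(sim$reads)$reads, fix$fam,
                       fix$transcripts)
  tab2 <- tabulateHybrids(acceptedHybrids(det), "m1")
  expect_equal(sum(hybridPairs(tab2)$rpm), 1e6, tolerance = 1e-9)
})

test_that("binding-site clustering merges overlapping spans and finds summits", {
  mk <- function(starts, ends, mirna = "A", tx = "tx1") {
    S4Vectors::DataFrame(read_id = paste0("r", seq_along(starts)),
                         status = "accepted", mirna_id = mirna,
                         mirna_start = 0L, mirna_end = 22L,
                         transcript_id = tx, target_start = starts,
                         target_end = ends, arm_order = "mirna_first")
  }
  # overlapping spans merge into one site covering the union
  s1 <- clusterBindingSites(mk(c(100L, 110L), c(125L, 140L)))
  expect_length(s1, 1L)
  expect_equal(GenomicRanges::start(s1), 101L)  # 1-based
  expect_equal(GenomicRanges::end(s1), 140L)
  # disjoint spans stay separate
  s2 <- clusterBindingSites(mk(c(100L, 200L), c(125L, 230L)))
  expect_length(s2, 2L)
  # summit: maximal coverage (three fragments stack over [120, 130))
  s3 <- clusterBindingSites(mk(c(100L, 100L, 120L), c(130L, 130L, 150L)))
  expect_equal(s3$summit, 120L)
  # flat coverage: summit falls on the leftmost maximal position
  s4 <- clusterBindingSites(mk(100L, 130L))
  expect_equal(s4$summit, 100L)

  # simulated trigger library: exactly two trigger sites within +/- 5 nt
  fix <- smallFixture()
  sim <- simulateChimericReads(fix$cfg, fix$fam, fix$transcripts, fix$truth,
                               "decay_null", 2)
  det <- detectHybrids(preprocessReads(sim$reads)$reads, fix$fam,
                       fix$transcripts)
  sites <- clusterBindingSites(acceptedHybrids(det))
  trg <- sites[as.character(GenomicRanges::seqnames(sites)) == fix$truth@trigger_id]
  expect_length(trg, 2L)
  truth_sites <- as.data.frame(fix$truth@sites)
  truth_sites <- truth_sites[order(truth_sites$start), ]
  expect_true(all(abs(GenomicRanges::start(trg) - truth_sites$start) <= 5))
  expect_true(all(abs(GenomicRanges::end(trg) - truth_sites$end) <= 5))
  # all family members observed at the perfect-seed site
  seed_site <- trg[truth_sites$site_id == "site1"]
  expect_setequal(unlist(seed_site$member_ids), fix$truth@members$id)
})
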