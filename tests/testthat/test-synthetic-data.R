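# The synthetic-data generator: family design, planted trigger sites,
# chimeric libraries, count tables, isoform reads and quantification
# fixtures, with determinism under the config seed.

test_that("family construction: shared seed, divergent 3' ends, hairpin passengers", {
  cfg <- simConfig(rng_seed = 7, family_size = 8)
  fam <- makeMirnaFamily(cfg)
  g <- guideRecords(fam)
  p <- passengerRecords(fam)
  expect_equal(nrow(g), 8L)
  expect_equal(nrow(p), 8L)
  # identical seed (positions 2-8) across members
  expect_length(unique(substr(g$sequence, 2, 8)), 1L)
  # positions 9..end pairwise divergent by >= 30%
  tails <- substr(g$sequence, 9, cfg@mirna_length)
  tl <- nchar(tails[1])
  for (i in 1:7) for (j in (i + 1):8) {
    mm <- sum(strsplit(tails[i], "")[[1]] != strsplit(tails[j], "")[[1]])
    expect_gte(mm, ceiling(0.3 * tl))
  }
  # hairpin rule: passenger differs from revcomp(guide) at exactly the two
  # substituted positions (1 and 10)
  for (i in 1:8) {
    rc <- rcRna(g$sequence[i])
    diffs <- which(strsplit(p$sequence[i], "")[[1]] != strsplit(rc, "")[[1]])
    expect_equal(diffs, c(1L, 10L))
  }
  expect_true(all(nchar(g$context) >= 10))
  # smallest family and invalid configs
  expect_equal(nrow(guideRecords(makeMirnaFamily(simConfig(rng_seed = 1, family_size = 2)))), 2L)
  expect_error(simConfig(family_size = 1), "family_size")
  expect_error(simConfig(mirna_length = 17), "mirna_length")
})

test_that("generators are byte-identical under the same config seed", {
  cfg <- simConfig(rng_seed = 7)
  f1 <- makeMirnaFamily(cfg); f2 <- makeMirnaFamily(cfg)
  expect_identical(mirnaRecords(f1), mirnaRecords(f2))
  t1 <- makeTranscriptome(cfg, f1); t2 <- makeTranscriptome(cfg, f2)
  expect_identical(t1$transcripts, t2$transcripts)
  s1 <- simulateChimericReads(smallConfig(3), makeMirnaFamily(smallConfig(3)),
                              makeTranscriptome(smallConfig(3), makeMirnaFamily(smallConfig(3)))$transcripts,
                              makeTranscriptome(smallConfig(3), makeMirnaFamily(smallConfig(3)))$truth,
                              "wild_type", 1)
  s2 <- simulateChimericReads(smallConfig(3), makeMirnaFamily(smallConfig(3)),
                              makeTranscriptome(smallConfig(3), makeMirnaFamily(smallConfig(3)))$transcripts,
                              makeTranscriptome(smallConfig(3), makeMirnaFamily(smallConfig(3)))$truth,
                              "wild_type", 1)
  expect_identical(s1$reads$seq, s2$reads$seq)
})

test_that("transcriptome plants the designed site architecture", {
  fix <- smallFixture()
  g <- guideRecords(fix$fam)
  truth <- fix$truth
  tx <- fix$transcripts[[truth@trigger_id]]
  sites <- as.data.frame(truth@sites)
  s1 <- sites[sites$site_id == "site1", ]
  s2 <- sites[sites$site_id == "site2", ]
  win1 <- substr(tx, s1$start - 10, s1$end + 10)
  win2 <- substr(tx, s2$start - 10, s2$end + 10)

  # site 1 carries the exact seed complement of every member
  for (i in seq_len(nrow(g))) {
    expect_true(grepl(rcRna(substr(g$sequence[i], 2, 8)), win1, fixed = TRUE))
  }
  # designated 3'-paired member: tdtt-prone duplex at site 1
  des <- truth@members$id[which.max(truth@members$site1_3p)]
  d1 <- predictDuplex(g$sequence[g$id == des], win1)
  a1 <- classifyArchitecture(d1)
  expect_equal(a1@seed_match, "perfect_2_8")
  expect_true(a1@tdtt_prone)
  # a site carrying only a 2-nt 3' complement for the same member (rest of
  # the window built non-pairing against the local neighborhood) is not
  # tdtt-prone; contrast with the planted 12-nt complement above
  partners <- list(A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))
  ch <- strsplit(g$sequence[g$id == des], "")[[1]]
  L <- length(ch)
  dead <- vapply(seq_len(L), function(gg) {
    bad <- unique(unlist(partners[ch[max(1, gg - 2):min(L, gg + 2)]]))
    cand <- setdiff(c("A", "C", "G", "U"), bad)
    if (length(cand)) cand[1] else
      setdiff(c("A", "C", "G", "U"), unlist(partners[ch[gg]]))[1]
  }, character(1))
  site2nt <- rev(ifelse(seq_len(L) %in% c(2:8, (L - 1):L),
                        chartr("ACGU", "UGCA", ch), dead))
  a2nt <- classifyArchitecture(predictDuplex(g$sequence[g$id == des],
                                             paste(site2nt, collapse = "")))
  expect_equal(a2nt@seed_match, "perfect_2_8")
  expect_false(a2nt@tdtt_prone)
  # the planted flag in the truth marks exactly the designated member
  expect_equal(truth@members$id[truth@members$is_3p_paired], des)

  # site 2: offset seed for the designated member, no pair at position 2,
  # >= 8 pairs in positions 9..end
  s2_member <- g$id[fix$cfg@trigger_site2_member]
  d2 <- predictDuplex(g$sequence[g$id == s2_member], win2)
  pr <- duplexPairs(d2)
  expect_false(2L %in% pr[, "g"])
  expect_true(all(3:8 %in% pr[, "g"]))
  expect_gte(sum(pr[, "g"] >= 9), 8)
  expect_equal(classifyArchitecture(d2)@seed_match, "offset_3_8")

  # a planted decoy site is seed-only for the reference member
  dec <- as.data.frame(truth@decoy_sites)[1, ]
  dwin <- substr(fix$transcripts[[dec$transcript_id]],
                 dec$start - 9, dec$end + 10)
  ad <- classifyArchitecture(predictDuplex(g$sequence[1], dwin))
  expect_equal(ad@seed_match, "perfect_2_8")
  expect_equal(ad@n_supplemental_pairs + ad@three_prime_extent, 0L)

  # truth spans lie within the trigger and do not overlap
  expect_true(all(sites$start >= 1 & sites$end <= nchar(tx)))
  expect_true(s1$start > s2$end || s2$start > s1$end)
})

test_that("chimeric libraries: read architecture, background and duplication", {
  fix <- smallFixture()
  sim <- simulateChimericReads(fix$cfg, fix$fam, fix$transcripts, fix$truth,
                               "wild_type", 1)
  mol <- as.data.frame(sim$molecules)
  expect_equal(mean(mol$type == "background"), 0.1, tolerance = 0.01)
  # reads end in the adapter and carry 4-nt UMIs around the insert
  expect_true(all(grepl(paste0(DEFAULT_ADAPTER3, "$"),
                        head(sim$reads$seq, 50))))
  h <- which(mol$type == "hybrid")[1:25]
  g <- guideRecords(fix$fam)
  for (i in h) {
    arm <- g$sequence[g$id == mol$mirna_id[i]]
    frag <- substr(fix$transcripts[[mol$transcript_id[i]]],
                   mol$target_start[i] + 1, mol$target_end[i])
    insert <- if (mol$mirna_first[i]) paste0(arm, frag) else paste0(frag, arm)
    r <- sim$reads$seq[match(i, sim$reads$molecule_id)]
    expect_equal(substr(r, 5, 4 + nchar(insert)), insert)
  }

  # no PCR duplication -> every read is a unique molecule
  cfg0 <- smallConfig(12, pcr_duplication_mean = 0)
  fam0 <- makeMirnaFamily(cfg0); tr0 <- makeTranscriptome(cfg0, fam0)
  s0 <- simulateChimericReads(cfg0, fam0, tr0$transcripts, tr0$truth,
                              "wild_type", 1)
  expect_equal(nrow(s0$reads), nrow(s0$molecules))
  expect_false(any(duplicated(s0$reads$seq)))
})

test_that("trigger-hybrid enrichment matches lambda (and vanishes at lambda = 1)", {
  # lambda = 1: trigger molecule rates equal across genotypes within 3 SD
  cfg1 <- smallConfig(21, enrichment_lambda = 1, hybrid_depth = 2e4)
  fam1 <- makeMirnaFamily(cfg1); tr1 <- makeTranscriptome(cfg1, fam1)
  frac <- sapply(c("wild_type", "decay_null"), function(gt) {
    m <- as.data.frame(simulateChimericReads(cfg1, fam1, tr1$transcripts,
                                             tr1$truth, gt, 1)$molecules)
    mean(m$type == "hybrid" & m$transcript_id == tr1$truth@trigger_id)
  })
  n <- cfg1@hybrid_depth
  sd3 <- 3 * sqrt(frac[1] * (1 - frac[1]) / n + frac[2] * (1 - frac[2]) / n)
  expect_lt(abs(frac[1] - frac[2]), sd3)

  # lambda = 4 at full depth: trigger-pair RPM ratio in [3, 5]
  cfg4 <- simConfig(rng_seed = 22, enrichment_lambda = 4, hybrid_depth = 2e5)
  fam4 <- makeMirnaFamily(cfg4); tr4 <- makeTranscriptome(cfg4, fam4)
  rpm <- sapply(c("wild_type", "decay_null"), function(gt) {
    sim <- simulateChimericReads(cfg4, fam4, tr4$transcripts, tr4$truth, gt, 1)
    pp <- preprocessReads(sim$reads)
    det <- detectHybrids(pp$reads, fam4, tr4$transcripts)
    acc <- acceptedHybrids(det)
    tab <- tabulateHybrids(acc, gt)
    p <- hybridPairs(tab)
    sum(p$rpm[p$transcript_id == tr4$truth@trigger_id])
  })
  expect_gte(rpm[2] / rpm[1], 3)
  expect_lte(rpm[2] / rpm[1], 5)
})

test_that("count tables: planted stabilization, neutral passengers and classes", {
  fix <- smallFixture()
  cfg <- fix$cfg
  se_wt <- simulateCountTables(cfg, fix$truth, "wild_type", "L1")
  se_mu <- simulateCountTables(cfg, fix$truth, "decay_null", "L1")
  rd <- SummarizedExperiment::rowData(se_wt)
  expect_setequal(unique(rd$class),
                  c("mirna_guide", "mirna_passenger", "pirna", "spikein"))
  fam_ids <- fix$truth@members$id

  # no planted effect -> genotype means agree
  cfg0 <- smallConfig(31, decay_fold = 1)
  fam0 <- makeMirnaFamily(cfg0); tr0 <- makeTranscriptome(cfg0, fam0)
  a <- simulateCountTables(cfg0, tr0$truth, "wild_type", "L1")
  b <- simulateCountTables(cfg0, tr0$truth, "decay_null", "L1")
  fc0 <- foldChanges(combineCountTables(a, b), c("wild_type", "decay_null"),
                     normalizer_class = "pirna")
  expect_lt(mean(abs(fc0$log2fc)), 0.25)
  expect_lt(max(abs(fc0$log2fc)), 1.5)

  # planted fold recovered, passengers flat
  se <- combineCountTables(se_wt, se_mu)
  fc <- foldChanges(se, c("wild_type", "decay_null"), normalizer_class = "pirna")
  f <- as.data.frame(fc)
  est <- 2^f$log2fc[match(fam_ids, f$feature_id)]
  expect_equal(mean(est), cfg@decay_fold[1], tolerance = 0.2)
  pas <- f$log2fc[match(paste0(fam_ids, "*"), f$feature_id)]
  expect_lt(mean(abs(pas)), 0.4)
})

test_that("isoform reads follow the configured class probabilities", {
  cfg <- smallConfig(41, reads_per_mirna = 1e4)
  fam <- makeMirnaFamily(cfg); tr <- makeTranscriptome(cfg, fam)
  sim <- simulateIsoformReads(cfg, fam, tr$truth, "wild_type")
  r <- as.data.frame(sim$reads)
  # wild-type trimming rate for every member (trimmed classes together)
  for (id in unique(r$mirna_id)) {
    tr_frac <- mean(r$true_class[r$mirna_id == id] %in%
                      c("trimmed", "trimmed_tailed"))
    expect_lt(abs(tr_frac - cfg@trim_prob[["wild_type"]]), 0.02)
  }
  # no trimming, no tailing -> all canonical
  cfg0 <- smallConfig(42, trim_prob = c(wild_type = 0, decay_null = 0),
                      tail_prob = c(wild_type = 0, decay_null = 0))
  fam0 <- makeMirnaFamily(cfg0); tr0 <- makeTranscriptome(cfg0, fam0)
  s0 <- simulateIsoformReads(cfg0, fam0, tr0$truth, "wild_type")
  expect_true(all(s0$reads$true_class == "canonical"))
  # invalid probabilities
  expect_error(simConfig(trim_prob = c(wild_type = 0.6, decay_null = 0.6),
                         tail_prob = c(wild_type = 0.5, decay_null = 0.5)),
               "trim_prob")
})

test_that("qPCR model: closed-form Ct spacing and noise-free round trip", {
  fix <- smallFixture()
  cfg1 <- smallConfig(51, qpcr_efficiency = 1)
  fam1 <- makeMirnaFamily(cfg1); tr1 <- makeTranscriptome(cfg1, fam1)
  qd <- simulateQuantData(cfg1, tr1$truth, noise_free = TRUE)
  st <- as.data.frame(qd$standards)
  st <- st[st$species == "guide_ref", ]
  ct_by_dil <- tapply(st$ct, st$copies, unique)
  # efficiency 1 -> Ct drops by 1/log10(2) = 3.3219 per 10-fold dilution
  expect_equal(unique(round(diff(as.numeric(ct_by_dil)), 4)), -3.3219)

  # noise-free sample round trip through the fitted curve
  curve <- fitStandardCurve(st$copies, st$ct)
  sa <- as.data.frame(qd$samples)
  ct <- sa$ct[sa$species == "guide_ref"][1]
  expect_equal(quantifyCopies(ct, curve, tr1$truth@quant$input_ng),
               unname(tr1$truth@quant$copies_per_ng["guide"]),
               tolerance = 1e-6)
  expect_error(simConfig(qpcr_efficiency = 1.5), "qpcr_efficiency")

  # reference-stage spots: unit intensity recovered within 2%
  qd2 <- simulateQuantData(fix$cfg, fix$truth)
  sp <- as.data.frame(qd2$spots)
  expect_equal(median(sp$intensity[sp$stage == "bean"]),
               fix$cfg@spot_unit_intensity, tolerance = 0.02)
})
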