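# Size-factor normalization, permutation fold changes, decay amplitude,
# guide/passenger strand inference and pathway congruence.

mkSE <- function(counts, classes, genotype, stage = "L1") {
  reps <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(reps))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(class = classes,
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(genotype = genotype, stage = stage,
                                   replicate = seq_len(reps),
                                   row.names = colnames(counts)))
}

test_that("size factors are class totals over their geometric mean", {
  counts <- rbind(f1 = c(60L, 240L), p1 = c(40L, 160L))
  colnames(counts) <- c("s1", "s2")
  se <- mkSE(counts, c("mirna_guide", "pirna"), c("a", "b"))
  # totals 100 and 400 -> geometric mean 200 -> factors 0.5 and 2
  expect_equal(unname(computeSizeFactors(se, "total")), c(0.5, 2))
  # equal class totals -> unit factors
  eq <- mkSE(rbind(f1 = c(60L, 60L), p1 = c(40L, 40L),
                   sp = c(10L, 10L)),
             c("mirna_guide", "pirna", "spikein"), c("a", "b"))
  expect_equal(unname(computeSizeFactors(eq, "pirna")), c(1, 1))
  # scaling one sample x3 scales its relative factor x3; normalized counts
  # shift by one shared constant (the geometric mean moves), so all ratios
  # between normalized counts are untouched
  sc <- counts; sc[, 2] <- sc[, 2] * 3L
  se3 <- mkSE(sc, c("mirna_guide", "pirna"), c("a", "b"))
  f <- computeSizeFactors(se, "total"); f3 <- computeSizeFactors(se3, "total")
  expect_equal(unname(f3[2] / f[2]) / unname(f3[1] / f[1]), 3)
  n1 <- normalizedCounts(se, "total"); n3 <- normalizedCounts(se3, "total")
  expect_equal(n3, sqrt(3) * n1, tolerance = 1e-9)
  expect_equal(n3[1, ] / n3[2, ], n1[1, ] / n1[2, ], tolerance = 1e-9)
  # zero normalizer total errors with the sample name
  z <- mkSE(rbind(f1 = c(5L, 5L), p1 = c(0L, 7L)),
            c("mirna_guide", "pirna"), c("a", "b"))
  expect_error(computeSizeFactors(z, "pirna"), "s1")
})

test_that("fold changes use the pseudocounted normalized means and baseMean filter", {
  counts <- rbind(
    big = matrix(rep(c(10L, 80L), each = 3), nrow = 1),
    tiny = matrix(rep(c(5L, 5L), each = 3), nrow = 1),
    ref = matrix(100L, 1, 6))
  colnames(counts) <- paste0("s", 1:6)
  rownames(counts) <- c("big", "tiny", "ref")
  se <- mkSE(counts, c("mirna_guide", "mirna_guide", "pirna"),
             rep(c("a", "b"), each = 3))
  fc <- as.data.frame(foldChanges(se, c("a", "b"), normalizer_class = "pirna"))
  # normalized means 10 and 80 with c = 0.5 -> log2(80.5 / 10.5)
  expect_equal(fc$log2fc[fc$feature_id == "big"], log2(80.5 / 10.5))
  # baseMean 5 < 10 excluded
  expect_false("tiny" %in% fc$feature_id)
  expect_error(foldChanges(se, c("a", "zz")), "input error")
  # rescaling a sample's counts leaves fold changes unchanged up to the
  # pseudocount (exact without it, since normalized counts shift by one
  # shared constant)
  sc <- counts; sc[, 4] <- sc[, 4] * 5L
  fc2 <- as.data.frame(foldChanges(mkSE(sc, c("mirna_guide", "mirna_guide", "pirna"),
                                        rep(c("a", "b"), each = 3)),
                                   c("a", "b"), normalizer_class = "pirna"))
  expect_equal(fc2$log2fc, fc$log2fc, tolerance = 0.02)
  fc0 <- foldChanges(se, c("a", "b"), normalizer_class = "pirna", pseudocount = 0)
  fc0b <- foldChanges(mkSE(sc, c("mirna_guide", "mirna_guide", "pirna"),
                           rep(c("a", "b"), each = 3)),
                      c("a", "b"), normalizer_class = "pirna", pseudocount = 0)
  expect_equal(fc0b$log2fc, fc0$log2fc, tolerance = 1e-9)
})

test_that("exact permutation p-values hit their attainable floor", {
  set.seed(601)
  counts <- matrix(rnbinom(600, mu = 500, size = 20), nrow = 100)
  counts[1, 4:6] <- counts[1, 4:6] * 50L   # one enormous effect
  rownames(counts) <- paste0("f", 1:100)
  colnames(counts) <- paste0("s", 1:6)
  se <- mkSE(counts, rep("mirna_guide", 100), rep(c("a", "b"), each = 3))
  fc <- as.data.frame(foldChanges(se, c("a", "b")))
  # 3v3: 20 label splits in complementary pairs -> the smallest p is 2/20
  expect_equal(min(fc$p_perm), 0.1)
  expect_equal(fc$p_perm[fc$feature_id == "f1"], 0.1)
  # single replicate in a group -> p omitted
  se1 <- se[, c(1, 4:6)]
  fc1 <- foldChanges(se1, c("a", "b"))
  expect_true(all(is.na(fc1$p_perm)))
})

test_that("decay amplitude is the log2 stage ratio and flags missing features", {
  e <- mkSE(rbind(f1 = c(800L, 800L), f2 = c(400L, 400L), p = c(100L, 100L)),
            c("mirna_guide", "mirna_guide", "pirna"), c("wt", "wt"), "embryo")
  l_counts <- rbind(f1 = c(800L, 800L), f2 = c(50L, 50L), p = c(100L, 100L))
  l <- mkSE(l_counts, c("mirna_guide", "mirna_guide", "pirna"),
            c("wt", "wt"), "L1")
  amp <- as.data.frame(decayAmplitude(e, l, c("f1", "f2", "ghost"),
                                      normalizer_class = "pirna"))
  expect_equal(amp$amplitude[amp$feature_id == "f1"], 0, tolerance = 1e-3)
  expect_equal(amp$amplitude[amp$feature_id == "f2"], -3, tolerance = 0.01)
  expect_true(amp$missing_stage[amp$feature_id == "ghost"])
  expect_false(any(amp$missing_stage[amp$feature_id != "ghost"]))
})

test_that("decay amplitude difference between genotypes recovers the planted fold", {
  cfg <- smallConfig(81, srna_depth = 1e6)
  fam <- makeMirnaFamily(cfg); tr <- makeTranscriptome(cfg, fam)
  fam_ids <- tr$truth@members$id
  se_e <- simulateCountTables(cfg, tr$truth, "wild_type", "embryo")
  se_lw <- simulateCountTables(cfg, tr$truth, "wild_type", "L1")
  se_em <- simulateCountTables(cfg, tr$truth, "decay_null", "embryo")
  se_lm <- simulateCountTables(cfg, tr$truth, "decay_null", "L1")
  a_wt <- decayAmplitude(se_e, se_lw, fam_ids, normalizer_class = "pirna")
  a_mu <- decayAmplitude(se_em, se_lm, fam_ids, normalizer_class = "pirna")
  diffs <- a_mu$amplitude - a_wt$amplitude
  expect_equal(mean(diffs), log2(cfg@decay_fold[1]), tolerance = 0.3)
})

test_that("strand-level inference separates decay from biogenesis effects", {
  row <- function(fc, q) S4Vectors::DataFrame(feature_id = "x", class = "c",
                                              base_mean = 100,
                                              log2fc = log2(fc), p_perm = q,
                                              q = q)
  expect_equal(strandLevelInference(row(7.1, 0.01), row(1.0, 0.9)),
               "decay_level")
  expect_equal(strandLevelInference(row(3, 0.01), row(3, 0.01)),
               "biogenesis_level")
  expect_equal(strandLevelInference(row(1.1, 0.5), row(1.0, 0.9)), "no_call")
  # significant guide change with an elevated passenger is not a decay call
  expect_equal(strandLevelInference(row(3, 0.01), row(1.6, 0.2)), "no_call")
})

test_that("pathway congruence distinguishes epistasis from additivity", {
  expect_equal(pathwayCongruence(2.8, 2.5, 2.9), "same_pathway")
  expect_equal(pathwayCongruence(1.0, 1.0, 2.0), "additive")
  expect_equal(pathwayCongruence(1.0, 1.0, 4.0), "intermediate")
  # vectorized over the family: double = max single -> all same_pathway
  fa <- c(2.8, 2.5, 3.0, 2.2); fb <- fa - 0.2
  expect_true(all(pathwayCongruence(fa, fb, pmax(fa, fb)) == "same_pathway"))
})
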