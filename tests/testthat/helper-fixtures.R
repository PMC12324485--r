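# Shared fixtures and independent oracles for the test suite. Fixtures are
# generated in code (no stored data); the small experiment is cached per
# session because several files reuse it.

.fixture_cache <- new.env(parent = emptyenv())

smallConfig <- function(seed = 11L, ...) {
  args <- list(rng_seed = seed, family_size = 4L, n_decoy_transcripts = 8L,
               decoy_site_fraction = 0.5, hybrid_depth = 4000,
               srna_depth = 2e5, reads_per_mirna = 2000, n_replicates = 3L)
  over <- list(...)
  args[names(over)] <- over
  do.call(simConfig, args)
}

smallFixture <- function(seed = 11L) {
  key <- paste0("fix", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- smallConfig(seed)
  fam <- makeMirnaFamily(cfg)
  tr <- makeTranscriptome(cfg, fam)
  fix <- list(cfg = cfg, fam = fam, transcripts = tr$transcripts,
              truth = tr$truth)
  .fixture_cache[[key]] <- fix
  fix
}

randRna <- function(n, len) {
  vapply(rep(len, n), function(l) {
    paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = "")
  }, character(1))
}

rcRna <- function(x) {
  vapply(strsplit(chartr("ACGU", "UGCA", x), ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

.pairScoreOf <- function(a, b, scoring) {
  if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")) return(scoring[["WC"]])
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(scoring[["GU"]])
  NA_real_
}

.interiorPenalty <- function(a, b, scoring) {
  d <- abs(a - b)
  scoring[["mismatch"]] * min(a, b) +
    if (d > 0) scoring[["gap_open"]] + scoring[["gap_extend"]] * (d - 1) else 0
}

# Pure enumeration over every non-crossing pair set (exponential; use only for
# lengths <= ~7). Scores a pair set as the sum of pair scores plus the
# closed-form interior penalty between consecutive pairs; terminal unpaired
# stretches are free; the empty set scores 0.
oracleDuplexEnum <- function(mirna, target,
                             scoring = c(WC = 2, GU = 1, mismatch = -1,
                                         gap_open = -2, gap_extend = -1)) {
  xs <- strsplit(mirna, "")[[1]]
  yr <- rev(strsplit(target, "")[[1]])
  n <- length(xs); m <- length(yr)
  best <- 0
  rec <- function(i, j, score, lasti, lastj) {
    best <<- max(best, score)
    if (i > n || j > m) return(invisible())
    for (ii in i:n) {
      for (jj in j:m) {
        ps <- .pairScoreOf(xs[ii], yr[jj], scoring)
        if (is.na(ps)) next
        pen <- if (lasti == 0) 0 else
          .interiorPenalty(ii - lasti - 1, jj - lastj - 1, scoring)
        rec(ii + 1, jj + 1, score + ps + pen, ii, jj)
      }
    }
  }
  rec(1, 1, 0, 0, 0)
  best
}

# Last-pair chain recursion over the same pair-set definition, polynomial via
# tabulation; agrees with oracleDuplexEnum (checked in the suite) and serves
# as the scalable oracle for the DP equivalence tests.
oracleDuplexChain <- function(mirna, target,
                              scoring = c(WC = 2, GU = 1, mismatch = -1,
                                          gap_open = -2, gap_extend = -1)) {
  xs <- strsplit(mirna, "")[[1]]
  yr <- rev(strsplit(target, "")[[1]])
  n <- length(xs); m <- length(yr)
  sc <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc[i, j] <- .pairScoreOf(xs[i], yr[j], scoring)
  }
  best_cell <- matrix(-Inf, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (is.na(sc[i, j])) next
    prev <- 0
    if (i > 1 && j > 1) {
      for (ii in seq_len(i - 1)) for (jj in seq_len(j - 1)) {
        if (!is.finite(best_cell[ii, jj])) next
        cand <- best_cell[ii, jj] +
          .interiorPenalty(i - ii - 1, j - jj - 1, scoring)
        prev <- max(prev, cand)
      }
    }
    best_cell[i, j] <- sc[i, j] + prev
  }
  max(0, best_cell[is.finite(best_cell)], na.rm = TRUE)
}

# Independent scalar re-derivation of the isoform decomposition rules.
oracleIsoform <- function(read, canon, context, anchor_len = 4L, max_tail = 5L) {
  if (nchar(read) < anchor_len ||
      substr(read, 1, anchor_len) != substr(canon, 1, anchor_len)) {
    return("unassigned")
  }
  ref <- paste0(canon, context)
  tl <- 0L
  for (i in seq_len(nchar(read))) {
    if (i <= nchar(ref) && substr(read, i, i) == substr(ref, i, i)) {
      tl <- i
    } else break
  }
  tail_len <- nchar(read) - tl
  if (tail_len > max_tail) return("unassigned")
  trim <- max(0L, nchar(canon) - tl)
  if (trim == 0L && tail_len == 0L) "canonical"
  else if (trim > 0L && tail_len == 0L) "trimmed"
  else if (trim == 0L) "tailed"
  else "trimmed_tailed"
}

# Build a HybridTable directly from (mirna, transcript, site, count) rows,
# for arithmetic tests that bypass read-level simulation.
tableFromCounts <- function(mirna, transcript, site, count, sample_id = "s") {
  total <- sum(count)
  new("HybridTable",
      pairs = S4Vectors::DataFrame(
        mirna_id = mirna, transcript_id = transcript, site_id = site,
        start = NA_integer_, end = NA_integer_,
        count = as.integer(count), rpm = count / total * 1e6),
      sample_id = sample_id, total_hybrids = as.integer(total))
}
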