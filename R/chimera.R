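#' Preprocess raw chimeric eCLIP reads
#'
#' Applies the standard small-RNA preprocessing pipeline in this fixed order:
#' (1) trim the first occurrence of the 3' adapter and everything 3' of it;
#' (2) collapse exact duplicate sequences to one representative, recording
#' multiplicities (PCR deduplication *before* UMI removal, so molecules
#' sharing an insert but differing in UMIs stay distinct); (3) remove
#' `umi_len` nt from both ends; (4) drop reads shorter than `min_len`.
#'
#' @param reads character vector of read sequences (RNA or DNA alphabet;
#'   T is converted to U), or the `reads` DataFrame of
#'   [simulateChimericReads()].
#' @param adapter3 3' adapter sequence (non-empty).
#' @param umi_len UMI length removed from each end after collapsing.
#' @param min_len minimum retained read length.
#' @return list with `reads` (named character vector of processed sequences),
#'   `multiplicity` (duplicates collapsed into each representative) and `log`
#'   (named read counts after each step).
#' @examples
#' pr <- preprocessReads(c("ACGU", "ACGU"), adapter3 = "UGGAAUU",
#'                       umi_len = 0, min_len = 4)
#' pr$log
#' @export
preprocessReads <- function(reads, adapter3 = DEFAULT_ADAPTER3,
                            umi_len = 4L, min_len = 18L) {
  if (!nzchar(adapter3)) stop("adapter3 must be non-empty")
  if (umi_len < 0L) stop("umi_len must be >= 0")
  ids <- NULL
  if (is(reads, "DataFrame") || is.data.frame(reads)) {
    ids <- reads$read_id
    reads <- reads$seq
  }
  reads <- .dnaToRna(reads)
  if (is.null(ids)) ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  log <- c(input = length(reads))

  # (1) adapter trim: everything from the adapter's first occurrence is lost
  pos <- regexpr(adapter3, reads, fixed = TRUE)
  end <- pos - 1L
  miss <- pos < 0L
  if (any(miss)) end[miss] <- nchar(reads[miss])
  trimmed <- substr(reads, 1L, end)
  log <- c(log, adapter_trimmed = length(trimmed))

  # (2) collapse exact duplicates
  cl <- cpp_collapse(trimmed)
  collapsed <- trimmed[cl$keep]
  mult <- cl$multiplicity
  ids <- ids[cl$keep]
  log <- c(log, collapsed = length(collapsed))

  # (3) strip UMIs from both ends
  stripped <- substr(collapsed, umi_len + 1L, nchar(collapsed) - umi_len)
  log <- c(log, umi_removed = length(stripped))

  # (4) length filter
  ok <- nchar(stripped) >= min_len
  out <- stats::setNames(stripped[ok], ids[ok])
  log <- c(log, length_filtered = length(out))

  list(reads = out, multiplicity = mult[ok], log = log)
}

#' Detect miRNA-target hybrids in processed reads
#'
#' For each read, finds the best full-length occurrence of any *guide* miRNA
#' as a substring (Hamming distance <= `max_mirna_mismatches`); the flanking
#' remainder of length >= `min_target_len` must then map uniquely to one
#' transcript locus by exact k-mer seeding plus ungapped extension. A locus is
#' unique when the best candidate beats the runner-up by at least 2 matching
#' bases and matches the flank nearly exactly (>= length - 2). Reads failing
#' any stage are kept with a rejection reason: `no_mirna_arm`,
#' `multiple_mirna_arms` (two disjoint full-length miRNA occurrences),
#' `target_too_short`, or `ambiguous_target` (no unique locus).
#'
#' @param reads named character vector of processed reads (RNA or DNA).
#' @param mirna_set a [MiRNASet-class]; only guide strands are searched.
#' @param transcripts named character vector of transcript sequences.
#' @param max_mirna_mismatches maximum mismatches in the miRNA arm.
#' @param min_target_len minimum target-fragment length.
#' @param k k-mer size of the transcript index.
#' @return DataFrame with one row per read: `read_id`, `status` ("accepted"
#'   or a rejection reason), `mirna_id`, `mirna_start`/`mirna_end` (0-based
#'   half-open in the read), `transcript_id`, `target_start`/`target_end`
#'   (0-based half-open on the transcript sense strand), `arm_order`.
#' @export
detectHybrids <- function(reads, mirna_set, transcripts,
                          max_mirna_mismatches = 0L, min_target_len = 16L,
                          k = 12L) {
  g <- guideRecords(mirna_set)
  if (nrow(g) == 0L) stop("configuration error: empty miRNA database")
  seqs <- .dnaToRna(unname(reads))
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  tx_rna <- .dnaToRna(unname(transcripts))

  res <- cpp_detect(seqs, g$sequence, tx_rna,
                    as.integer(max_mirna_mismatches),
                    as.integer(min_target_len), as.integer(k))
  status_levels <- c("accepted", "no_mirna_arm", "multiple_mirna_arms",
                     "target_too_short", "ambiguous_target")
  DataFrame(read_id = ids,
            status = status_levels[res$status],
            mirna_id = g$id[res$pattern],
            mirna_start = res$mirna_start, mirna_end = res$mirna_end,
            transcript_id = names(transcripts)[res$tx],
            target_start = res$target_start, target_end = res$target_end,
            arm_order = c("mirna_first", "target_first")[res$arm_order])
}

#' Accepted hybrid rows of a detection table
#' @param detections DataFrame from [detectHybrids()]
#' @export
acceptedHybrids <- function(detections) {
  detections[detections$status == "accepted", , drop = FALSE]
}

#' Tabulate hybrids into a normalized per-sample interaction table
#'
#' Aggregates accepted hybrid reads by (miRNA, transcript, binding site) and
#' normalizes to reads per million total hybrids:
#' `rpm = count / total_hybrids * 1e6`, where `total_hybrids` is the number of
#' accepted hybrid reads in the sample (not collapsed pairs). When `sites` is
#' supplied, each hybrid is assigned to the overlapping clustered site
#' (maximum overlap); hybrids outside all sites get site_id `"nosite"`.
#'
#' @param hybrids accepted rows from [detectHybrids()] (rows with other
#'   status values are ignored).
#' @param sample_id sample label.
#' @param sites optional [GenomicRanges::GRanges] from
#'   [clusterBindingSites()].
#' @return a [HybridTable-class]; its per-sample rpm sums to 1e6.
#' @export
tabulateHybrids <- function(hybrids, sample_id, sites = NULL) {
  h <- hybrids[hybrids$status == "accepted", , drop = FALSE]
  if (nrow(h) == 0L) stop("empty-table error: no accepted hybrids in sample ", sample_id)

  site_id <- rep("nosite", nrow(h))
  s_start <- rep(NA_integer_, nrow(h)); s_end <- rep(NA_integer_, nrow(h))
  if (!is.null(sites) && length(sites)) {
    q <- GRanges(h$transcript_id, IRanges(h$target_start + 1L, h$target_end))
    ov <- GenomicRanges::findOverlaps(q, sites)
    if (length(ov)) {
      qh0 <- S4Vectors::queryHits(ov); sh0 <- S4Vectors::subjectHits(ov)
      wid <- pmin(IRanges::end(IRanges::ranges(q))[qh0],
                  GenomicRanges::end(sites)[sh0]) -
        pmax(IRanges::start(IRanges::ranges(q))[qh0],
             GenomicRanges::start(sites)[sh0]) + 1L
      o <- order(S4Vectors::queryHits(ov), -wid)
      first <- !duplicated(S4Vectors::queryHits(ov)[o])
      qh <- S4Vectors::queryHits(ov)[o][first]
      sh <- S4Vectors::subjectHits(ov)[o][first]
      site_id[qh] <- sites$site_id[sh]
      s_start[qh] <- GenomicRanges::start(sites)[sh] - 1L
      s_end[qh] <- GenomicRanges::end(sites)[sh]
    }
  }

  key <- paste(h$mirna_id, h$transcript_id, site_id, sep = "\r")
  agg <- rowsum(rep(1L, nrow(h)), key)
  first <- !duplicated(key)
  ord <- match(rownames(agg), key[first])
  keep <- which(first)[ord]
  total <- nrow(h)
  pairs <- DataFrame(
    mirna_id = h$mirna_id[keep],
    transcript_id = h$transcript_id[keep],
    site_id = site_id[keep],
    start = s_start[keep],
    end = s_end[keep],
    count = as.integer(agg[, 1]),
    rpm = as.numeric(agg[, 1]) / total * 1e6
  )
  new("HybridTable", pairs = pairs, sample_id = sample_id,
      total_hybrids = as.integer(total))
}

#' Cluster hybrid target fragments into binding sites
#'
#' Single-linkage clustering of target spans with pairwise overlap of at
#' least `min_overlap` nt; the site span is the union of its fragments and
#' the summit is the (leftmost, on ties) coordinate of maximal per-base
#' fragment coverage.
#'
#' @param hybrids accepted rows from [detectHybrids()]; may cover several
#'   transcripts (clustering is per transcript).
#' @param min_overlap minimum fragment overlap (nt) for single linkage.
#' @return [GenomicRanges::GRanges] (1-based spans on transcript coordinates)
#'   with metadata `site_id`, `summit` (0-based), `member_ids`
#'   (CharacterList of guide miRNAs observed) and `n_fragments`.
#' @export
clusterBindingSites <- function(hybrids, min_overlap = 1L) {
  sel <- hybrids$status == "accepted"
  tx_v <- as.character(hybrids$transcript_id[sel])
  s0 <- as.integer(hybrids$target_start[sel])
  e0 <- as.integer(hybrids$target_end[sel])
  mir <- as.character(hybrids$mirna_id[sel])
  acc <- list(tx = character(0), start = integer(0), end = integer(0),
              summit = integer(0), members = list(), n = integer(0))
  for (ii in split(seq_along(tx_v), tx_v)) {
    tx <- tx_v[ii[1]]
    s1 <- s0[ii] + 1L; e1 <- e0[ii]
    # single-linkage over intervals by a sorted sweep on the unique spans: a
    # span joins the open cluster iff its overlap with the member of maximal
    # end reaches min_overlap, which is exact for interval overlap graphs
    keynum <- as.numeric(s1) * 1e9 + e1
    uniq <- which(!duplicated(keynum))
    su <- s1[uniq]; eu <- e1[uniq]
    o <- order(su, eu)
    s <- su[o]; e <- eu[o]
    comp_sorted <- integer(length(s))
    cid <- 0L; max_end <- -1e9
    for (i in seq_along(s)) {
      if (min(max_end, e[i]) - s[i] + 1L < min_overlap) cid <- cid + 1L
      comp_sorted[i] <- cid
      max_end <- max(max_end, e[i])
    }
    comp_uniq <- integer(length(s)); comp_uniq[o] <- comp_sorted
    frag_comp <- comp_uniq[match(keynum, keynum[uniq])]
    cov_full <- as.integer(IRanges::coverage(IRanges(s1, e1)))
    for (cc in unique(frag_comp)) {
      members <- which(frag_comp == cc)
      span_start <- min(s1[members])
      span_end <- max(e1[members])
      covv <- cov_full[span_start:span_end]
      summit <- span_start + which.max(covv) - 1L
      i <- length(acc$start) + 1L
      acc$tx[i] <- tx; acc$start[i] <- span_start; acc$end[i] <- span_end
      acc$summit[i] <- summit - 1L
      acc$members[[i]] <- sort(unique(mir[ii][members]))
      acc$n[i] <- length(members)
    }
  }
  res <- GRanges(acc$tx, IRanges(acc$start, acc$end),
                 site_id = sprintf("%s:%d-%d", acc$tx, acc$start - 1L, acc$end),
                 summit = acc$summit,
                 member_ids = IRanges::CharacterList(acc$members),
                 n_fragments = acc$n)
  res[order(as.character(GenomicRanges::seqnames(res)), GenomicRanges::start(res))]
}

#' Run the chimera-calling pipeline over several libraries
#'
#' Preprocesses and hybrid-calls each library, clusters binding sites on the
#' pooled accepted hybrids (so site definitions are shared across samples),
#' and tabulates each sample against the shared sites.
#'
#' @param libraries named list; each element is either a character vector of
#'   raw reads or the result of [simulateChimericReads()].
#' @param mirna_set,transcripts,adapter3,umi_len,min_len,max_mirna_mismatches,min_target_len
#'   passed through to [preprocessReads()] and [detectHybrids()].
#' @param min_overlap site-clustering overlap.
#' @return list with `tables` (named list of [HybridTable-class]), `sites`
#'   (shared GRanges), `logs` (per-sample preprocess logs) and
#'   `status` (per-sample table of detection outcomes).
#' @export
runChimeraPipeline <- function(libraries, mirna_set, transcripts,
                               adapter3 = DEFAULT_ADAPTER3, umi_len = 4L,
                               min_len = 18L, max_mirna_mismatches = 0L,
                               min_target_len = 16L, min_overlap = 1L) {
  if (is.null(names(libraries))) names(libraries) <- sprintf("sample%02d", seq_along(libraries))
  hybrids <- list(); logs <- list(); statuses <- list()
  for (nm in names(libraries)) {
    lib <- libraries[[nm]]
    raw <- if (is.list(lib) && !is.null(lib$reads)) lib$reads else lib
    pp <- preprocessReads(raw, adapter3 = adapter3, umi_len = umi_len,
                          min_len = min_len)
    det <- detectHybrids(pp$reads, mirna_set, transcripts,
                         max_mirna_mismatches = max_mirna_mismatches,
                         min_target_len = min_target_len)
    hybrids[[nm]] <- acceptedHybrids(det)
    logs[[nm]] <- pp$log
    statuses[[nm]] <- table(det$status)
  }
  pooled <- data.frame(
    status = "accepted",
    transcript_id = unlist(lapply(hybrids, function(h) h$transcript_id),
                           use.names = FALSE),
    target_start = unlist(lapply(hybrids, function(h) h$target_start),
                          use.names = FALSE),
    target_end = unlist(lapply(hybrids, function(h) h$target_end),
                        use.names = FALSE),
    mirna_id = unlist(lapply(hybrids, function(h) h$mirna_id),
                      use.names = FALSE))
  sites <- clusterBindingSites(pooled, min_overlap = min_overlap)
  tables <- lapply(names(libraries), function(nm) {
    tabulateHybrids(hybrids[[nm]], sample_id = nm, sites = sites)
  })
  names(tables) <- names(libraries)
  list(tables = tables, sites = sites, logs = logs, status = statuses)
}
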