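#' Decompose small-RNA reads into 3' isoforms of a miRNA
#'
#' Assigns reads to a miRNA by an exact 5' anchor (the first `anchor_len` nt
#' must equal canonical positions 1..anchor_len; 5' isomiRs are out of scope)
#' and decomposes each assigned read against the *templated reference* —
#' canonical sequence followed by the genomic downstream context. The
#' templated length is the longest read prefix matching the reference
#' (greedy maximal matching: a 3' addition identical to the genomic context is
#' classified templated, not tail), the remaining suffix is the untemplated
#' tail, and `trim_len = max(0, canonical_length - templated_len)`. Classes:
#' `canonical` (no trim, no tail), `trimmed`, `tailed`, `trimmed_tailed`;
#' reads failing the anchor, or with tails longer than `max_tail`, are
#' `unassigned`. Reads extending past the canonical 3' end within the genomic
#' context are classified canonical with a `templated_extension` flag.
#'
#' @param read_seq character vector of read sequences (RNA or DNA).
#' @param mirna a single row of [guideRecords()] (fields `id`, `sequence`,
#'   `canonical_length`, `context`), or a list with those fields.
#' @param anchor_len exact 5' anchor length.
#' @param max_tail tails longer than this mark the read unassigned.
#' @return DataFrame with one row per read: `mirna_id`, `read_seq`,
#'   `templated_len`, `trim_len`, `tail_seq`, `iso_class`,
#'   `templated_extension`. Invariant: `templated_len + nchar(tail_seq) ==
#'   nchar(read_seq)` for every assigned read.
#' @export
assignIsoform <- function(read_seq, mirna, anchor_len = 14L, max_tail = 5L) {
  canon <- .dnaToRna(mirna$sequence)
  context <- .dnaToRna(mirna$context)
  if (!nzchar(context)) stop("downstream genomic context required for isoform analysis")
  canon_len <- nchar(canon)
  if (anchor_len > canon_len) stop("anchor_len exceeds canonical length")
  reads <- .dnaToRna(read_seq)
  n <- length(reads)
  ref <- paste0(canon, context)
  ref_len <- nchar(ref)

  anchored <- nchar(reads) >= anchor_len &
    substr(reads, 1L, anchor_len) == substr(canon, 1L, anchor_len)

  # longest read prefix matching the templated reference, vectorized by
  # scanning positions anchor_len+1 .. max read length
  tl <- ifelse(anchored, pmin(anchor_len, nchar(reads)), 0L)
  maxl <- max(c(nchar(reads), 0L))
  alive <- anchored
  pos <- anchor_len
  while (pos < maxl && any(alive)) {
    pos <- pos + 1L
    alive <- alive & nchar(reads) >= pos & pos <= ref_len &
      substr(reads, pos, pos) == substr(ref, pos, pos)
    tl[alive] <- pos
  }

  tail_seq <- ifelse(anchored, substr(reads, tl + 1L, nchar(reads)), "")
  trim_len <- ifelse(anchored, pmax(0L, canon_len - tl), NA_integer_)
  templated_extension <- anchored & tl > canon_len

  iso <- rep("unassigned", n)
  ok <- anchored & nchar(tail_seq) <= max_tail
  iso[ok & trim_len == 0L & tail_seq == ""] <- "canonical"
  iso[ok & trim_len > 0L & tail_seq == ""] <- "trimmed"
  iso[ok & trim_len == 0L & tail_seq != ""] <- "tailed"
  iso[ok & trim_len > 0L & tail_seq != ""] <- "trimmed_tailed"

  DataFrame(mirna_id = mirna$id, read_seq = reads,
            templated_len = ifelse(iso == "unassigned", NA_integer_, as.integer(tl)),
            trim_len = ifelse(iso == "unassigned", NA_integer_, as.integer(trim_len)),
            tail_seq = ifelse(iso == "unassigned", NA_character_, tail_seq),
            iso_class = iso,
            templated_extension = iso != "unassigned" & templated_extension)
}

#' Per-miRNA isoform profiles for one sample
#'
#' Class fractions over assigned reads (they sum to 1 per miRNA), the mean
#' trim length among trimmed reads, and the tail nucleotide composition
#' (per-nucleotide frequency across all tail positions).
#'
#' @param records DataFrame rows from [assignIsoform()] (several miRNAs may
#'   be mixed; profiles are per miRNA).
#' @param sample_id sample label.
#' @return DataFrame with one row per miRNA: `n_reads` (assigned),
#'   `n_unassigned`, `frac_canonical`, `frac_trimmed`, `frac_tailed`,
#'   `frac_trimmed_tailed`, `mean_trim_len`, `tail_A`/`tail_C`/`tail_G`/`tail_U`.
#' @export
profileIsoforms <- function(records, sample_id = "sample") {
  if (!nrow(records)) stop("no records to profile")
  rows <- lapply(unique(records$mirna_id), function(id) {
    r <- records[records$mirna_id == id, , drop = FALSE]
    assigned <- r[r$iso_class != "unassigned", , drop = FALSE]
    n <- nrow(assigned)
    fr <- function(cls) if (n) sum(assigned$iso_class == cls) / n else NA_real_
    trimmed <- assigned$trim_len[assigned$iso_class %in% c("trimmed", "trimmed_tailed")]
    tails <- unlist(strsplit(assigned$tail_seq[assigned$tail_seq != ""], "", fixed = TRUE))
    comp <- if (length(tails)) table(factor(tails, levels = RNA_ALPHABET)) / length(tails)
            else stats::setNames(rep(NA_real_, 4), RNA_ALPHABET)
    DataFrame(mirna_id = id, sample_id = sample_id,
              n_reads = n, n_unassigned = nrow(r) - n,
              frac_canonical = fr("canonical"), frac_trimmed = fr("trimmed"),
              frac_tailed = fr("tailed"), frac_trimmed_tailed = fr("trimmed_tailed"),
              mean_trim_len = if (length(trimmed)) mean(trimmed) else NA_real_,
              tail_A = as.numeric(comp[["A"]]), tail_C = as.numeric(comp[["C"]]),
              tail_G = as.numeric(comp[["G"]]), tail_U = as.numeric(comp[["U"]]))
  })
  do.call(rbind, rows)
}

#' Compare isoform profiles between two samples or genotypes
#'
#' Per-miRNA two-proportion z-test on the chosen isoform fraction. A read
#' counts toward the metric when its class contains the metric (so
#' `trimmed_tailed` reads count as both trimmed and tailed). Positive
#' differences mean a higher fraction in group b. P-values are
#' Benjamini-Hochberg adjusted across miRNAs.
#'
#' @param profiles_a,profiles_b DataFrames from [profileIsoforms()].
#' @param metric `"trimmed"` or `"tailed"`.
#' @param min_reads miRNAs with fewer assigned reads in either group are
#'   flagged `low_power`.
#' @return DataFrame per miRNA: fractions, `delta` (b - a), `z`, `p`, `q`,
#'   `low_power`.
#' @export
compareProfiles <- function(profiles_a, profiles_b,
                            metric = c("trimmed", "tailed"), min_reads = 50L) {
  metric <- match.arg(metric)
  fracOf <- function(pr) {
    pr$frac_trimmed_tailed +
      if (metric == "trimmed") pr$frac_trimmed else pr$frac_tailed
  }
  ids <- intersect(profiles_a$mirna_id, profiles_b$mirna_id)
  ia <- match(ids, profiles_a$mirna_id); ib <- match(ids, profiles_b$mirna_id)
  na <- profiles_a$n_reads[ia]; nb <- profiles_b$n_reads[ib]
  pa <- fracOf(profiles_a)[ia]; pb <- fracOf(profiles_b)[ib]
  pooled <- (pa * na + pb * nb) / (na + nb)
  se <- sqrt(pooled * (1 - pooled) * (1 / na + 1 / nb))
  z <- ifelse(se > 0, (pb - pa) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1)
  DataFrame(mirna_id = ids, n_a = na, n_b = nb, frac_a = pa, frac_b = pb,
            delta = pb - pa, z = z, p = p,
            q = stats::p.adjust(p, method = "BH"),
            low_power = na < min_reads | nb < min_reads)
}
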