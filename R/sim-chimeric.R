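#' Default 3' sequencing adapter (RNA alphabet)
#'
#' The small-RNA 3' adapter used by the simulated libraries and by the
#' preprocessing defaults.
#' @export
DEFAULT_ADAPTER3 <- "UGGAAUUCUCGGGUGCCAAGG"

#' Simulate one chimeric eCLIP library
#'
#' Draws `hybrid_depth` unique molecules: a fraction `background_fraction` are
#' target-only fragments (exercising the no-miRNA-arm rejection path); the
#' rest are miRNA-target chimeras sampled from the planted interaction table
#' with probability proportional to the duplex score. In the `decay_null`
#' genotype, trigger-site interactions of degraded members are multiplied by
#' `enrichment_lambda`. Each molecule is a read of the form
#' `UMI(4) + [miRNA arm || target fragment, random order] + UMI(4) + adapter`,
#' emitted `Poisson(pcr_duplication_mean) + 1` times.
#'
#' @param config a [SimConfig-class]
#' @param family a [MiRNASet-class]
#' @param transcriptome named character vector of transcript sequences (from
#'   [makeTranscriptome()])
#' @param truth the matching [SimTruth-class]
#' @param genotype `"wild_type"` or `"decay_null"`
#' @param replicate replicate index (each replicate draws an independent,
#'   deterministic sub-stream)
#' @return list with `reads` (DataFrame: read_id, seq, molecule_id),
#'   `molecules` (per-molecule ground truth: type, mirna_id, transcript_id,
#'   0-based half-open target span, site_id) and `sample_id`
#' @export
simulateChimericReads <- function(config, family, transcriptome, truth,
                                  genotype = c("wild_type", "decay_null"),
                                  replicate = 1L) {
  genotype <- match.arg(genotype)
  stopifnot(is(config, "SimConfig"), is(truth, "SimTruth"))
  if (config@hybrid_depth <= 0) stop("invalid config: hybrid_depth must be positive")
  inter <- truth@interactions
  g <- guideRecords(family)
  degraded <- truth@members$id[truth@members$degraded]

  .withSeed(.deriveSeed(config@rng_seed, paste0("chimeric_", genotype), replicate), {
    w <- inter$score
    if (genotype == "decay_null") {
      boost <- inter$is_trigger & inter$mirna_id %in% degraded
      w[boost] <- w[boost] * config@enrichment_lambda
    }
    depth <- round(config@hybrid_depth)
    n_bg <- round(depth * config@background_fraction)
    n_hyb <- depth - n_bg

    idx <- sample.int(nrow(inter), n_hyb, replace = TRUE, prob = w)
    tx_id <- inter$transcript_id[idx]
    tx_seq <- unname(transcriptome[tx_id])
    tx_len <- nchar(tx_seq)
    # fragments bracket the protected site with 0-4 nt of jitter per end;
    # sites narrower than a 22-nt footprint are padded symmetrically so every
    # fragment clears the hybrid caller's minimum target length
    pad <- pmax(0L, ceiling((22L - (inter$end[idx] - inter$start[idx])) / 2))
    fs <- pmax(0L, inter$start[idx] - pad - sample(0:4, n_hyb, replace = TRUE))
    fe <- pmin(tx_len, inter$end[idx] + pad + sample(0:4, n_hyb, replace = TRUE))
    frag <- substring(tx_seq, fs + 1L, fe)
    arm <- g$sequence[match(inter$mirna_id[idx], g$id)]
    mirna_first <- stats::runif(n_hyb) < 0.5
    insert <- ifelse(mirna_first, paste0(arm, frag), paste0(frag, arm))

    bg_tx <- sample(names(transcriptome), n_bg, replace = TRUE)
    bg_len <- nchar(transcriptome[bg_tx])
    bg_fs <- floor(stats::runif(n_bg) * pmax(1L, bg_len - 50L))
    bg_fe <- pmin(bg_len, bg_fs + sample(30:50, n_bg, replace = TRUE))
    bg_insert <- substring(unname(transcriptome[bg_tx]), bg_fs + 1L, bg_fe)

    n_mol <- n_hyb + n_bg
    u <- matrix(sample(RNA_ALPHABET, 8L * n_mol, replace = TRUE), nrow = n_mol)
    inserts <- c(insert, bg_insert)
    mol_seq <- paste0(u[, 1], u[, 2], u[, 3], u[, 4], inserts,
                      u[, 5], u[, 6], u[, 7], u[, 8], DEFAULT_ADAPTER3)

    molecules <- DataFrame(
      molecule_id = seq_len(n_mol),
      type = rep(c("hybrid", "background"), c(n_hyb, n_bg)),
      mirna_id = c(inter$mirna_id[idx], rep(NA_character_, n_bg)),
      transcript_id = c(tx_id, bg_tx),
      target_start = c(fs, bg_fs),
      target_end = c(fe, bg_fe),
      site_id = c(inter$site_id[idx], rep(NA_character_, n_bg)),
      mirna_first = c(mirna_first, rep(NA, n_bg))
    )

    copies <- stats::rpois(n_mol, config@pcr_duplication_mean) + 1L
    rid <- rep.int(seq_len(n_mol), copies)
    ord <- sample.int(length(rid))
    rid <- rid[ord]
    reads <- DataFrame(
      read_id = paste0("r", seq_along(rid)),
      seq = mol_seq[rid],
      molecule_id = rid
    )
    list(reads = reads, molecules = molecules,
         sample_id = sprintf("%s_rep%d", genotype, replicate))
  })
}

#' Write a simulated chimeric library as gzip FASTQ (Phred+33)
#'
#' Sequences are written in the DNA alphabet (U -> T) with uniform quality.
#' @param sim result of [simulateChimericReads()]
#' @param path output path (".fastq.gz")
#' @export
writeChimericFastq <- function(sim, path) {
  con <- gzfile(path, "wt")
  on.exit(close(con))
  seqs <- .rnaToDna(sim$reads$seq)
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", sim$reads$read_id, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ file into a named character vector of RNA sequences
#'
#' A strict reader for the small libraries this package produces: malformed
#' records raise a parse error naming the record index.
#' @param path FASTQ path (plain or gzip)
#' @return named character vector (RNA alphabet)
#' @export
readFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("FASTQ parse error: truncated file")
  n <- length(lines) / 4L
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+"))
  if (length(bad)) stop("FASTQ parse error at record ", bad[1])
  stats::setNames(.dnaToRna(sq), sub("^@", "", hd))
}
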