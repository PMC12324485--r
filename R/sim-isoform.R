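# Untemplated tail nucleotide distribution: uridylation dominates, some
# adenylation, rare C/G — typical of metazoan 3' nucleotidyl transferases.
TAIL_NT_PROBS <- c(A = 0.2, C = 0.05, G = 0.05, U = 0.7)

#' Simulate small-RNA reads with 3' trimming and tailing
#'
#' For each guide member, draws `reads_per_mirna` reads. Independent trim and
#' tail coins fire with probabilities `trim_prob` and `tail_prob`, so the
#' trimmed (resp. tailed) class fraction — counting `trimmed_tailed` in both —
#' is exactly the configured probability; reads where neither fires are
#' canonical. Trimming removes 1-3 nt off the 3' end; tailing appends 1-3
#' untemplated nt from [TAIL_NT_PROBS]. The
#' elevated trimming probability (`trim_prob["decay_null"]` by default)
#' applies only to members flagged 3'-paired in the truth, and only in the
#' configured `tdtt_genotype`; all other members keep the wild-type rate.
#' The first tail nucleotide is forced to differ from the next templated
#' nucleotide, since a matching base would by definition be a templated
#' extension, not a tail.
#'
#' @param config a [SimConfig-class]
#' @param family a [MiRNASet-class]
#' @param truth a [SimTruth-class] (flags the 3'-paired members)
#' @param genotype `"wild_type"` or `"decay_null"`
#' @return list with `reads` (DataFrame: mirna_id, read_seq, true_class) and
#'   `probs` (per-member trim/tail probabilities used)
#' @export
simulateIsoformReads <- function(config, family, truth,
                                 genotype = c("wild_type", "decay_null")) {
  genotype <- match.arg(genotype)
  stopifnot(is(config, "SimConfig"), is(truth, "SimTruth"))
  base_trim <- config@trim_prob[["wild_type"]]
  elev_trim <- config@trim_prob[[genotype]]
  tailp <- config@tail_prob[[genotype]]
  if (base_trim + tailp > 1 || elev_trim + tailp > 1) {
    stop("invalid config: trim_prob + tail_prob must be <= 1")
  }
  g <- guideRecords(family)
  members <- truth@members

  .withSeed(.deriveSeed(config@rng_seed, paste0("isoforms_", genotype)), {
    out <- list(); probs <- list()
    for (i in seq_len(nrow(g))) {
      id <- g$id[i]
      canon <- g$sequence[i]; context <- g$context[i]
      L <- nchar(canon)
      elevated <- genotype == config@tdtt_genotype &&
        id %in% members$id[members$is_3p_paired]
      trimp <- if (elevated) elev_trim else base_trim
      n <- round(config@reads_per_mirna)

      # independent trim/tail coins: the trimmed (resp. tailed) class
      # fraction, counting trimmed_tailed in both, is exactly trim_prob
      # (resp. tail_prob)
      do_trim <- stats::runif(n) < trimp
      do_tail <- stats::runif(n) < tailp
      trim_n <- ifelse(do_trim, sample(1:3, n, replace = TRUE), 0L)
      tail_n <- ifelse(do_tail, sample(1:3, n, replace = TRUE), 0L)

      body <- substring(canon, 1L, L - trim_n)
      next_templated <- ifelse(trim_n > 0,
                               substring(canon, L - trim_n + 1L, L - trim_n + 1L),
                               substr(context, 1L, 1L))
      tails <- vapply(seq_len(n), function(r) {
        if (tail_n[r] == 0L) return("")
        nts <- sample(names(TAIL_NT_PROBS), tail_n[r], replace = TRUE,
                      prob = TAIL_NT_PROBS)
        if (nts[1] == next_templated[r]) {
          nts[1] <- if (next_templated[r] == "U") "A" else "U"
        }
        paste(nts, collapse = "")
      }, character(1))

      cls <- ifelse(trim_n > 0 & tail_n > 0, "trimmed_tailed",
                    ifelse(trim_n > 0, "trimmed",
                           ifelse(tail_n > 0, "tailed", "canonical")))
      out[[id]] <- DataFrame(mirna_id = id, read_seq = paste0(body, tails),
                             true_class = cls)
      probs[[id]] <- DataFrame(mirna_id = id, trim_prob = trimp,
                               tail_prob = tailp, elevated = elevated)
    }
    list(reads = do.call(rbind, unname(out)),
         probs = do.call(rbind, unname(probs)))
  })
}
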