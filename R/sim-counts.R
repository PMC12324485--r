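#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Simulate a small-RNA count table for one genotype and stage
#'
#' Negative-binomial counts for a feature panel comprising the family guide
#' and passenger strands, background (non-family) guide miRNAs, a piRNA class
#' and a spike-in class. Expected fractions of the library are fixed per
#' feature (drawn once, deterministically, from the config seed, so every
#' genotype/stage table shares the same baseline means). The planted effects:
#' family guide means drop by each member's `decay_fold` between embryo and
#' L1 in wild type, and are restored (multiplied by `decay_fold`) at L1 in
#' null genotypes; passenger, piRNA and spike-in means are genotype- and
#' stage-independent. Per-replicate library sizes vary uniformly by +/- 15%.
#'
#' @param config a [SimConfig-class]
#' @param truth a [SimTruth-class] (per-member effective decay folds; in a
#'   retargeted design the stabilized set follows the truth, not the family)
#' @param genotype `"wild_type"` or `"decay_null"`
#' @param stage `"embryo"` or `"L1"`
#' @param n_background_guides,n_pirna,n_spikein panel sizes
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, rowData `class` (mirna_guide / mirna_passenger / pirna /
#'   spikein), and colData `genotype`, `stage`, `replicate`
#' @export
simulateCountTables <- function(config, truth,
                                genotype = c("wild_type", "decay_null"),
                                stage = c("embryo", "L1"),
                                n_background_guides = 50L, n_pirna = 60L,
                                n_spikein = 6L) {
  genotype <- match.arg(genotype); stage <- match.arg(stage)
  stopifnot(is(config, "SimConfig"), is(truth, "SimTruth"))
  members <- truth@members

  # fixed baseline panel, shared by all genotype/stage tables of this config
  base <- .withSeed(.deriveSeed(config@rng_seed, "count_means"), {
    fam_mean <- stats::rlnorm(nrow(members), log(2e4), 0.5)
    pass_mean <- fam_mean * stats::runif(nrow(members), 0.005, 0.02)
    bg_mean <- stats::rlnorm(n_background_guides, log(3e3), 1)
    pi_mean <- stats::rlnorm(n_pirna, log(5e3), 0.7)
    sp_mean <- stats::rlnorm(n_spikein, log(4e3), 0.3)
    list(fam = fam_mean, pass = pass_mean, bg = bg_mean, pi = pi_mean,
         sp = sp_mean)
  })

  fam <- base$fam
  if (stage == "L1") {
    fam <- fam / members$decay_fold            # EtoL1 decay in wild type
    if (genotype == "decay_null") fam <- fam * members$decay_fold
  }
  mu <- c(fam, base$pass, base$bg, base$pi, base$sp)
  ids <- c(members$id, paste0(members$id, "*"),
           sprintf("miR-bg%03d", seq_len(n_background_guides)),
           sprintf("piR-%03d", seq_len(n_pirna)),
           sprintf("spike-%02d", seq_len(n_spikein)))
  cls <- c(rep("mirna_guide", nrow(members)),
           rep("mirna_passenger", nrow(members)),
           rep("mirna_guide", n_background_guides),
           rep("pirna", n_pirna), rep("spikein", n_spikein))
  mu <- mu / sum(mu) * config@srna_depth

  .withSeed(.deriveSeed(config@rng_seed, paste0("counts_", genotype, "_", stage)), {
    reps <- config@n_replicates
    libsize <- stats::runif(reps, 0.85, 1.15)
    counts <- vapply(seq_len(reps), function(r) {
      stats::rnbinom(length(mu), mu = mu * libsize[r],
                     size = 1 / config@nb_dispersion)
    }, numeric(length(mu)))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(ids, sprintf("%s_%s_rep%d", genotype, stage,
                                          seq_len(reps)))
    SummarizedExperiment(
      assays = list(counts = counts),
      rowData = DataFrame(class = cls, row.names = ids),
      colData = DataFrame(genotype = rep(genotype, reps),
                          stage = rep(stage, reps),
                          replicate = seq_len(reps),
                          row.names = colnames(counts)))
  })
}

#' Combine count tables column-wise
#'
#' Binds SummarizedExperiments from [simulateCountTables()] (or any tables
#' sharing a feature panel) into one object, e.g. wild-type plus mutant
#' replicates ahead of [foldChanges()].
#'
#' @param ... SummarizedExperiments with identical rowData
#' @return a single SummarizedExperiment
#' @export
combineCountTables <- function(...) {
  do.call(BiocGenerics::cbind, list(...))
}
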