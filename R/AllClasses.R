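#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Simulation configuration for synthetic TDMD experiments
#'
#' Holds every tunable of the synthetic-data generator: the miRNA family
#' design, the trigger/decoy transcriptome, hybrid-library and small-RNA
#' library depths and noise, isomiR probabilities, and the qPCR / smFISH
#' measurement models. Construct with [simConfig()].
#'
#' @slot rng_seed master seed; every generator derives its own deterministic
#'   sub-stream from it, so identical configs give byte-identical outputs.
#' @slot family_size number of guide miRNAs sharing the seed (positions 2-8).
#' @slot mirna_length canonical miRNA length in nt.
#' @slot n_decoy_transcripts decoy transcripts beside the trigger lncRNA.
#' @slot decoy_site_fraction fraction of decoys carrying a conventional
#'   seed-only site.
#' @slot trigger_site1_3p_pairing per-member number of 3'-end positions
#'   complementary to trigger site 1; the member with the maximal count is the
#'   designated 3'-paired member and is planted exactly.
#' @slot trigger_site2_member index of the member with extensive 3' pairing at
#'   site 2.
#' @slot enrichment_lambda fold-enrichment of trigger hybrids in the
#'   decay-deficient genotype (>= 1; 1 disables enrichment).
#' @slot decay_fold per-member guide-strand stabilization (mutant/wt at L1).
#' @slot n_replicates replicates per genotype.
#' @slot hybrid_depth unique chimeric molecules per library.
#' @slot srna_depth expected total small-RNA counts per library.
#' @slot nb_dispersion negative-binomial dispersion of count noise.
#' @slot trim_prob,tail_prob named per-genotype isoform probabilities
#'   (names \code{wild_type}, \code{decay_null}).
#' @slot tdtt_genotype genotype in which trimming is elevated for 3'-paired
#'   members.
#' @slot pcr_duplication_mean mean extra PCR copies per unique molecule.
#' @slot background_fraction fraction of non-hybrid (target-only) reads.
#' @slot qpcr_efficiency,qpcr_ct_sd,qpcr_ct_at_one_copy amplification model:
#'   Ct = intercept + slope * log10(copies), slope = -1/log10(1+efficiency).
#' @slot spot_unit_intensity,spot_intensity_cv smFISH single-molecule
#'   intensity model.
#' @slot smfish_stage_fold planted fold difference in molecules per embryo
#'   between the late and the reference embryonic stage.
#' @slot reads_per_mirna isomiR reads simulated per guide.
#' @slot n_outsider_mirnas extra non-family guides (used for seed
#'   retargeting experiments).
#' @slot site1_seed_from id of the miRNA whose seed is complemented at trigger
#'   site 1 (\code{NA} = the shared family seed).
#' @export
setClass("SimConfig", representation(
  rng_seed = "integer",
  family_size = "integer",
  mirna_length = "integer",
  n_decoy_transcripts = "integer",
  decoy_site_fraction = "numeric",
  trigger_site1_3p_pairing = "numeric",
  trigger_site2_member = "integer",
  enrichment_lambda = "numeric",
  decay_fold = "numeric",
  n_replicates = "integer",
  hybrid_depth = "numeric",
  srna_depth = "numeric",
  nb_dispersion = "numeric",
  trim_prob = "numeric",
  tail_prob = "numeric",
  tdtt_genotype = "character",
  pcr_duplication_mean = "numeric",
  background_fraction = "numeric",
  qpcr_efficiency = "numeric",
  qpcr_ct_sd = "numeric",
  qpcr_ct_at_one_copy = "numeric",
  spot_unit_intensity = "numeric",
  spot_intensity_cv = "numeric",
  smfish_stage_fold = "numeric",
  reads_per_mirna = "numeric",
  n_outsider_mirnas = "integer",
  site1_seed_from = "character"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@family_size < 2L) msg <- c(msg, "family_size must be >= 2")
  if (object@mirna_length < 18L) msg <- c(msg, "mirna_length must be >= 18")
  if (object@enrichment_lambda < 1) {
    msg <- c(msg, "enrichment_lambda must be >= 1")
  }
  if (any(object@decay_fold < 1)) msg <- c(msg, "decay_fold must be >= 1 per member")
  probs <- c(object@decoy_site_fraction, object@trim_prob, object@tail_prob,
             object@background_fraction)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "all probabilities must lie in [0, 1]")
  for (g in names(object@trim_prob)) {
    if (object@trim_prob[[g]] + object@tail_prob[[g]] > 1) {
      msg <- c(msg, sprintf("trim_prob + tail_prob > 1 for genotype %s", g))
    }
  }
  if (length(object@trigger_site1_3p_pairing) != object@family_size) {
    msg <- c(msg, "trigger_site1_3p_pairing must have one entry per member")
  }
  if (length(object@decay_fold) != object@family_size) {
    msg <- c(msg, "decay_fold must have one entry per member")
  }
  if (object@trigger_site2_member < 1L ||
      object@trigger_site2_member > object@family_size) {
    msg <- c(msg, "trigger_site2_member out of range")
  }
  if (object@qpcr_efficiency <= 0 || object@qpcr_efficiency > 1.2) {
    msg <- c(msg, "qpcr_efficiency must lie in (0, 1.2]")
  }
  if (object@hybrid_depth <= 0 || object@srna_depth <= 0) {
    msg <- c(msg, "library depths must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth planted by the synthetic-data generator
#'
#' Records everything a downstream module should be able to recover: the
#' trigger transcript and its two binding-site spans, the per-member decay
#' folds and isoform probabilities, the chimeric interaction table used as
#' sampling weights, and the true copy numbers behind the quantification
#' fixtures.
#'
#' @slot trigger_id id of the planted trigger lncRNA.
#' @slot sites [GenomicRanges::GRanges] on transcript coordinates (1-based)
#'   with metadata \code{site_id} and \code{kind}.
#' @slot members per-member truth table (decay fold, 3'-pairing, degradation
#'   status, trim probabilities).
#' @slot interactions chimeric sampling-weight table (member x site, duplex
#'   score, trigger flag).
#' @slot decoy_sites planted conventional decoy sites.
#' @slot quant true values behind the qPCR / smFISH fixtures.
#' @export
setClass("SimTruth", representation(
  trigger_id = "character",
  sites = "ANY",
  members = "DataFrame",
  interactions = "DataFrame",
  decoy_sites = "DataFrame",
  quant = "list"
))

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth: trigger", object@trigger_id, "with",
      length(object@sites), "planted sites;",
      nrow(object@members), "family members;",
      nrow(object@interactions), "chimeric interactions\n")
})

#' A set of miRNA records (guides and passengers)
#'
#' Container for guide/passenger small-RNA annotations: sequence, strand role,
#' family membership, canonical length and the genomic context immediately 3'
#' of the locus (used by the isomiR decomposition to distinguish templated
#' extensions from untemplated tails).
#'
#' @slot records a [S4Vectors::DataFrame] with columns \code{id},
#'   \code{sequence}, \code{role} (guide/passenger), \code{family_id},
#'   \code{canonical_length}, \code{context}.
#' @export
setClass("MiRNASet", representation(records = "DataFrame"))

setValidity("MiRNASet", function(object) {
  rec <- object@records
  need <- c("id", "sequence", "role", "family_id", "canonical_length", "context")
  if (!all(need %in% colnames(rec))) {
    return(paste("missing columns:", paste(setdiff(need, colnames(rec)), collapse = ", ")))
  }
  if (any(nchar(rec$sequence) < 18L)) return("all sequences must be >= 18 nt")
  if (any(grepl("[^ACGU]", rec$sequence))) return("sequences must use the RNA alphabet A/C/G/U")
  if (!all(rec$role %in% c("guide", "passenger"))) return("role must be guide or passenger")
  if (anyDuplicated(rec$id)) return("miRNA ids must be unique")
  TRUE
})

setMethod("show", "MiRNASet", function(object) {
  rec <- object@records
  cat("MiRNASet with", sum(rec$role == "guide"), "guides and",
      sum(rec$role == "passenger"), "passengers in",
      length(unique(rec$family_id)), "family/families\n")
})

setMethod("length", "MiRNASet", function(x) nrow(x@records))

#' @describeIn MiRNASet-class access the underlying record table
#' @param x a `MiRNASet`
#' @export
mirnaRecords <- function(x) x@records

#' @describeIn MiRNASet-class guide-strand records only
#' @export
guideRecords <- function(x) x@records[x@records$role == "guide", , drop = FALSE]

#' @describeIn MiRNASet-class passenger-strand records only
#' @export
passengerRecords <- function(x) x@records[x@records$role == "passenger", , drop = FALSE]

#' Per-sample table of miRNA-target hybrid interactions
#'
#' One row per (miRNA, transcript, binding site) with its raw hybrid read
#' count and its RPM, i.e. reads per million *total accepted hybrids* in the
#' sample. The per-sample RPM column always sums to 1e6.
#'
#' @slot pairs DataFrame with columns \code{mirna_id}, \code{transcript_id},
#'   \code{site_id}, \code{start}, \code{end} (0-based half-open target span
#'   of the site, NA when untabulated), \code{count}, \code{rpm}.
#' @slot sample_id sample label.
#' @slot total_hybrids number of accepted hybrid reads in the sample.
#' @export
setClass("HybridTable", representation(
  pairs = "DataFrame",
  sample_id = "character",
  total_hybrids = "integer"
))

setValidity("HybridTable", function(object) {
  p <- object@pairs
  need <- c("mirna_id", "transcript_id", "site_id", "count", "rpm")
  if (!all(need %in% colnames(p))) {
    return(paste("missing columns:", paste(setdiff(need, colnames(p)), collapse = ", ")))
  }
  if (any(p$count < 0) || any(p$count != round(p$count))) {
    return("counts must be non-negative integers")
  }
  if (nrow(p) > 0 && abs(sum(p$rpm) - 1e6) > 1e-3) {
    return(sprintf("rpm must sum to 1e6 per sample (got %.3f)", sum(p$rpm)))
  }
  TRUE
})

setMethod("show", "HybridTable", function(object) {
  cat("HybridTable '", object@sample_id, "': ", nrow(object@pairs),
      " interaction rows over ", object@total_hybrids, " total hybrids\n", sep = "")
})

#' @describeIn HybridTable-class interaction rows as a DataFrame
#' @param x a `HybridTable`
#' @export
hybridPairs <- function(x) x@pairs

#' @describeIn HybridTable-class total accepted hybrid reads in the sample
#' @export
totalHybrids <- function(x) x@total_hybrids

#' Predicted intermolecular miRNA:target duplex
#'
#' The maximum-score non-crossing base-pair set between a miRNA (positions
#' numbered 1..n from the 5' end, "g" numbering) and a target window, as
#' returned by [predictDuplex()]. Target positions are 1-based within the
#' window; \code{target_offset} locates the window on its transcript
#' (0-based).
#'
#' @slot mirna_id,mirna_seq,target_seq identifiers and sequences (5'->3').
#' @slot target_offset 0-based transcript coordinate of window position 1.
#' @slot pairs integer matrix with columns \code{g} and \code{t}; antiparallel,
#'   so \code{t} strictly decreases as \code{g} increases.
#' @slot pair_kinds "WC" or "GU" per pair.
#' @slot score dimensionless alignment score.
#' @slot structure two-element character: pairing masks ('|' paired, '.'
#'   unpaired) for the miRNA and the target window.
#' @export
setClass("Duplex", representation(
  mirna_id = "character",
  mirna_seq = "character",
  target_seq = "character",
  target_offset = "integer",
  pairs = "matrix",
  pair_kinds = "character",
  score = "numeric",
  structure = "character"
))

setValidity("Duplex", function(object) {
  p <- object@pairs
  if (nrow(p) > 1) {
    o <- order(p[, "g"])
    if (any(diff(p[o, "t"]) >= 0)) {
      return("pairs must be non-crossing: t strictly decreasing in g")
    }
  }
  if (anyDuplicated(p[, "g"]) || anyDuplicated(p[, "t"])) {
    return("each position may occur in at most one pair")
  }
  TRUE
})

setMethod("show", "Duplex", function(object) {
  cat("Duplex ", object@mirna_id, " vs target window (", nchar(object@target_seq),
      " nt): ", nrow(object@pairs), " pairs, score ", object@score, "\n",
      "  miRNA  5' ", object@structure[1], " 3'\n",
      "  target 3' ", paste(rev(strsplit(object@structure[2], "")[[1]]), collapse = ""),
      " 5'\n", sep = "")
})

#' @describeIn Duplex-class the base-pair matrix (columns g, t)
#' @param x a `Duplex`
#' @export
duplexPairs <- function(x) x@pairs

#' @describeIn Duplex-class the duplex score
#' @export
duplexScore <- function(x) x@score

#' Pairing-architecture classification of a duplex
#'
#' Region-wise pair counts and the derived seed-match class and
#' TDTT-proneness flag, from [classifyArchitecture()]. Regions: seed g2-g8,
#' central g9-g12, supplemental g13-g16, tail g17-end.
#'
#' @slot seed_match one of perfect_2_8, offset_3_8, partial, none.
#' @slot n_seed_pairs,n_central_pairs,n_supplemental_pairs,n_tail_pairs
#'   per-region pair counts (g1 pairs are counted in none of the regions).
#' @slot three_prime_extent paired positions in g9..end.
#' @slot tdtt_prone TRUE when the miRNA 3' extremity is engaged enough to
#'   predict target-directed tailing/trimming.
#' @export
setClass("PairingArchitecture", representation(
  seed_match = "character",
  n_seed_pairs = "integer",
  n_central_pairs = "integer",
  n_supplemental_pairs = "integer",
  n_tail_pairs = "integer",
  three_prime_extent = "integer",
  tdtt_prone = "logical"
))

setMethod("show", "PairingArchitecture", function(object) {
  cat("PairingArchitecture:", object@seed_match,
      sprintf("(seed %d, central %d, supplemental %d, tail %d; 3' extent %d; tdtt_prone %s)\n",
              object@n_seed_pairs, object@n_central_pairs,
              object@n_supplemental_pairs, object@n_tail_pairs,
              object@three_prime_extent, object@tdtt_prone))
})

#' qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(input copies), with amplification
#' efficiency derived from the slope: efficiency = 10^(-1/slope) - 1.
#'
#' @slot slope Ct per log10 copies (negative).
#' @slot intercept Ct at one copy.
#' @slot efficiency amplification efficiency in (0, 1.2].
#' @slot r_squared coefficient of determination of the fit.
#' @slot n_points number of dilution points fitted.
#' @export
setClass("StandardCurve", representation(
  slope = "numeric",
  intercept = "numeric",
  efficiency = "numeric",
  r_squared = "numeric",
  n_points = "integer"
))

setValidity("StandardCurve", function(object) {
  if (object@slope >= 0) return("slope must be negative")
  if (object@efficiency <= 0 || object@efficiency > 1.2) {
    return("efficiency must lie in (0, 1.2]")
  }
  if (object@n_points < 4L) return("a standard curve needs >= 4 dilution points")
  TRUE
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: slope %.4f, intercept %.2f, efficiency %.3f, R^2 %.4f (%d points)\n",
              object@slope, object@intercept, object@efficiency,
              object@r_squared, object@n_points))
})
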