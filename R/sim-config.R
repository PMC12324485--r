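#' Build a simulation configuration
#'
#' Creates a validated [SimConfig-class] describing one synthetic TDMD
#' experiment: an 8-member miRNA family sharing positions 2-8, a trigger
#' lncRNA carrying a perfect-seed site (site 1) and an offset 3-8 seed site
#' with extensive 3' pairing for one member (site 2), hybrid libraries in
#' wild-type vs decay-deficient genotypes, stage/genotype count tables with
#' stabilized guides and unchanged passengers, isomiR reads, and qPCR/smFISH
#' quantification fixtures.
#'
#' Per-member defaults scale with `family_size`: member 1 is the designated
#' 3'-paired member at site 1 (12 complementary positions), all members share
#' a 7.1-fold guide stabilization in the decay-deficient genotype, and member
#' 3 carries the extensive 3' pairing at site 2.
#'
#' @param rng_seed master integer seed; every generator derives its own
#'   deterministic sub-stream, so equal configs give byte-identical outputs.
#' @param family_size,mirna_length family design (>= 2 members, >= 18 nt).
#' @param n_decoy_transcripts,decoy_site_fraction decoy transcriptome design.
#' @param trigger_site1_3p_pairing per-member 3'-complementarity at site 1.
#' @param trigger_site2_member member with extensive 3' pairing at site 2.
#' @param enrichment_lambda trigger-hybrid fold enrichment in the
#'   decay-deficient genotype (>= 1).
#' @param decay_fold per-member (or scalar, recycled) guide stabilization.
#' @param n_replicates replicates per genotype.
#' @param hybrid_depth unique chimeric molecules per library.
#' @param srna_depth expected small-RNA counts per library.
#' @param nb_dispersion negative-binomial dispersion of count noise.
#' @param trim_prob,tail_prob named per-genotype probabilities
#'   (`wild_type`, `decay_null`); `trim_prob["decay_null"]` applies only to
#'   3'-paired members (others keep the wild-type rate).
#' @param tdtt_genotype genotype with elevated trimming for 3'-paired members.
#' @param pcr_duplication_mean mean extra PCR copies per molecule.
#' @param background_fraction fraction of non-hybrid target-only reads.
#' @param qpcr_efficiency,qpcr_ct_sd,qpcr_ct_at_one_copy qPCR model.
#' @param spot_unit_intensity,spot_intensity_cv,smfish_stage_fold smFISH model.
#' @param reads_per_mirna isomiR reads per guide.
#' @param n_outsider_mirnas extra non-family guides with their own seed.
#' @param site1_seed_from miRNA id whose seed is complemented at site 1
#'   (default `NA`: the shared family seed), used for retargeting experiments.
#' @return a validated [SimConfig-class]
#' @examples
#' cfg <- simConfig(rng_seed = 1, family_size = 8)
#' cfg
#' @export
simConfig <- function(rng_seed = 1L,
                      family_size = 8L,
                      mirna_length = 22L,
                      n_decoy_transcripts = 50L,
                      decoy_site_fraction = 0.6,
                      trigger_site1_3p_pairing = NULL,
                      trigger_site2_member = NULL,
                      enrichment_lambda = 4,
                      decay_fold = 7.1,
                      n_replicates = 3L,
                      hybrid_depth = 2e5,
                      srna_depth = 1e6,
                      nb_dispersion = 0.05,
                      trim_prob = c(wild_type = 0.05, decay_null = 0.2),
                      tail_prob = c(wild_type = 0.1, decay_null = 0.1),
                      tdtt_genotype = "decay_null",
                      pcr_duplication_mean = 0.3,
                      background_fraction = 0.1,
                      qpcr_efficiency = 0.95,
                      qpcr_ct_sd = 0.15,
                      qpcr_ct_at_one_copy = 40,
                      spot_unit_intensity = 1000,
                      spot_intensity_cv = 0.15,
                      smfish_stage_fold = 37.6,
                      reads_per_mirna = 1e4,
                      n_outsider_mirnas = 0L,
                      site1_seed_from = NA_character_) {
  if (family_size < 2L) stop("invalid config: family_size must be >= 2")
  if (mirna_length < 18L) stop("invalid config: mirna_length must be >= 18")
  if (is.null(trigger_site1_3p_pairing)) {
    trigger_site1_3p_pairing <- c(12, rep(0, family_size - 1L))
  }
  if (is.null(trigger_site2_member)) {
    trigger_site2_member <- min(3L, family_size)
  }
  decay_fold <- rep_len(decay_fold, family_size)
  new("SimConfig",
      rng_seed = as.integer(rng_seed),
      family_size = as.integer(family_size),
      mirna_length = as.integer(mirna_length),
      n_decoy_transcripts = as.integer(n_decoy_transcripts),
      decoy_site_fraction = decoy_site_fraction,
      trigger_site1_3p_pairing = trigger_site1_3p_pairing,
      trigger_site2_member = as.integer(trigger_site2_member),
      enrichment_lambda = enrichment_lambda,
      decay_fold = decay_fold,
      n_replicates = as.integer(n_replicates),
      hybrid_depth = hybrid_depth,
      srna_depth = srna_depth,
      nb_dispersion = nb_dispersion,
      trim_prob = trim_prob,
      tail_prob = tail_prob,
      tdtt_genotype = tdtt_genotype,
      pcr_duplication_mean = pcr_duplication_mean,
      background_fraction = background_fraction,
      qpcr_efficiency = qpcr_efficiency,
      qpcr_ct_sd = qpcr_ct_sd,
      qpcr_ct_at_one_copy = qpcr_ct_at_one_copy,
      spot_unit_intensity = spot_unit_intensity,
      spot_intensity_cv = spot_intensity_cv,
      smfish_stage_fold = smfish_stage_fold,
      reads_per_mirna = reads_per_mirna,
      n_outsider_mirnas = as.integer(n_outsider_mirnas),
      site1_seed_from = site1_seed_from)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@family_size, "member family,",
      object@n_decoy_transcripts, "decoys, lambda =", object@enrichment_lambda,
      ", decay_fold =", paste(unique(object@decay_fold), collapse = "/"),
      ", seed =", object@rng_seed, "\n")
})
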