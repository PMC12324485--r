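#' Simulate absolute-quantification fixtures (qPCR and smFISH)
#'
#' qPCR: standards spanning six decades (10^2..10^8 copies, triplicate) and
#' triplicate samples for the reference guide miRNA, the trigger lncRNA in L1
#' RNA, and the trigger in a mixed-stage embryo sample, under the model
#' `Ct = intercept + slope * log10(copies) + Normal(0, qpcr_ct_sd)` with
#' `slope = -1/log10(1 + qpcr_efficiency)`. The mixed embryo sample's true
#' concentration is the planted peak concentration attenuated by the planted
#' stage mixture, `sum(w_s * r_s)`, so the peak is recoverable by
#' deconvolution.
#'
#' smFISH: integrated spot intensities `Normal(k * unit, cv * k * unit)` where
#' the per-spot molecule count k is 1 for every reference-stage (bean) spot
#' and follows a planted k-mixture at the late (pretzel) stage; per-embryo
#' spot numbers are Poisson with stage-dependent means chosen so mean
#' molecules per embryo differ by the planted `smfish_stage_fold`.
#'
#' @param config a [SimConfig-class]
#' @param truth a [SimTruth-class]; `truth@quant` holds the planted values
#' @param noise_free set the Ct noise and intensity CV to 0 (round-trip tests)
#' @return list with `standards` (species, copies, ct), `samples` (species,
#'   ct, input_ng), `spots` (embryo_id, stage, spot_id, intensity, true_k)
#'   and `truth` (planted quantities, including the late-stage k-mixture)
#' @export
simulateQuantData <- function(config, truth, noise_free = FALSE) {
  stopifnot(is(config, "SimConfig"), is(truth, "SimTruth"))
  eff <- config@qpcr_efficiency
  if (eff <= 0 || eff > 1.2) stop("invalid config: qpcr_efficiency must lie in (0, 1.2]")
  slope <- -1 / log10(1 + eff)
  intercept <- config@qpcr_ct_at_one_copy
  sd_ct <- if (noise_free) 0 else config@qpcr_ct_sd
  cv <- if (noise_free) 0 else config@spot_intensity_cv
  q <- truth@quant

  .withSeed(.deriveSeed(config@rng_seed, "quant"), {
    std_copies <- rep(10^(2:8), each = 3)
    standards <- rbind(
      DataFrame(species = "guide_ref", role = "standard", copies = std_copies,
                ct = intercept + slope * log10(std_copies) +
                  stats::rnorm(length(std_copies), 0, sd_ct)),
      DataFrame(species = "trigger", role = "standard", copies = std_copies,
                ct = intercept + slope * log10(std_copies) +
                  stats::rnorm(length(std_copies), 0, sd_ct)))

    mix_atten <- sum(q$stage_weights * q$stage_profile)
    sample_def <- DataFrame(
      species = c("guide_ref", "trigger", "trigger_embryo_mix"),
      copies_per_ng = c(q$copies_per_ng[["guide"]], q$copies_per_ng[["trigger"]],
                        q$peak_copies * mix_atten))
    rows <- lapply(seq_len(nrow(sample_def)), function(i) {
      copies_rxn <- sample_def$copies_per_ng[i] * q$input_ng
      DataFrame(species = sample_def$species[i], role = "sample",
                copies = NA_real_,
                ct = intercept + slope * log10(copies_rxn) +
                  stats::rnorm(3, 0, sd_ct))
    })
    samples <- do.call(rbind, rows)
    samples$input_ng <- q$input_ng

    # smFISH spot tables
    k_mix <- c(`1` = 0.45, `2` = 0.3, `3` = 0.15, `4` = 0.1)
    mean_k_late <- sum(as.integer(names(k_mix)) * k_mix)
    n_embryos <- 10L
    unit <- config@spot_unit_intensity
    mkStage <- function(stage, spots_mean, ks_sampler) {
      rows <- lapply(seq_len(n_embryos), function(e) {
        ns <- stats::rpois(1, spots_mean)
        k <- ks_sampler(ns)
        DataFrame(embryo_id = sprintf("%s_e%02d", stage, e), stage = stage,
                  spot_id = seq_len(ns),
                  intensity = stats::rnorm(ns, k * unit, cv * k * unit),
                  true_k = k)
      })
      do.call(rbind, rows)
    }
    spots_ref_mean <- q$spots_mean_reference
    spots_late_mean <- spots_ref_mean * q$stage_fold / mean_k_late
    spots <- rbind(
      mkStage("bean", spots_ref_mean, function(n) rep(1L, n)),
      mkStage("pretzel", spots_late_mean, function(n) {
        as.integer(sample(names(k_mix), n, replace = TRUE, prob = k_mix))
      }))

    list(standards = standards, samples = samples, spots = spots,
         truth = c(q, list(slope = slope, intercept = intercept,
                           efficiency = eff, k_mix_late = k_mix,
                           mixed_copies = q$peak_copies * mix_atten,
                           molecules_per_embryo = c(
                             bean = spots_ref_mean,
                             pretzel = spots_ref_mean * q$stage_fold))))
  })
}
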