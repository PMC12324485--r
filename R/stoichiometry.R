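#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(input copies). Requires at least 4
#' dilution points spanning at least 3 decades. The amplification efficiency
#' is `10^(-1/slope) - 1` (a perfect doubling per cycle gives slope -3.3219
#' and efficiency 1).
#'
#' @param dilution_copies input copies per reaction of each standard (> 0).
#' @param ct_values measured Ct values (same length).
#' @return a [StandardCurve-class]
#' @examples
#' copies <- 10^(3:8)
#' fitStandardCurve(copies, 40 - 3.3219 * log10(copies))
#' @export
fitStandardCurve <- function(dilution_copies, ct_values) {
  if (length(dilution_copies) != length(ct_values)) {
    stop("dilution_copies and ct_values must have equal length")
  }
  if (any(dilution_copies <= 0)) stop("standard copies must be positive")
  if (length(unique(dilution_copies)) < 4L) {
    stop("precondition error: a standard curve needs >= 4 dilution points")
  }
  lx <- log10(dilution_copies)
  if (diff(range(lx)) < 3) {
    stop("precondition error: standards must span >= 3 decades")
  }
  fit <- stats::lm(ct_values ~ lx)
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) stop("curve-quality error: non-negative slope")
  ss_tot <- sum((ct_values - mean(ct_values))^2)
  rsq <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  new("StandardCurve", slope = slope, intercept = intercept,
      efficiency = 10^(-1 / slope) - 1,
      r_squared = rsq,
      n_points = length(unique(dilution_copies)))
}

#' Absolute copy number from a Ct value
#'
#' Inverts the standard curve: `copies_per_reaction = 10^((ct - intercept) /
#' slope)`, reported per ng of input RNA.
#'
#' @param ct Ct value(s); must be finite.
#' @param curve a [StandardCurve-class].
#' @param input_ng ng of total RNA per reaction (> 0).
#' @return copies per ng (vectorized over `ct`)
#' @export
quantifyCopies <- function(ct, curve, input_ng) {
  stopifnot(is(curve, "StandardCurve"))
  if (any(!is.finite(ct))) stop("input error: non-finite Ct value")
  if (input_ng <= 0) stop("input_ng must be positive")
  10^((ct - curve@intercept) / curve@slope) / input_ng
}

#' Excess family molecules in the decay-deficient state
#'
#' Extrapolates the total stabilized molecules across a miRNA family from the
#' absolute quantification of one reference member, the known per-member
#' abundance ratios relative to that member, and the per-member mutant/wt
#' fold changes: `excess = sum_i ratio_i * ref_copies_wt * (FC_i - 1)`
#' (copies per ng).
#'
#' @param ref_copies_wt wild-type copies/ng of the reference member.
#' @param member_ratios named per-member abundance relative to the reference
#'   (reference itself = 1; all > 0).
#' @param fold_changes named per-member mutant/wild-type fold changes (>= 0);
#'   names must cover `member_ratios`.
#' @return excess copies per ng (numeric scalar)
#' @export
excessFamilyMolecules <- function(ref_copies_wt, member_ratios, fold_changes) {
  if (any(member_ratios <= 0)) stop("member ratios must be positive")
  missing <- setdiff(names(member_ratios), names(fold_changes))
  if (length(missing)) {
    stop("input error: missing fold change for member(s) ",
         paste(missing, collapse = ", "))
  }
  fc <- fold_changes[names(member_ratios)]
  if (any(fc < 0)) stop("fold changes must be >= 0")
  sum(member_ratios * ref_copies_wt * (fc - 1))
}

#' Molecules degraded per trigger molecule
#'
#' The potency of a TDMD trigger: excess stabilized miRNA molecules per ng
#' divided by trigger copies per ng. Reported raw and rounded for
#' presentation (nearest integer for ratios >= 20, one decimal below 20).
#'
#' @param excess_copies_per_ng excess miRNA molecules per ng.
#' @param trigger_copies_per_ng trigger molecules per ng (> 0).
#' @return list with `ratio` (raw) and `rounded`
#' @examples
#' moleculesPerTrigger(6.39e6, 89836)$rounded   # ~71
#' @export
moleculesPerTrigger <- function(excess_copies_per_ng, trigger_copies_per_ng) {
  if (trigger_copies_per_ng <= 0) stop("input error: trigger copies must be positive")
  ratio <- excess_copies_per_ng / trigger_copies_per_ng
  list(ratio = ratio,
       rounded = if (abs(ratio) >= 20) round(ratio) else round(ratio, 1))
}

#' Peak expression from a stage-mixed measurement
#'
#' A measurement on a mixed-stage sample underestimates the peak when some
#' stages express below peak. Given mixture weights `w_s` (summing to 1) and
#' the relative temporal profile `r_s` (expression relative to peak, peak =
#' 1), the peak is `measured / sum(w_s * r_s)`; the estimate is never below
#' the measurement when all `r_s <= 1`.
#'
#' @param measured_mixed measured copies/ng in the mixed sample.
#' @param weights stage mixture weights (sum to 1 within 1e-6).
#' @param relative_profile per-stage expression relative to peak, in [0, 1].
#' @return peak copies/ng
#' @export
estimatePeakCopies <- function(measured_mixed, weights, relative_profile) {
  if (abs(sum(weights) - 1) > 1e-6) stop("stage weights must sum to 1")
  atten <- sum(weights * relative_profile)
  if (atten == 0) stop("degenerate-mixture error: sum(w * r) is zero")
  measured_mixed / atten
}

#' smFISH spot intensities to molecule counts
#'
#' Calibrates the single-molecule unit intensity as the median integrated
#' intensity of reference-stage spots (where essentially all foci are single
#' molecules), bins each spot to `max(1, round(intensity / unit))` molecules,
#' and totals molecules per embryo. When the sample covers two stages, the
#' stage fold change (ratio of mean per-embryo totals) is reported.
#'
#' @param reference_spot_intensities numeric vector of reference-stage
#'   integrated intensities (>= 20 spots).
#' @param sample_spot_table data.frame/DataFrame with columns `embryo_id`,
#'   `stage`, `intensity`.
#' @param fold_contrast optional length-2 character `c(denominator_stage,
#'   numerator_stage)`; default: first two stages in order of appearance.
#' @return list with `unit_intensity`, `spots` (per-spot molecule calls),
#'   `embryos` (per-embryo totals), `stage_means`, `stage_fold`
#' @export
smfishMoleculeCounts <- function(reference_spot_intensities, sample_spot_table,
                                 fold_contrast = NULL) {
  if (length(reference_spot_intensities) < 20L) {
    stop("calibration error: need >= 20 reference spots")
  }
  unit <- stats::median(reference_spot_intensities)
  if (unit <= 0) stop("calibration error: non-positive unit intensity")
  tab <- as.data.frame(sample_spot_table)
  molecules <- pmax(1L, as.integer(round(tab$intensity / unit)))
  per_embryo <- rowsum(molecules, tab$embryo_id)
  stage_of <- tab$stage[match(rownames(per_embryo), tab$embryo_id)]
  embryos <- data.frame(embryo_id = rownames(per_embryo),
                        stage = stage_of, molecules = per_embryo[, 1],
                        row.names = NULL)
  stage_means <- tapply(embryos$molecules, embryos$stage, mean)
  fold <- NA_real_
  stages <- unique(tab$stage)
  if (is.null(fold_contrast) && length(stages) >= 2L) {
    fold_contrast <- stages[1:2]
  }
  if (!is.null(fold_contrast)) {
    fold <- unname(stage_means[[fold_contrast[2]]] / stage_means[[fold_contrast[1]]])
  }
  list(unit_intensity = unit,
       spots = data.frame(embryo_id = tab$embryo_id, stage = tab$stage,
                          intensity = tab$intensity, molecules = molecules),
       embryos = embryos,
       stage_means = stage_means,
       stage_fold = fold)
}
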