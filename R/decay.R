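#' Per-sample size factors from a normalizer class
#'
#' Size factors are the per-sample totals of the chosen normalizer class
#' (total mapped reads, the piRNA class, or spike-ins) divided by their
#' geometric mean across samples, so the factors multiply to 1 in geometric
#' mean and normalized counts are `count / factor`.
#'
#' @param se a SummarizedExperiment count table (see [simulateCountTables()]).
#' @param normalizer_class `"total"`, `"pirna"` or `"spikein"`.
#' @return named numeric vector of per-sample factors.
#' @export
computeSizeFactors <- function(se, normalizer_class = c("total", "pirna", "spikein")) {
  normalizer_class <- match.arg(normalizer_class)
  counts <- SummarizedExperiment::assay(se, "counts")
  sel <- if (normalizer_class == "total") rep(TRUE, nrow(counts)) else
    SummarizedExperiment::rowData(se)$class == normalizer_class
  totals <- colSums(counts[sel, , drop = FALSE])
  zero <- totals == 0
  if (any(zero)) {
    stop("normalization error: zero ", normalizer_class, " total in sample(s) ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  totals / .geomMean(totals)
}

#' Normalized counts under a size-factor model
#' @inheritParams computeSizeFactors
#' @return matrix of `count / factor`
#' @export
normalizedCounts <- function(se, normalizer_class = "total") {
  f <- computeSizeFactors(se, normalizer_class)
  sweep(SummarizedExperiment::assay(se, "counts"), 2, f, "/")
}

#' Fold changes with a permutation test
#'
#' Normalizes the contrast samples, filters features by mean normalized count
#' (`base_mean >= base_mean_min`), and computes
#' `log2fc = log2((mean_b + c) / (mean_a + c))` with pseudocount `c`. The
#' permutation p-value is the fraction of distinct group-label assignments
#' (all of them when there are at most `max_exact` = 5040, otherwise `n_perm`
#' random ones under a fixed seed) whose |log2fc| reaches the observed value;
#' q-values are Benjamini-Hochberg. With fewer than 2 replicates in a group
#' the p-value is omitted (NA).
#'
#' @param se SummarizedExperiment with a `genotype` (or other) grouping
#'   column in colData.
#' @param contrast length-2 character `c(group_a, group_b)`; log2fc is b vs a.
#' @param group_col colData column holding the group labels.
#' @param normalizer_class passed to [computeSizeFactors()].
#' @param pseudocount pseudocount c on normalized means.
#' @param base_mean_min baseMean filter (mean normalized count across the
#'   contrast samples).
#' @param n_perm random permutations when exhaustive enumeration exceeds
#'   `max_exact`.
#' @param perm_seed seed for the random-permutation fallback.
#' @param max_exact largest number of distinct label assignments enumerated
#'   exhaustively.
#' @return DataFrame: `feature_id`, `class`, `base_mean`, `log2fc`, `p_perm`,
#'   `q`.
#' @export
foldChanges <- function(se, contrast, group_col = "genotype",
                        normalizer_class = "total", pseudocount = 0.5,
                        base_mean_min = 10, n_perm = 1e4, perm_seed = 20231L,
                        max_exact = 5040L) {
  groups <- SummarizedExperiment::colData(se)[[group_col]]
  sel <- groups %in% contrast
  if (!any(groups == contrast[1]) || !any(groups == contrast[2])) {
    stop("input error: both contrast groups must be present in '", group_col, "'")
  }
  sub <- se[, sel]
  groups <- groups[sel]
  norm <- normalizedCounts(sub, normalizer_class)
  base_mean <- rowMeans(norm)
  keep <- base_mean >= base_mean_min
  norm <- norm[keep, , drop = FALSE]

  is_b <- groups == contrast[2]
  statOf <- function(bmask) {
    log2((rowMeans(norm[, bmask, drop = FALSE]) + pseudocount) /
           (rowMeans(norm[, !bmask, drop = FALSE]) + pseudocount))
  }
  obs <- statOf(is_b)

  n <- length(groups); nb <- sum(is_b)
  p <- rep(NA_real_, length(obs))
  if (nb >= 2L && (n - nb) >= 2L) {
    n_assign <- choose(n, nb)
    masks <- if (n_assign <= max_exact) {
      combos <- utils::combn(n, nb)
      lapply(seq_len(ncol(combos)), function(i) {
        m <- rep(FALSE, n); m[combos[, i]] <- TRUE; m
      })
    } else {
      .withSeed(perm_seed, lapply(seq_len(n_perm), function(i) {
        m <- rep(FALSE, n); m[sample.int(n, nb)] <- TRUE; m
      }))
    }
    hits <- rep(0L, length(obs))
    for (m in masks) hits <- hits + (abs(statOf(m)) >= abs(obs) - 1e-12)
    p <- hits / length(masks)
  }

  DataFrame(feature_id = rownames(norm),
            class = SummarizedExperiment::rowData(sub)$class[keep],
            base_mean = base_mean[keep], log2fc = obs, p_perm = p,
            q = stats::p.adjust(p, method = "BH"))
}

#' Embryo-to-L1 decay amplitude
#'
#' Per-feature `log2(normalized L1 mean / normalized embryo mean)` with both
#' stages normalized by the same normalizer class (negative = decay across
#' the transition). Features missing from either stage are flagged rather
#' than dropped.
#'
#' @param se_embryo,se_l1 SummarizedExperiments for the two stages.
#' @param features feature ids to report (default: union of both).
#' @param normalizer_class shared normalizer.
#' @param pseudocount pseudocount on normalized means.
#' @return DataFrame: `feature_id`, `amplitude`, `missing_stage`.
#' @export
decayAmplitude <- function(se_embryo, se_l1, features = NULL,
                           normalizer_class = "total", pseudocount = 0.5) {
  ne <- rowMeans(normalizedCounts(se_embryo, normalizer_class))
  nl <- rowMeans(normalizedCounts(se_l1, normalizer_class))
  if (is.null(features)) features <- union(names(ne), names(nl))
  e <- ne[features]; l <- nl[features]
  missing <- is.na(e) | is.na(l)
  amp <- log2((l + pseudocount) / (e + pseudocount))
  amp[missing] <- NA_real_
  DataFrame(feature_id = features, amplitude = unname(amp),
            missing_stage = unname(missing))
}

#' Decay-level versus biogenesis-level inference from strand contrast
#'
#' A guide-strand increase without a matching passenger-strand increase
#' indicates an effect at the level of decay (the passenger, a biogenesis
#' byproduct, reports on transcription/processing): `decay_level` when the
#' guide fold change is at least `fc_min` with q < 0.05 and the passenger
#' fold change stays below `passenger_max`; `biogenesis_level` when both
#' strands rise at least `fc_min` with q < 0.05; otherwise `no_call`.
#'
#' @param guide_fc,passenger_fc single rows of [foldChanges()] output for the
#'   two strands of one miRNA, from the same contrast.
#' @param fc_min minimum fold change (ratio scale).
#' @param passenger_max maximum passenger fold change (ratio scale) compatible
#'   with a decay-level call.
#' @return `"decay_level"`, `"biogenesis_level"` or `"no_call"`.
#' @export
strandLevelInference <- function(guide_fc, passenger_fc, fc_min = 1.5,
                                 passenger_max = 1.3) {
  g_fc <- 2^guide_fc$log2fc; p_fc <- 2^passenger_fc$log2fc
  g_sig <- isTRUE(guide_fc$q < 0.05)
  p_sig <- isTRUE(passenger_fc$q < 0.05)
  if (g_sig && g_fc >= fc_min && p_fc < passenger_max) "decay_level"
  else if (g_sig && p_sig && g_fc >= fc_min && p_fc >= fc_min) "biogenesis_level"
  else "no_call"
}

#' Pathway congruence of single and double mutants
#'
#' If two genes act in one pathway, the double mutant should phenocopy the
#' stronger single mutant; independent mechanisms act additively on the log2
#' scale. `same_pathway` when `|fc_double - max(fc_a, fc_b)| <= tol_log2`;
#' `additive` when `|fc_double - (fc_a + fc_b)| <= tol_log2` (and not
#' same_pathway); otherwise `intermediate`.
#'
#' @param fc_a,fc_b,fc_double log2 fold changes from matched contrasts
#'   (single mutants and the double mutant, each vs the same control).
#' @param tol_log2 tolerance on the log2 scale.
#' @return one of `"same_pathway"`, `"additive"`, `"intermediate"` (vectorized
#'   over features).
#' @export
pathwayCongruence <- function(fc_a, fc_b, fc_double, tol_log2 = 0.5) {
  same <- abs(fc_double - pmax(fc_a, fc_b)) <= tol_log2
  addv <- abs(fc_double - (fc_a + fc_b)) <= tol_log2 & !same
  ifelse(same, "same_pathway", ifelse(addv, "additive", "intermediate"))
}
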