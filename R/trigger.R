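#' Compute genotype enrichment of hybrid interactions
#'
#' Aligns hybrid tables from two genotype groups on (miRNA, transcript, site),
#' treating absent entries as 0, and computes per-pair arithmetic mean RPM in
#' each group, the pseudocounted enrichment
#' `(mean_rpm_mut + p) / (mean_rpm_wt + p)`, and the abundance flag
#' `max(mean_rpm_wt, mean_rpm_mut) > rpm_threshold` (hybrids must be abundant,
#' > 0.1 reads per million by default, to be rankable).
#'
#' @param tables_wt,tables_mut lists of [HybridTable-class] per replicate.
#' @param pseudocount pseudocount p (rpm units) on both means.
#' @param rpm_threshold abundance threshold on the larger group mean.
#' @return DataFrame with one row per pair: means, `enrichment`,
#'   `passes_abundance`, `n_wt`, `n_mut`.
#' @export
computeEnrichment <- function(tables_wt, tables_mut, pseudocount = 0.01,
                              rpm_threshold = 0.1) {
  if (!length(tables_wt) || !length(tables_mut)) {
    stop("input error: both genotype groups need at least one hybrid table")
  }
  keyOf <- function(tab) {
    p <- hybridPairs(tab)
    paste(p$mirna_id, p$transcript_id, p$site_id, sep = "\r")
  }
  all_keys <- unique(unlist(c(lapply(tables_wt, keyOf), lapply(tables_mut, keyOf))))
  groupMean <- function(tabs) {
    acc <- matrix(0, length(all_keys), length(tabs))
    for (i in seq_along(tabs)) {
      p <- hybridPairs(tabs[[i]])
      acc[match(keyOf(tabs[[i]]), all_keys), i] <- p$rpm
    }
    rowMeans(acc)
  }
  mean_wt <- groupMean(tables_wt)
  mean_mut <- groupMean(tables_mut)
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  DataFrame(
    mirna_id = parts[, 1], transcript_id = parts[, 2], site_id = parts[, 3],
    mean_rpm_wt = mean_wt, mean_rpm_mut = mean_mut,
    enrichment = (mean_mut + pseudocount) / (mean_wt + pseudocount),
    passes_abundance = pmax(mean_wt, mean_mut) > rpm_threshold,
    n_wt = length(tables_wt), n_mut = length(tables_mut))
}

#' Rank candidate trigger interactions by enrichment
#'
#' Filters to abundant pairs, sorts by enrichment (descending; ties broken by
#' higher mutant mean RPM, then lexicographic ids) and reports the top `top_n`
#' together with, per transcript, how many of its pairs made the top list.
#'
#' @param records DataFrame from [computeEnrichment()].
#' @param top_n size of the ranked report.
#' @return list with `report` (top rows, with `rank`) and
#'   `transcript_counts` (named integer: entries within the top per
#'   transcript).
#' @export
rankCandidates <- function(records, top_n = 25L) {
  r <- records[records$passes_abundance, , drop = FALSE]
  o <- order(-r$enrichment, -r$mean_rpm_mut, r$mirna_id, r$transcript_id,
             r$site_id)
  r <- r[o, , drop = FALSE]
  top <- utils::head(r, top_n)
  top$rank <- seq_len(nrow(top))
  counts <- sort(table(top$transcript_id), decreasing = TRUE)
  list(report = top,
       transcript_counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Aggregate enrichment per binding site across a miRNA family
#'
#' For each (site, family): the member coverage (members observed in hybrids
#' at the site / family size) and the aggregate enrichment of summed member
#' RPM, `(sum mean_rpm_mut + p) / (sum mean_rpm_wt + p)`. Candidates with
#' coverage >= `coverage_min` are ranked by aggregate enrichment.
#'
#' @param records DataFrame from [computeEnrichment()].
#' @param family_map named character: guide miRNA id -> family id.
#' @param coverage_min minimum member coverage to be ranked.
#' @param pseudocount pseudocount p (rpm units).
#' @return DataFrame of trigger candidates sorted by rank; columns
#'   `transcript_id`, `site_id`, `family_id`, `member_coverage`,
#'   `aggregate_enrichment`, `rank` (NA for candidates below coverage_min).
#' @export
aggregateFamilySites <- function(records, family_map, coverage_min = 0.5,
                                 pseudocount = 0.01) {
  unknown <- setdiff(unique(records$mirna_id), names(family_map))
  if (length(unknown)) {
    stop("mapping error: miRNAs missing from family_map: ",
         paste(unknown, collapse = ", "))
  }
  fam <- family_map[records$mirna_id]
  fam_size <- table(family_map)
  key <- paste(records$transcript_id, records$site_id, fam, sep = "\r")
  present <- records$mean_rpm_wt > 0 | records$mean_rpm_mut > 0
  rows <- lapply(unique(key), function(kk) {
    sel <- key == kk
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    n_members <- length(unique(records$mirna_id[sel & present]))
    DataFrame(
      transcript_id = parts[1], site_id = parts[2], family_id = parts[3],
      member_coverage = n_members / as.integer(fam_size[[parts[3]]]),
      aggregate_enrichment = (sum(records$mean_rpm_mut[sel]) + pseudocount) /
        (sum(records$mean_rpm_wt[sel]) + pseudocount))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$aggregate_enrichment), , drop = FALSE]
  out$rank <- NA_integer_
  ranked <- out$member_coverage >= coverage_min
  out$rank[ranked] <- seq_len(sum(ranked))
  out
}
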