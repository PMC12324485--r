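#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

# Bases that form neither a Watson-Crick nor a G:U pair with b.
.nonPartners <- list(A = c("A", "C", "G"), C = c("A", "C", "U"),
                     G = c("A", "G"), U = c("C", "U"))
.wcPartner <- c(A = "U", C = "G", G = "C", U = "A")

#' Generate the synthetic transcriptome with a planted trigger lncRNA
#'
#' Builds one trigger lncRNA carrying two planted binding sites and
#' `n_decoy_transcripts` decoys (a configurable fraction carrying a
#' conventional seed-only site), and records the ground truth needed by the
#' recovery tests: site spans, the per-member chimeric sampling weights
#' (proportional to the predicted duplex score), which members are degraded,
#' and the true copy numbers behind the quantification fixtures.
#'
#' Site 1 is an exact Watson-Crick complement of seed positions 2-8 (shared by
#' all family members) with the 3' end of the designated member (the maximum
#' of `trigger_site1_3p_pairing`) complemented over that many positions; the
#' central region is built non-pairing for the designed member. Site 2
#' complements positions 3-8 only (the base opposite position 2 cannot pair)
#' and carries a 10-nt 3' complement for `trigger_site2_member`. Decoy sites
#' complement positions 2-8 with a 10-nt upstream flank built non-pairing for
#' family member 1, so a conventional site shows no supplemental/3' pairing
#' for that member.
#'
#' Members whose site-1 duplex classifies as a perfect 2-8 seed match are the
#' *degraded* members: their trigger hybrids are multiplied by
#' `enrichment_lambda` in the decay-deficient genotype and their guide strands
#' are stabilized by `decay_fold` in null-genotype count tables. Swapping
#' `site1_seed_from` to an outsider miRNA therefore retargets both the hybrid
#' enrichment and the stabilization to that miRNA.
#'
#' @param config a [SimConfig-class]
#' @param family a [MiRNASet-class] from [makeMirnaFamily()]
#' @return list with elements `transcripts` (named character vector of RNA
#'   sequences) and `truth` (a [SimTruth-class])
#' @export
makeTranscriptome <- function(config, family) {
  stopifnot(is(config, "SimConfig"), is(family, "MiRNASet"))
  g <- guideRecords(family)
  fam_ids <- g$id[g$family_id == "miR-f"]
  L <- config@mirna_length
  tx_len <- 400L

  design1_id <- if (!is.na(config@site1_seed_from)) config@site1_seed_from else
    fam_ids[which.max(config@trigger_site1_3p_pairing)]
  design1 <- g$sequence[match(design1_id, g$id)]
  if (is.na(design1)) stop("site1_seed_from names an unknown guide: ", config@site1_seed_from)
  c1 <- max(config@trigger_site1_3p_pairing)
  s2_id <- fam_ids[config@trigger_site2_member]
  design2 <- g$sequence[match(s2_id, g$id)]

  .withSeed(.deriveSeed(config@rng_seed, "transcriptome"), {
    trigger <- strsplit(.randSeq(1, tx_len), "", fixed = TRUE)[[1]]

    site1 <- .plantedSite(design1,
                          pair_g = c(2:8, if (c1 > 0) (L - c1 + 1L):L),
                          dead_g = if (L - c1 >= 9L) 9:(L - c1) else integer(0))
    site2 <- .plantedSite(design2, pair_g = c(3:8, (L - 9L):L),
                          dead_g = if (L - 10L >= 9L) 9:(L - 10L) else integer(0),
                          block_g2 = TRUE)

    p2 <- 120L; p1 <- 240L   # site2 upstream of site1; spans never overlap
    trigger[(p2 + 1L):(p2 + L)] <- strsplit(site2, "", fixed = TRUE)[[1]]
    trigger[(p1 + 1L):(p1 + L)] <- strsplit(site1, "", fixed = TRUE)[[1]]
    # bases just downstream of site 2 must not pair position 2, or the DP
    # could bridge a bulge and pair g2 against the flank
    g2base <- substr(design2, 2, 2)
    trigger[(p2 + L + 1L):(p2 + L + 4L)] <-
      sample(.nonPartners[[g2base]], 4L, replace = TRUE)
    trigger_seq <- paste(trigger, collapse = "")
    trigger_id <- "lnc-trig-1"

    n_dec <- config@n_decoy_transcripts
    decoys <- .randSeq(n_dec, tx_len)
    names(decoys) <- sprintf("tx-d%03d", seq_len(n_dec))
    n_sited <- round(config@decoy_site_fraction * n_dec)
    shared_seed <- substr(g$sequence[match(fam_ids[1], g$id)], 2, 8)
    m1_seq <- g$sequence[match(fam_ids[1], g$id)]
    decoy_rows <- list()
    for (i in seq_len(n_sited)) {
      site <- .seedOnlySite(m1_seq)
      pos <- 150L
      decoys[i] <- paste0(substr(decoys[i], 1, pos),
                          site,
                          substr(decoys[i], pos + nchar(site) + 1L, tx_len))
      # recorded span: the 8-nt seed-pairing core (0-based half-open)
      core_start <- pos + nchar(site) - 8L
      decoy_rows[[i]] <- DataFrame(transcript_id = names(decoys)[i],
                                   site_id = paste0("decoy@", names(decoys)[i]),
                                   start = core_start, end = core_start + 8L)
    }
    decoy_sites <- if (length(decoy_rows)) do.call(rbind, decoy_rows) else
      DataFrame(transcript_id = character(0), site_id = character(0),
                start = integer(0), end = integer(0))

    transcripts <- c(stats::setNames(trigger_seq, trigger_id), decoys)

    sites <- GRanges(trigger_id,
                     IRanges(start = c(p1 + 1L, p2 + 1L), width = L),
                     site_id = c("site1", "site2"),
                     kind = c("perfect_seed", "offset_seed"))

    # --- interaction table: duplex score of every guide vs every planted site
    all_guides <- g$id
    site_tbl <- rbind(
      DataFrame(transcript_id = trigger_id, site_id = "site1",
                start = p1, end = p1 + L),
      DataFrame(transcript_id = trigger_id, site_id = "site2",
                start = p2, end = p2 + L),
      decoy_sites
    )
    inter <- list()
    degraded <- character(0)
    for (gi in all_guides) {
      gseq <- g$sequence[match(gi, g$id)]
      for (r in seq_len(nrow(site_tbl))) {
        tx <- site_tbl$transcript_id[r]
        w0 <- max(1L, site_tbl$start[r] - 9L)
        w1 <- min(nchar(transcripts[[tx]]), site_tbl$end[r] + 10L)
        window <- substr(transcripts[[tx]], w0, w1)
        dup <- predictDuplex(gseq, window, mirna_id = gi,
                             target_offset = w0 - 1L)
        if (dup@score <= 0) next
        is_trig <- tx == trigger_id
        if (is_trig && site_tbl$site_id[r] == "site1" &&
            grepl(.revComp(substr(gseq, 2, 8)), window, fixed = TRUE)) {
          # Ago-anchored seed pairing: a member is degraded when site 1
          # carries the exact Watson-Crick complement of its positions 2-8
          degraded <- c(degraded, gi)
        }
        inter[[length(inter) + 1L]] <- DataFrame(
          mirna_id = gi, transcript_id = tx, site_id = site_tbl$site_id[r],
          start = site_tbl$start[r], end = site_tbl$end[r],
          score = dup@score, is_trigger = is_trig)
      }
    }
    interactions <- do.call(rbind, inter)
    degraded <- unique(degraded)

    fam_idx <- match(fam_ids, fam_ids)
    members <- DataFrame(
      id = all_guides,
      family_id = g$family_id[match(all_guides, g$id)],
      site1_3p = ifelse(all_guides %in% fam_ids,
                        config@trigger_site1_3p_pairing[match(all_guides, fam_ids)],
                        ifelse(all_guides == design1_id, c1, 0)),
      degraded = all_guides %in% degraded
    )
    members$is_3p_paired <- members$degraded & members$site1_3p >= 8
    fold <- rep(1, length(all_guides))
    fold[members$degraded] <- ifelse(
      all_guides[members$degraded] %in% fam_ids,
      config@decay_fold[match(all_guides[members$degraded], fam_ids)],
      config@decay_fold[1])
    members$decay_fold <- fold

    quant <- list(
      copies_per_ng = c(guide = 2e5, trigger = 9e4),
      input_ng = 10,
      peak_copies = 4e5,
      stage_weights = c(early = 0.5, late = 0.5),
      stage_profile = c(early = 0.2, late = 1.0),
      unit_intensity = config@spot_unit_intensity,
      stage_fold = config@smfish_stage_fold,
      spots_mean_reference = 25
    )

    truth <- new("SimTruth", trigger_id = trigger_id, sites = sites,
                 members = members, interactions = interactions,
                 decoy_sites = decoy_sites, quant = quant)
    list(transcripts = transcripts, truth = truth)
  })
}

# Construct a planted binding site (5'->3' target string) for one design
# miRNA: positions in pair_g get the Watson-Crick complement, positions in
# dead_g get a base that can pair the design miRNA neither WC nor G:U.
# block_g2 additionally forces the base opposite g2 to be non-pairing and
# biases the base opposite g1 away from pairing g2.
.plantedSite <- function(mirna_seq, pair_g, dead_g, block_g2 = FALSE) {
  b <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  L <- length(b)
  opp <- character(L)                      # opp[g] = target base opposite g
  for (g in seq_len(L)) {
    if (g %in% pair_g) {
      opp[g] <- .wcPartner[[b[g]]]
    } else if (g %in% dead_g || (block_g2 && g == 2L)) {
      opp[g] <- sample(.nonPartners[[b[g]]], 1)
    } else if (g == 1L) {
      cand <- .nonPartners[[b[2L]]]
      pref <- intersect(cand, .nonPartners[[b[1L]]])
      opp[g] <- if (length(pref)) sample(pref, 1) else sample(cand, 1)
    } else {
      opp[g] <- sample(.nonPartners[[b[g]]], 1)
    }
  }
  # antiparallel: target 5'->3' runs opposite g = L..1
  paste(rev(opp), collapse = "")
}

# A conventional decoy site: 10-nt upstream flank non-pairing for the family
# reference member, the seed complement (g2-8), and a t1 base avoiding g2.
.seedOnlySite <- function(mirna_seq) {
  b <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  flank <- vapply(9:18, function(g) {
    gg <- min(g, length(b))
    sample(.nonPartners[[b[gg]]], 1)
  }, character(1))
  seed_rc <- .revComp(substr(mirna_seq, 2, 8))
  cand <- .nonPartners[[b[2L]]]
  pref <- intersect(cand, .nonPartners[[b[1L]]])
  t1 <- if (length(pref)) sample(pref, 1) else sample(cand, 1)
  paste0(paste(rev(flank), collapse = ""), seed_rc, t1)
}
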