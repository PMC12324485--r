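#' Generate a synthetic miRNA family (guides and passengers)
#'
#' Builds `family_size` guide miRNAs sharing identical nucleotides at seed
#' positions 2-8 while keeping positions 9..end pairwise divergent (>= 30%
#' mismatches between any two members), plus one passenger strand per guide
#' derived from a synthetic hairpin rule, and a random genomic downstream
#' context (20 nt) per record for isomiR analysis. With
#' `n_outsider_mirnas > 0`, additional single-member "outsider" guides with
#' their own, clearly distinct seed are appended (used by seed-retargeting
#' experiments).
#'
#' The hairpin rule for passengers: passenger = reverse complement of the
#' guide with positions 1 and 10 substituted by a different nucleotide
#' (imitating the duplex overhang and a bulge); only the guide/passenger
#' labelling matters downstream.
#'
#' @param config a [SimConfig-class]
#' @return a [MiRNASet-class]; guides named `miR-f01..`, outsiders `miR-x1..`,
#'   passengers carry a `*` suffix.
#' @examples
#' fam <- makeMirnaFamily(simConfig(rng_seed = 7))
#' fam
#' @export
makeMirnaFamily <- function(config) {
  stopifnot(is(config, "SimConfig"))
  if (config@family_size < 2L) stop("invalid config: family_size must be >= 2")
  if (config@mirna_length < 18L) stop("invalid config: mirna_length must be >= 18")
  L <- config@mirna_length
  tail_len <- L - 8L
  min_div <- ceiling(0.3 * tail_len)

  .withSeed(.deriveSeed(config@rng_seed, "mirna_family"), {
    seed7 <- paste(sample(RNA_ALPHABET, 7, replace = TRUE), collapse = "")
    tails <- character(0)
    for (i in seq_len(config@family_size)) {
      for (try in 1:500) {
        cand <- .randSeq(1, tail_len)
        if (all(vapply(tails, function(t) .mismatches(t, cand) >= min_div,
                       logical(1)))) break
        cand <- NA_character_
      }
      if (is.na(cand)) stop("could not generate divergent member tails; lower family_size")
      tails <- c(tails, cand)
    }
    guides <- paste0("U", seed7, tails)
    ids <- sprintf("miR-f%02d", seq_len(config@family_size))
    fams <- rep("miR-f", config@family_size)

    # outsider guides: own seed, >= 3 mismatches to the family seed
    if (config@n_outsider_mirnas > 0L) {
      for (k in seq_len(config@n_outsider_mirnas)) {
        repeat {
          s <- paste(sample(RNA_ALPHABET, 7, replace = TRUE), collapse = "")
          if (.mismatches(s, seed7) >= 3) break
        }
        guides <- c(guides, paste0("U", s, .randSeq(1, tail_len)))
        ids <- c(ids, sprintf("miR-x%d", k))
        fams <- c(fams, sprintf("miR-x%d", k))
      }
    }

    passengers <- vapply(guides, .hairpinPassenger, character(1), USE.NAMES = FALSE)
    contexts <- .randSeq(2L * length(guides), 20L)

    rec <- DataFrame(
      id = c(ids, paste0(ids, "*")),
      sequence = c(guides, passengers),
      role = rep(c("guide", "passenger"), each = length(guides)),
      family_id = c(fams, fams),
      canonical_length = nchar(c(guides, passengers)),
      context = contexts
    )
    new("MiRNASet", records = rec)
  })
}

# The synthetic hairpin rule: reverse complement of the guide with positions 1
# and 10 substituted (deterministically, given the RNG state) by another base.
.hairpinPassenger <- function(guide) {
  p <- strsplit(.revComp(guide), "", fixed = TRUE)[[1]]
  for (pos in c(1L, 10L)) {
    p[pos] <- sample(setdiff(RNA_ALPHABET, p[pos]), 1)
  }
  paste(p, collapse = "")
}

#' Shared seed sequence (positions 2-8) of a guide set
#' @param mirna_set a [MiRNASet-class]
#' @param id optional guide id; default: first family guide
#' @return 7-nt seed string
#' @export
seedSequence <- function(mirna_set, id = NULL) {
  g <- guideRecords(mirna_set)
  if (is.null(id)) id <- g$id[1]
  seq <- g$sequence[match(id, g$id)]
  if (is.na(seq)) stop("unknown guide id: ", id)
  substr(seq, 2, 8)
}
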