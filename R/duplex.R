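#' Predict the intermolecular miRNA:target duplex by dynamic programming
#'
#' Computes the maximum-score non-crossing base-pair set between a miRNA and a
#' target window under a simple match/mismatch/affine-gap scoring model. The
#' two strands are antiparallel; a "match" is Watson-Crick (A:U, G:C) or G:U
#' complementarity. Terminal unpaired stretches on either strand are free;
#' interior unpaired stretches are charged as mismatches and affine gaps. The
#' model scores pairing topology (which positions pair), not thermodynamic
#' free energy: the downstream architecture classification needs only the
#' pair map.
#'
#' Ties in score are broken deterministically: prefer more Watson-Crick pairs,
#' then more seed pairs (positions 2-8), then the leftmost target start.
#'
#' @param mirna_seq miRNA sequence, 5'->3', RNA alphabet.
#' @param target_window target sequence, 5'->3', RNA alphabet; include 10-nt
#'   flanks around a binding site when available.
#' @param scoring named numeric: `WC`, `GU`, `mismatch`, `gap_open`
#'   (first gapped position), `gap_extend` (each further position).
#' @param mirna_id optional id stored in the result.
#' @param target_offset 0-based transcript coordinate of window position 1.
#' @return a [Duplex-class]. With no positive-scoring pairing the pair set is
#'   empty and the score is 0.
#' @examples
#' d <- predictDuplex("UGAGGUAG", "CUACUCA")
#' duplexPairs(d)
#' @export
predictDuplex <- function(mirna_seq, target_window,
                          scoring = c(WC = 2, GU = 1, mismatch = -1,
                                      gap_open = -2, gap_extend = -1),
                          mirna_id = NA_character_, target_offset = 0L) {
  mirna_seq <- toupper(mirna_seq); target_window <- toupper(target_window)
  .checkRnaAlphabet(mirna_seq, "miRNA sequence")
  .checkRnaAlphabet(target_window, "target window")
  x <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  y <- strsplit(target_window, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  if (n < 7L || m < 7L) stop("both sequences must be at least 7 nt")
  yr <- rev(y)   # reversed target: antiparallel pairing becomes co-linear

  kind <- matrix(0L, n, m)  # 2 = WC, 1 = GU, 0 = no pair, vs reversed target
  for (i in seq_len(n)) {
    kind[i, ] <- ifelse(yr == .wcPartner[[x[i]]], 2L,
                        ifelse((x[i] == "G" & yr == "U") |
                               (x[i] == "U" & yr == "G"), 1L, 0L))
  }
  sc <- ifelse(kind == 2L, scoring[["WC"]],
               ifelse(kind == 1L, scoring[["GU"]], scoring[["mismatch"]]))

  # Lexicographic (score, #WC, #seed) packed into one exact number.
  K2 <- 16; K1 <- 16 * n + 32
  edge <- sc * K1 + (kind == 2L) * K2 +
    ((kind > 0L) & (seq_len(n) >= 2L & seq_len(n) <= 8L))
  go <- scoring[["gap_open"]] * K1; ge <- scoring[["gap_extend"]] * K1

  NEG <- -Inf
  M <- matrix(NEG, n + 1L, m + 1L); X <- M; Y <- M
  tbM <- matrix(0L, n + 1L, m + 1L); tbX <- tbM; tbY <- tbM
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L], 0)
      w <- which.max(prev)
      M[i, j] <- edge[i - 1L, j - 1L] + prev[w]
      tbM[i, j] <- c(1L, 2L, 3L, 0L)[w]
      px <- c(M[i - 1L, j] + go, X[i - 1L, j] + ge, Y[i - 1L, j] + go)
      wx <- which.max(px); X[i, j] <- px[wx]; tbX[i, j] <- wx
      py <- c(M[i, j - 1L] + go, Y[i, j - 1L] + ge, X[i, j - 1L] + go)
      wy <- which.max(py); Y[i, j] <- py[wy]; tbY[i, j] <- c(1L, 3L, 2L)[wy]
    }
  }

  # best endpoint in M; ties -> larger j (leftmost start in original target)
  best <- NEG; bi <- 0L; bj <- 0L
  for (i in 2:(n + 1L)) for (j in 2:(m + 1L)) {
    if (M[i, j] > best || (M[i, j] == best && j > bj)) {
      best <- M[i, j]; bi <- i; bj <- j
    }
  }

  pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("g", "t")))
  kinds <- character(0)
  score <- 0
  if (is.finite(best) && best > 0) {
    score <- floor(best / K1 + 1e-9)
    i <- bi; j <- bj; state <- 1L
    while (i > 1L || j > 1L) {
      if (state == 1L) {
        gi <- i - 1L; gj <- j - 1L
        if (kind[gi, gj] > 0L) {
          pairs <- rbind(pairs, c(gi, m - gj + 1L))
          kinds <- c(kinds, if (kind[gi, gj] == 2L) "WC" else "GU")
        }
        state <- tbM[i, j]; i <- i - 1L; j <- j - 1L
        if (state == 0L) break
      } else if (state == 2L) {
        state <- tbX[i, j]; i <- i - 1L
      } else {
        state <- tbY[i, j]; j <- j - 1L
      }
    }
    o <- order(pairs[, 1])
    pairs <- pairs[o, , drop = FALSE]
    colnames(pairs) <- c("g", "t")
    kinds <- kinds[o]
  }

  mask_m <- rep(".", n); mask_m[pairs[, "g"]] <- "|"
  mask_t <- rep(".", m); mask_t[pairs[, "t"]] <- "|"
  new("Duplex", mirna_id = as.character(mirna_id), mirna_seq = mirna_seq,
      target_seq = target_window, target_offset = as.integer(target_offset),
      pairs = pairs, pair_kinds = kinds, score = as.numeric(score),
      structure = c(paste(mask_m, collapse = ""), paste(mask_t, collapse = "")))
}

#' Classify the pairing architecture of a duplex
#'
#' Region-wise pair counting (seed g2-g8, central g9-g12, supplemental
#' g13-g16, tail g17-end) plus the derived seed-match class and the
#' TDTT-proneness call. Seed classes: `perfect_2_8` when g2-g8 are all
#' Watson-Crick paired (G:U does not count as perfect), `offset_3_8` when
#' g3-g8 are paired but g2 is not, `partial` when at least 4 of g2-g8 pair,
#' else `none`. A duplex is TDTT-prone when the miRNA 3' extremity is engaged:
#' at least `min_tail3_pairs` pairs within the last 3 positions and at least
#' `min_three_prime_extent` paired positions in g9..end.
#'
#' @param duplex a [Duplex-class] from [predictDuplex()]
#' @param mirna_len canonical miRNA length (>= 17, else region boundaries are
#'   undefined and an error is thrown)
#' @param tdtt_rule list with `min_tail3_pairs` and `min_three_prime_extent`
#' @return a [PairingArchitecture-class]
#' @export
classifyArchitecture <- function(duplex, mirna_len = nchar(duplex@mirna_seq),
                                 tdtt_rule = list(min_tail3_pairs = 2L,
                                                  min_three_prime_extent = 8L)) {
  stopifnot(is(duplex, "Duplex"))
  if (mirna_len < 17L) {
    stop("classification error: mirna_len < 17, region boundaries undefined")
  }
  g <- duplex@pairs[, "g"]
  kinds <- duplex@pair_kinds
  seed_g <- 2:8
  n_seed <- sum(g %in% seed_g)
  all_wc_seed <- all(seed_g %in% g[kinds == "WC"])
  seed_match <- if (all_wc_seed) "perfect_2_8"
    else if (all(3:8 %in% g) && !(2L %in% g)) "offset_3_8"
    else if (n_seed >= 4L) "partial"
    else "none"
  extent <- sum(g >= 9L & g <= mirna_len)
  tail3 <- sum(g >= mirna_len - 2L & g <= mirna_len)
  new("PairingArchitecture",
      seed_match = seed_match,
      n_seed_pairs = as.integer(n_seed),
      n_central_pairs = as.integer(sum(g %in% 9:12)),
      n_supplemental_pairs = as.integer(sum(g %in% 13:16)),
      n_tail_pairs = as.integer(sum(g >= 17L)),
      three_prime_extent = as.integer(extent),
      tdtt_prone = tail3 >= tdtt_rule$min_tail3_pairs &&
        extent >= tdtt_rule$min_three_prime_extent)
}

#' Map trigger "t positions" under the seed-anchored register
#'
#' Trigger nucleotides are conventionally indexed by the miRNA position they
#' sit opposite: t8 is the base opposite miRNA nucleotide 8. The register is
#' anchored on the 5'-most seed pair and extended with unit steps; indices
#' beyond the miRNA 3' end continue 5'-ward (upstream) along the trigger, so
#' e.g. t35 lies 27 nt upstream of t8.
#'
#' @param duplex a [Duplex-class] with at least one seed pair (g2-g8)
#' @param extend_to largest t index to report
#' @return named integer vector `t1..t<extend_to>` of 0-based transcript
#'   coordinates (window position + `target_offset`); positions are
#'   extrapolated where unpaired and may fall outside the window.
#' @export
mapTPositions <- function(duplex, extend_to = 35L) {
  stopifnot(is(duplex, "Duplex"))
  g <- duplex@pairs[, "g"]
  sel <- which(g >= 2L & g <= 8L)
  if (!length(sel)) stop("undefined-register error: duplex has no seed pair")
  a <- sel[which.min(g[sel])]
  g0 <- duplex@pairs[a, "g"]; t0 <- duplex@pairs[a, "t"]
  idx <- seq_len(extend_to)
  t_win <- t0 - (idx - g0)           # antiparallel: higher g, lower t
  stats::setNames(as.integer(duplex@target_offset + t_win - 1L),
                  paste0("t", idx))
}
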