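# Internal helpers shared across modules.

RNA_ALPHABET <- c("A", "C", "G", "U")

.rnaComplementMap <- c(A = "U", C = "G", G = "C", U = "A")

#' Reverse complement of RNA character strings
#' @param x character vector of RNA sequences (A/C/G/U)
#' @return character vector
#' @keywords internal
.revComp <- function(x) {
  flipped <- chartr("ACGU", "UGCA", x)
  vapply(flipped, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.checkRnaAlphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("invalid alphabet in ", what, ": expected A/C/G/U only (offending: ",
         paste(utils::head(x[bad], 3), collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Convert DNA-alphabet strings (T) to RNA (U) and vice versa
#'
#' The conversion is skipped when the input is already uppercase RNA (fast
#' path for the internal simulators, which only emit A/C/G/U).
#' @keywords internal
.dnaToRna <- function(x) {
  if (!any(grepl("[^ACGU]", x))) return(x)
  chartr("Tt", "Uu", toupper(x))
}
.rnaToDna <- function(x) chartr("U", "T", x)

# Evaluate expr under a temporary RNG state so callers' streams are untouched.
.withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and a string tag,
# so independent operations draw from independent, deterministic streams.
.deriveSeed <- function(base, tag, extra = 0L) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(base) * 48271 + h * 1009 + as.numeric(extra) * 7919) %%
               2147483563) + 1L
}

# n random RNA sequences of the given length(s)
.randSeq <- function(n, len, alphabet = RNA_ALPHABET) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(alphabet, l, replace = TRUE), collapse = "")
  }, character(1))
}

# Hamming-style mismatch count between equal-length strings
.mismatches <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(ca != cb)
}

.geomMean <- function(x) exp(mean(log(x)))
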