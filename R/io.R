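# Plain-text interchange: FASTA for sequence sets, TSV for tables, JSON for
# the planted truth. Headers of the miRNA database carry role/family/context
# tokens so the set round-trips.

#' Write a miRNA database as FASTA
#'
#' Headers follow `id|role family=<id> context=<seq>`.
#' @param mirna_set a [MiRNASet-class]
#' @param path output path
#' @export
writeMirnaFasta <- function(mirna_set, path) {
  rec <- mirnaRecords(mirna_set)
  hdr <- sprintf(">%s|%s family=%s context=%s", rec$id, rec$role,
                 rec$family_id, rec$context)
  writeLines(paste0(hdr, "\n", rec$sequence), path)
  invisible(path)
}

#' Read a miRNA database written by [writeMirnaFasta()]
#' @param path FASTA path
#' @return a [MiRNASet-class]
#' @export
readMirnaFasta <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, ">")]
  seqs <- lines[!startsWith(lines, ">")]
  id_role <- sub("^>", "", vapply(strsplit(hdr, " "), `[`, character(1), 1))
  parts <- strsplit(id_role, "|", fixed = TRUE)
  token <- function(key) sub(paste0(".*", key, "="), "", hdr)
  rec <- DataFrame(
    id = vapply(parts, `[`, character(1), 1),
    sequence = .dnaToRna(seqs),
    role = vapply(parts, `[`, character(1), 2),
    family_id = sub(" .*", "", token("family")),
    canonical_length = nchar(seqs),
    context = .dnaToRna(sub(" .*", "", token("context"))))
  new("MiRNASet", records = rec)
}

#' Write a transcriptome as FASTA
#' @param transcripts named character vector (RNA or DNA)
#' @param path output path
#' @export
writeTranscriptomeFasta <- function(transcripts, path) {
  writeLines(paste0(">", names(transcripts), "\n", transcripts), path)
  invisible(path)
}

#' Read a transcriptome FASTA into a named character vector (RNA alphabet)
#' @param path FASTA path (single-line or wrapped sequences)
#' @export
readTranscriptomeFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  stats::setNames(.dnaToRna(as.character(set)), sub(" .*", "", names(set)))
}

#' Write hybrid tables as a TSV
#'
#' Columns: sample, mirna, transcript, site, start, end, count, rpm.
#' @param tables list of [HybridTable-class]
#' @param path output path
#' @export
writeHybridTables <- function(tables, path) {
  rows <- lapply(tables, function(tab) {
    p <- as.data.frame(hybridPairs(tab))
    cbind(sample = tab@sample_id, p)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export planted simulation truth as JSON
#' @param truth a [SimTruth-class]
#' @param path output path
#' @export
exportSimTruth <- function(truth, path) {
  sites <- data.frame(site_id = truth@sites$site_id,
                      start = GenomicRanges::start(truth@sites) - 1L,
                      end = GenomicRanges::end(truth@sites))
  jsonlite::write_json(list(
    trigger_id = truth@trigger_id,
    sites = sites,
    members = as.data.frame(truth@members),
    quant = truth@quant), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
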