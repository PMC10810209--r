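#' Find an anchor sequence within a read
#'
#' Returns the leftmost 1-based position where the anchor matches a window of
#' the read with at most `maxMismatches` Hamming mismatches (no indels), or
#' `NA` when no such window exists.
#'
#' @param read A single read sequence (character or `DNAString`).
#' @param anchor Anchor sequence to locate (character).
#' @param maxMismatches Maximum Hamming distance tolerated (default 0).
#' @return Integer position (1-based) of the leftmost match, or `NA_integer_`.
#' @examples
#' findAnchor("AAACGTAAA", "CGT")      # 4
#' findAnchor("AAACGAAAA", "CGT", 1)   # 4
#' @export
#' @importFrom Biostrings matchPattern
findAnchor <- function(read, anchor, maxMismatches = 0L) {
  if (!is.character(anchor) || length(anchor) != 1L || nchar(anchor) == 0L)
    stop("'anchor' must be a single non-empty sequence")
  read <- if (is.character(read)) Biostrings::DNAString(read) else read
  if (nchar(anchor) > length(read)) return(NA_integer_)
  m <- Biostrings::matchPattern(anchor, read,
                                max.mismatch = maxMismatches,
                                with.indels = FALSE)
  if (length(m) == 0L) NA_integer_ else min(Biostrings::start(m))
}

## Leftmost match start per read for a fixed anchor, vectorized over a
## DNAStringSet. minStart restricts matches to start positions >= minStart
## (per read). Returns NA where no match.
.leftmostMatch <- function(reads, anchor, maxMismatches, minStart = NULL) {
  m <- Biostrings::vmatchPattern(anchor, reads,
                                 max.mismatch = maxMismatches,
                                 with.indels = FALSE)
  starts <- Biostrings::startIndex(m)
  out <- vapply(seq_along(starts), function(i) {
    s <- starts[[i]]
    if (is.null(s)) return(NA_integer_)
    if (!is.null(minStart)) s <- s[s >= minStart[i]]
    if (length(s) == 0L) NA_integer_ else min(s)
  }, integer(1))
  out
}

#' Extract fixed-length inserts from construct-flanked reads
#'
#' Locates the suffix anchor of the left arm and, downstream of it, the
#' prefix anchor of the right arm; the sequence between the two anchors is
#' the insert. Only inserts of exactly `insertLength(spec)` bases are kept.
#' Qualities are carried through when the input is quality-scaled.
#'
#' @param reads A `DNAStringSet` or `QualityScaledDNAStringSet`.
#' @param spec A [ConstructSpec-class].
#' @return A list with elements `inserts` (same class as `reads`, names
#'   preserved), `pass` (logical per input read) and `stats`
#'   ([PrepStats-class]).
#' @examples
#' spec <- ConstructSpec()
#' insert <- paste(rep("A", 25), collapse = "")
#' reads <- Biostrings::DNAStringSet(
#'   paste0(leftArm(spec), insert, rightArm(spec)))
#' extractInserts(reads, spec)$inserts
#' @export
#' @importFrom Biostrings vmatchPattern startIndex subseq quality
#'   QualityScaledDNAStringSet
extractInserts <- function(reads, spec = ConstructSpec()) {
  n <- length(reads)
  la <- leftAnchor(spec)
  ra <- rightAnchor(spec)
  mm <- spec@maxArmMismatches
  if (n == 0L) {
    empty <- reads[0]
    return(list(inserts = empty, pass = logical(0), stats = PrepStats()))
  }
  seqs <- if (is(reads, "QualityScaledDNAStringSet"))
    suppressWarnings(Biostrings::DNAStringSet(reads)) else reads
  lpos <- .leftmostMatch(seqs, la, mm)
  insStart <- lpos + nchar(la)               # first insert base
  rpos <- .leftmostMatch(seqs, ra, mm, minStart = insStart)
  armsFound <- !is.na(lpos) & !is.na(rpos)
  insLen <- rpos - insStart                  # bases between the anchors
  lengthPass <- armsFound & !is.na(insLen) & insLen == spec@insertLength
  idx <- which(lengthPass)
  ins <- Biostrings::subseq(seqs[idx], start = insStart[idx],
                            width = spec@insertLength)
  names(ins) <- names(seqs)[idx]
  if (is(reads, "QualityScaledDNAStringSet")) {
    q <- Biostrings::subseq(Biostrings::quality(reads)[idx],
                            start = insStart[idx],
                            width = spec@insertLength)
    ins <- Biostrings::QualityScaledDNAStringSet(ins, q)
  }
  list(
    inserts = ins,
    pass = lengthPass,
    stats = PrepStats(totalReads = n, armsFound = sum(armsFound),
                      lengthPass = sum(lengthPass), emitted = length(ins))
  )
}

#' Build full construct reads around inserts
#'
#' The inverse of [extractInserts()]: wraps each insert with the construct
#' arms. Used by the screen simulator and round-trip tests.
#'
#' @param inserts A `DNAStringSet` (or character vector) of inserts.
#' @param spec A [ConstructSpec-class].
#' @return A `DNAStringSet` of `leftArm + insert + rightArm`, names kept.
#' @export
#' @importFrom Biostrings xscat
buildConstructReads <- function(inserts, spec = ConstructSpec()) {
  inserts <- Biostrings::DNAStringSet(inserts)
  out <- Biostrings::xscat(spec@leftArm, inserts, spec@rightArm)
  names(out) <- names(inserts)
  out
}

#' Prepare a library: extract inserts from a FASTQ/FASTA stream
#'
#' Reads a sequencing library, extracts the fixed-length inserts per
#' [extractInserts()], optionally writes them out (FASTQ when qualities are
#' available, FASTA otherwise), and returns QC tallies.
#'
#' @param input Path to a FASTA/FASTQ file (optionally gzipped) or an
#'   in-memory `DNAStringSet`/`QualityScaledDNAStringSet`.
#' @param spec A [ConstructSpec-class].
#' @param outPath Optional path for the extracted inserts.
#' @param statsPath Optional path for a one-row TSV of the tallies.
#' @return A list with `inserts` and `stats` ([PrepStats-class]).
#' @export
#' @importFrom Biostrings writeXStringSet writeQualityScaledXStringSet
prepLibrary <- function(input, spec = ConstructSpec(), outPath = NULL,
                        statsPath = NULL) {
  reads <- if (is.character(input)) {
    if (grepl("\\.(fq|fastq)(\\.gz)?$", input, ignore.case = TRUE))
      readFastqFile(input)
    else
      readFastaFile(input)
  } else input
  res <- extractInserts(reads, spec)
  if (!is.null(outPath)) {
    if (is(res$inserts, "QualityScaledDNAStringSet"))
      Biostrings::writeQualityScaledXStringSet(res$inserts, outPath)
    else
      Biostrings::writeXStringSet(res$inserts, outPath)
  }
  if (!is.null(statsPath)) {
    s <- res$stats
    writeResultTable(data.frame(totalReads = s@totalReads,
                                armsFound = s@armsFound,
                                lengthPass = s@lengthPass,
                                emitted = s@emitted), statsPath)
  }
  list(inserts = res$inserts, stats = res$stats)
}
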