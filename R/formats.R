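#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that concatenates
#' multi-line records, normalizes case to upper, and rejects records with an
#' empty sequence.
#'
#' @param path Path to a FASTA file (may be gzip-compressed).
#' @return A [Biostrings::DNAStringSet] (possibly empty).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt", "ACGT"), fa)
#' readFastaFile(fa)
#' @export
#' @importFrom Biostrings readBStringSet DNAStringSet
readFastaFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (any(Biostrings::width(x) == 0L)) {
    bad <- names(x)[Biostrings::width(x) == 0L][1L]
    stop("FASTA parse error: record '", bad, "' has an empty sequence")
  }
  Biostrings::DNAStringSet(toupper(x))
}

#' Read a FASTQ file
#'
#' Reads plain or gzip-compressed FASTQ into a quality-scaled string set.
#' Truncated records raise a parse error.
#'
#' @param path Path to a FASTQ file (`.fq`, `.fastq`, optionally `.gz`).
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
#' @importFrom Biostrings readQualityScaledDNAStringSet
readFastqFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # structural validation first: the Biostrings reader silently tolerates a
  # truncated trailing record
  lines <- readLines(path)  # file() decompresses gzip transparently
  if (length(lines) %% 4L != 0L)
    stop("FASTQ parse error in '", path, "': truncated record ",
         length(lines) %/% 4L + 1L)
  if (length(lines)) {
    rec <- matrix(lines, nrow = 4L)
    bad <- which(!startsWith(rec[1L, ], "@") | !startsWith(rec[3L, ], "+") |
                 nchar(rec[2L, ]) != nchar(rec[4L, ]))
    if (length(bad))
      stop("FASTQ parse error in '", path, "': malformed record ", bad[1L])
  }
  withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) stop("FASTQ parse error in '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    ),
    # harmless upstream notice when qualities are re-attached
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
}

#' Read a BED file into GRanges
#'
#' Parses BED3+ with strict validation: tab-separated, `track`/`browser`/`#`
#' lines skipped, and every interval must have a non-negative start strictly
#' below its end (zero-length intervals are rejected). BED's 0-based
#' half-open coordinates are converted to the 1-based closed `GRanges`
#' convention at parse time; the 4th column (name) and 6th (strand) are
#' retained when present, further columns are ignored.
#'
#' @param path Path to a BED file.
#' @param minCols Minimum number of columns required (default 3).
#' @return A `GRanges`, in file order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t125\tpeak1", bed)
#' readBedFile(bed)
#' @export
readBedFile <- function(path, minCols = 3L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineNo <- which(keep)
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < minCols))
    stop("BED parse error at line ", lineNo[which(nf < minCols)[1L]],
         ": fewer than ", minCols, " columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad))
    stop("BED parse error at line ", lineNo[which(bad)[1L]],
         ": start must be a non-negative integer strictly below end")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (any(nf >= 4L))
    gr$name <- vapply(fields, function(f)
      if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  if (any(nf >= 6L)) {
    s <- vapply(fields, function(f)
      if (length(f) >= 6L) f[[6L]] else "*", "")
    s[!s %in% c("+", "-")] <- "*"
    GenomicRanges::strand(gr) <- s
  }
  gr
}

#' Write GRanges as BED
#'
#' Converts back to 0-based half-open coordinates. Writes BED6 when the
#' ranges carry a `name` column or non-`*` strand, BED3 otherwise.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param scores Optional numeric score column (default 0).
#' @return The path, invisibly.
#' @export
writeBedFile <- function(gr, path, scores = NULL) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  nm <- if (!is.null(gr$name)) gr$name else names(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  if (is.null(nm) && all(strand == "*")) {
    out <- paste(chrom, start, end, sep = "\t")
  } else {
    if (is.null(nm)) nm <- rep(".", length(gr))
    if (is.null(scores)) scores <- rep(0L, length(gr))
    strand[strand == "*"] <- "."
    out <- paste(chrom, start, end, nm, scores, strand, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a BEDPE file of paired anchors
#'
#' @param path Path to a BEDPE (>= 6 columns) file.
#' @return A [S4Vectors::Pairs] of two `GRanges` (anchor1, anchor2).
#' @export
readBedpeFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rtracklayer::import(path, format = "bedpe")
}

#' Read SAM alignments into a DataFrame
#'
#' Reads a text SAM file through `Rsamtools` and returns the fields this
#' pipeline uses: query name, flag, chromosome, 1-based leftmost position,
#' mapping quality, CIGAR, the NM mismatch tag (NA when absent), whether an
#' XA alternate-hits tag is present, and the reference span implied by the
#' CIGAR. Unmapped records are retained with `chrom`/`pos` set to NA.
#' Records are returned in coordinate-sorted order (mapped first), not file
#' order.
#'
#' @param path Path to a SAM file with `@SQ` headers.
#' @return A [S4Vectors::DataFrame] with columns `qname`, `flag`, `chrom`,
#'   `pos`, `mapq`, `cigar`, `nm`, `hasAltHits`, `refSpan`.
#' @export
#' @importFrom Rsamtools asBam scanBam ScanBamParam
readSamFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dest <- tempfile()
  bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = c("NM", "XA")))[[1L]]
  n <- length(res$qname)
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  xa <- res$tag$XA
  hasAltHits <- if (is.null(xa)) rep(FALSE, n) else !is.na(xa)
  S4Vectors::DataFrame(
    qname = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    pos = res$pos,
    mapq = res$mapq,
    cigar = res$cigar,
    nm = nm,
    hasAltHits = hasAltHits,
    refSpan = cigarReferenceSpan(res$cigar)
  )
}

#' Convert mapped alignment records to loci
#'
#' A mapped record at 1-based SAM position `pos` spanning `refSpan` reference
#' bases becomes the interval `pos .. pos + refSpan - 1` (1-based closed),
#' i.e. BED `[pos-1, pos-1+refSpan)`. Strand is collapsed to `*`.
#'
#' @param aln DataFrame from [readSamFile()]; unmapped rows are dropped.
#' @return A `GRanges`, one range per mapped record.
#' @export
alignmentsToLoci <- function(aln) {
  mapped <- !is.na(aln$pos) & bitwAnd(aln$flag, 0x4L) == 0L
  aln <- aln[mapped, , drop = FALSE]
  GenomicRanges::GRanges(aln$chrom,
                         IRanges::IRanges(aln$pos, width = aln$refSpan))
}

#' Write a tab-separated result table
#'
#' Writes a header line plus one row per record, unquoted, with full numeric
#' precision. When the first three columns are `chrom`, `start`, `end` the
#' body is BED-compatible.
#'
#' @param df A data.frame (all rows sharing one schema).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
#' @importFrom utils write.table
writeResultTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a table written by [writeResultTable()]
#'
#' @param path Path to a TSV with a header line.
#' @return A data.frame.
#' @export
#' @importFrom utils read.delim
readResultTable <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
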