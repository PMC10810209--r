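#' Alignment retention filters
#'
#' A record is retained iff it is mapped, is neither secondary (0x100) nor
#' supplementary (0x800), carries no alternate-hit (XA) tag, has mapping
#' quality at least `minMapq`, spans exactly `insertLength` reference bases,
#' and has at most `maxMismatches` mismatches (NM tag). A missing NM tag
#' fails the filter unless `assumeNm0 = TRUE`.
#'
#' @param aln DataFrame from [readSamFile()].
#' @param maxMismatches Maximum NM value retained (default 2).
#' @param insertLength Required reference span in bp (default 25).
#' @param minMapq Minimum mapping quality defining "uniquely mapped"
#'   together with the XA check (default 1).
#' @param assumeNm0 Treat a missing NM tag as 0 mismatches (default FALSE).
#' @return Logical vector, one element per record.
#' @export
alignmentPassesFilters <- function(aln, maxMismatches = 2L,
                                   insertLength = 25L, minMapq = 1L,
                                   assumeNm0 = FALSE) {
  flag <- aln$flag
  mapped <- bitwAnd(flag, 0x4L) == 0L & !is.na(aln$pos)
  primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  uniqueHit <- !aln$hasAltHits & !is.na(aln$mapq) & aln$mapq >= minMapq
  spanOk <- !is.na(aln$refSpan) & aln$refSpan == insertLength
  nm <- aln$nm
  if (assumeNm0) nm[is.na(nm)] <- 0L
  nmOk <- !is.na(nm) & nm <= maxMismatches
  mapped & primary & uniqueHit & spanOk & nmOk
}

## Tabulate a GRanges of equal-width loci into a LocusCounts, collapsing
## strand. recordsSeen is the pre-filter record count for bookkeeping.
.tabulateLoci <- function(gr, insertLength, recordsSeen) {
  GenomicRanges::strand(gr) <- "*"
  if (length(gr) == 0L) {
    u <- GenomicRanges::GRanges()
    u$count <- integer(0)
    return(LocusCounts(u, insertLength, totalRetained = 0,
                       totalRecordsSeen = recordsSeen))
  }
  u <- unique(gr)
  idx <- GenomicRanges::match(gr, u)
  u$count <- tabulate(idx, nbins = length(u))
  LocusCounts(u, insertLength, totalRetained = length(gr),
              totalRecordsSeen = recordsSeen)
}

#' @describeIn countLoci Count from alignment records: applies
#'   [alignmentPassesFilters()], converts each passing record to its locus,
#'   and tabulates. PCR duplicates are deliberately retained (identical
#'   inserts are indistinguishable); conservation holds: the counts sum to
#'   the number of retained records.
#' @param maxMismatches,insertLength,minMapq,assumeNm0 See
#'   [alignmentPassesFilters()].
#' @param knownChroms Optional character vector of expected chromosome names;
#'   records on other chromosomes raise a warning but are counted.
#' @export
setMethod("countLoci", "DataFrame", function(x, maxMismatches = 2L,
                                             insertLength = 25L,
                                             minMapq = 1L,
                                             assumeNm0 = FALSE,
                                             knownChroms = NULL) {
  keep <- alignmentPassesFilters(x, maxMismatches = maxMismatches,
                                 insertLength = insertLength,
                                 minMapq = minMapq, assumeNm0 = assumeNm0)
  aln <- x[keep, , drop = FALSE]
  if (!is.null(knownChroms)) {
    stray <- setdiff(unique(aln$chrom), knownChroms)
    if (length(stray))
      warning("records on chromosomes absent from the genome manifest: ",
              paste(stray, collapse = ", "), " (counted anyway)")
  }
  gr <- GenomicRanges::GRanges(aln$chrom,
                               IRanges::IRanges(aln$pos, width = aln$refSpan))
  .tabulateLoci(gr, insertLength, recordsSeen = nrow(x))
})

#' @describeIn countLoci Count from pre-extracted fragment coordinates
#'   (e.g. a BED of fragment positions). All intervals must already have
#'   width `insertLength`; others raise an error.
#' @export
setMethod("countLoci", "GRanges", function(x, insertLength = 25L, ...) {
  if (length(x) && any(GenomicRanges::width(x) != insertLength))
    stop("all fragment intervals must have width ", insertLength)
  .tabulateLoci(granges(x), insertLength, recordsSeen = length(x))
})

#' Pair input and output count tables over the union of loci
#'
#' Builds a `RangedSummarizedExperiment` whose rows are the union of loci
#' seen in either library (sorted by coordinate) and whose single `counts`
#' assay holds the raw input (`x`) and output (`y`) counts, with 0 where a
#' locus was absent from one side. Pairing is symmetric up to the column
#' swap.
#'
#' @param input,output [LocusCounts-class] objects with equal insert length.
#' @return A `RangedSummarizedExperiment` with assay `counts` (columns
#'   `input`, `output`), `colData` columns `totalRetained` and
#'   `totalRecordsSeen`, and `metadata()$insertLength`.
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
#'   colData
pairCounts <- function(input, output) {
  stopifnot(is(input, "LocusCounts"), is(output, "LocusCounts"))
  if (insertLength(input) != insertLength(output))
    stop("insert length mismatch between the two count tables: ",
         insertLength(input), " vs ", insertLength(output))
  gin <- lociCounts(input)
  gout <- lociCounts(output)
  u <- unique(c(granges(gin), granges(gout)))
  # coordinate order with chromosomes compared as strings, so the row order
  # is independent of which table came first
  u <- u[order(as.character(GenomicRanges::seqnames(u)),
               GenomicRanges::start(u), GenomicRanges::end(u))]
  xv <- integer(length(u))
  yv <- integer(length(u))
  xv[GenomicRanges::match(granges(gin), u)] <- gin$count
  yv[GenomicRanges::match(granges(gout), u)] <- gout$count
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cbind(input = xv, output = yv)),
    rowRanges = u,
    colData = S4Vectors::DataFrame(
      totalRetained = c(totalRetained(input), totalRetained(output)),
      totalRecordsSeen = c(totalRecordsSeen(input),
                           totalRecordsSeen(output)),
      row.names = c("input", "output"))
  )
  S4Vectors::metadata(se)$insertLength <- insertLength(input)
  se
}

#' Write a LocusCounts table as TSV
#'
#' Columns `chrom`, `start`, `end` (BED convention), `count`.
#'
#' @param counts A [LocusCounts-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeCountsTable <- function(counts, path) {
  gr <- lociCounts(counts)
  writeResultTable(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    count = gr$count), path)
}

#' Read a counts TSV back into LocusCounts
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `count` (BED
#'   convention coordinates).
#' @param insertLength Locus width to enforce.
#' @param totalRecordsSeen Optional pre-filter record count; defaults to the
#'   sum of counts.
#' @return A [LocusCounts-class].
#' @export
readCountsTable <- function(path, insertLength = 25L,
                            totalRecordsSeen = NULL) {
  df <- readResultTable(path)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(df)))
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end))
  gr$count <- df$count
  tot <- sum(as.numeric(df$count))
  LocusCounts(gr, insertLength, totalRetained = tot,
              totalRecordsSeen = if (is.null(totalRecordsSeen)) tot
                                 else totalRecordsSeen)
}
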