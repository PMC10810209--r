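#' @import methods
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
NULL

## The arm sequences of the standard one-step screening construct: the 25-bp
## random fragment sits between a left homology/adapter arm ending in the
## Tn5 mosaic end and a right arm starting with its reverse complement.
.DEFAULT_LEFT_ARM <- paste0(
  "CTAACTGGCCGGTACCTGAGCTCGCTAGCCTCGAGTCGTCGGCAGCGTCAGATGTGTATAAGAGACAG"
)
.DEFAULT_RIGHT_ARM <- paste0(
  "CTGTCTCTTATACACATCTCCGAGCCCACGAGACAAGCTTAGACACTAGAGGGTATATAATGGAAGCTCG"
)

#' Construct geometry for insert extraction
#'
#' Describes the fixed flanking arms around the random insert in a reporter
#' construct, how much of each arm is actually searched for (the anchor), the
#' expected insert length, and the Hamming mismatch tolerance of the anchor
#' search. Defaults describe the standard 25-bp screening construct.
#'
#' @slot leftArm Sequence 5' of the insert (character).
#' @slot rightArm Sequence 3' of the insert (character).
#' @slot insertLength Expected insert length in bp; inserts of any other
#'   length are discarded.
#' @slot maxArmMismatches Maximum Hamming mismatches tolerated per anchor.
#' @slot anchorLength How many bases of each arm are searched: the suffix of
#'   `leftArm` and the prefix of `rightArm`.
#'
#' @export
setClass("ConstructSpec",
  representation(
    leftArm = "character",
    rightArm = "character",
    insertLength = "integer",
    maxArmMismatches = "integer",
    anchorLength = "integer"
  )
)

setValidity("ConstructSpec", function(object) {
  msg <- character()
  if (length(object@leftArm) != 1L || nchar(object@leftArm) == 0L)
    msg <- c(msg, "'leftArm' must be a single non-empty sequence")
  if (length(object@rightArm) != 1L || nchar(object@rightArm) == 0L)
    msg <- c(msg, "'rightArm' must be a single non-empty sequence")
  if (length(object@insertLength) != 1L || is.na(object@insertLength) ||
      object@insertLength < 1L)
    msg <- c(msg, "'insertLength' must be >= 1")
  if (length(object@maxArmMismatches) != 1L || object@maxArmMismatches < 0L)
    msg <- c(msg, "'maxArmMismatches' must be >= 0")
  if (length(object@anchorLength) != 1L || object@anchorLength < 1L)
    msg <- c(msg, "'anchorLength' must be >= 1")
  if (length(msg) == 0L &&
      (object@anchorLength > nchar(object@leftArm) ||
       object@anchorLength > nchar(object@rightArm)))
    msg <- c(msg, "'anchorLength' cannot exceed the length of either arm")
  if (length(msg)) msg else TRUE
})

#' @param leftArm,rightArm Arm sequences flanking the insert.
#' @param insertLength Expected insert length (default 25).
#' @param maxArmMismatches Hamming mismatch tolerance per anchor (default 1).
#' @param anchorLength Searched anchor length (default 20).
#' @return A [ConstructSpec-class] object.
#' @examples
#' spec <- ConstructSpec()
#' leftAnchor(spec)
#' @rdname ConstructSpec-class
#' @export
ConstructSpec <- function(leftArm = .DEFAULT_LEFT_ARM,
                          rightArm = .DEFAULT_RIGHT_ARM,
                          insertLength = 25L,
                          maxArmMismatches = 1L,
                          anchorLength = 20L) {
  new("ConstructSpec",
      leftArm = toupper(as.character(leftArm)),
      rightArm = toupper(as.character(rightArm)),
      insertLength = as.integer(insertLength),
      maxArmMismatches = as.integer(maxArmMismatches),
      anchorLength = as.integer(anchorLength))
}

#' Per-library sequencing and amplification parameters
#'
#' Holds the quantities entering count normalization: the library's total
#' (retained) read count N, the per-cycle PCR amplification efficiency p,
#' and the number of PCR cycles c. Expected amplification per molecule is
#' (1+p)^c.
#'
#' @slot totalReads Total reads N (>= 1).
#' @slot pcrEfficiency Per-cycle duplication probability p in (0, 1].
#' @slot pcrCycles Number of PCR cycles c (>= 1).
#'
#' @export
setClass("LibraryStats",
  representation(
    totalReads = "numeric",
    pcrEfficiency = "numeric",
    pcrCycles = "integer"
  )
)

setValidity("LibraryStats", function(object) {
  msg <- character()
  if (length(object@totalReads) != 1L || is.na(object@totalReads) ||
      object@totalReads < 1)
    msg <- c(msg, "'totalReads' must be >= 1")
  if (length(object@pcrEfficiency) != 1L || is.na(object@pcrEfficiency) ||
      object@pcrEfficiency <= 0 || object@pcrEfficiency > 1)
    msg <- c(msg, "'pcrEfficiency' must be in (0, 1]")
  if (length(object@pcrCycles) != 1L || is.na(object@pcrCycles) ||
      object@pcrCycles < 1L)
    msg <- c(msg, "'pcrCycles' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param totalReads Total reads N.
#' @param pcrEfficiency Per-cycle efficiency p (default 1).
#' @param pcrCycles Number of PCR cycles c.
#' @return A [LibraryStats-class] object.
#' @examples
#' LibraryStats(1000, pcrCycles = 15)
#' @rdname LibraryStats-class
#' @export
LibraryStats <- function(totalReads, pcrEfficiency = 1, pcrCycles) {
  new("LibraryStats",
      totalReads = as.numeric(totalReads),
      pcrEfficiency = as.numeric(pcrEfficiency),
      pcrCycles = as.integer(pcrCycles))
}

#' Read-preparation tallies
#'
#' Counters along the insert-extraction filter chain. They are monotone:
#' `emitted <= lengthPass <= armsFound <= totalReads`.
#'
#' @slot totalReads Reads seen.
#' @slot armsFound Reads where both arm anchors were located.
#' @slot lengthPass Reads whose between-arm sequence had the expected length.
#' @slot emitted Inserts written out.
#' @export
setClass("PrepStats",
  representation(
    totalReads = "numeric",
    armsFound = "numeric",
    lengthPass = "numeric",
    emitted = "numeric"
  )
)

setValidity("PrepStats", function(object) {
  v <- c(object@emitted, object@lengthPass, object@armsFound,
         object@totalReads)
  if (any(is.na(v)) || any(v < 0))
    return("all counters must be non-negative")
  if (is.unsorted(v))
    return("counters must satisfy emitted <= lengthPass <= armsFound <= totalReads")
  TRUE
})

PrepStats <- function(totalReads = 0, armsFound = 0, lengthPass = 0,
                      emitted = 0) {
  new("PrepStats", totalReads = as.numeric(totalReads),
      armsFound = as.numeric(armsFound),
      lengthPass = as.numeric(lengthPass),
      emitted = as.numeric(emitted))
}

#' Per-locus fragment counts for one library
#'
#' Raw fragment counts keyed by genomic locus, where a locus is a fixed-width
#' interval (the insert length) identified by chromosome, start and end only
#' (strand collapsed). PCR duplicates are retained by design: identical
#' 25-mers cannot be deduplicated, so the count model absorbs amplification
#' via normalization instead.
#'
#' @slot loci `GRanges` of distinct loci with a `count` metadata column.
#' @slot insertLength Locus width enforced on every interval.
#' @slot totalRetained Sum of counts == number of records that passed filters.
#' @slot totalRecordsSeen Number of records examined before filtering.
#' @export
setClass("LocusCounts",
  representation(
    loci = "GRanges",
    insertLength = "integer",
    totalRetained = "numeric",
    totalRecordsSeen = "numeric"
  )
)

setValidity("LocusCounts", function(object) {
  msg <- character()
  w <- GenomicRanges::width(object@loci)
  if (length(w) && any(w != object@insertLength))
    msg <- c(msg, "all loci must have width == insertLength")
  cnt <- object@loci$count
  if (is.null(cnt) && length(object@loci))
    msg <- c(msg, "loci must carry a 'count' metadata column")
  if (!is.null(cnt)) {
    if (any(is.na(cnt)) || any(cnt < 0))
      msg <- c(msg, "counts must be non-negative")
    if (!isTRUE(all.equal(sum(as.numeric(cnt)), object@totalRetained)))
      msg <- c(msg, "sum(counts) must equal totalRetained")
  }
  if (object@totalRetained > object@totalRecordsSeen)
    msg <- c(msg, "totalRetained cannot exceed totalRecordsSeen")
  if (length(msg)) msg else TRUE
})

LocusCounts <- function(loci, insertLength = 25L, totalRetained = sum(as.numeric(loci$count)),
                        totalRecordsSeen = totalRetained) {
  new("LocusCounts", loci = loci, insertLength = as.integer(insertLength),
      totalRetained = as.numeric(totalRetained),
      totalRecordsSeen = as.numeric(totalRecordsSeen))
}

#' Enhancer-calling results
#'
#' Per-locus test results from [callEnhancers()] together with the fitted
#' model constants: the zoom factor, the input/output normalization
#' coefficients, and the compensation value used for loci missing from the
#' input library.
#'
#' @slot calls `GRanges` with metadata columns `x`, `y` (raw counts), `fIn`,
#'   `fOut` (normalized), `lambda`, `k`, `pvalue`, `qvalue`, `called`,
#'   `compensated`.
#' @slot parameters Named list: `omega`, `coefIn`, `coefOut`, `kappa`,
#'   `alpha`, `omegaMode`, `logBase`, `kMode`, `compensationMultiplier`,
#'   `nTested`, `nCalled`.
#' @export
setClass("MaeCalls",
  representation(calls = "GRanges", parameters = "list")
)

setValidity("MaeCalls", function(object) {
  need <- c("x", "y", "fIn", "fOut", "lambda", "k", "pvalue", "qvalue",
            "called", "compensated")
  have <- colnames(mcols(object@calls))
  if (!all(need %in% have))
    return(paste("calls must carry metadata columns:",
                 paste(setdiff(need, have), collapse = ", ")))
  p <- c("omega", "coefIn", "coefOut", "kappa", "alpha")
  if (!all(p %in% names(object@parameters)))
    return("parameters must include omega, coefIn, coefOut, kappa, alpha")
  TRUE
})
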