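#' @rdname ConstructSpec-class
#' @param object,x An object.
#' @export
setGeneric("leftArm", function(x) standardGeneric("leftArm"))
#' @rdname ConstructSpec-class
#' @export
setGeneric("rightArm", function(x) standardGeneric("rightArm"))
#' @rdname ConstructSpec-class
#' @export
setGeneric("insertLength", function(x) standardGeneric("insertLength"))
#' @rdname ConstructSpec-class
#' @export
setGeneric("leftAnchor", function(x) standardGeneric("leftAnchor"))
#' @rdname ConstructSpec-class
#' @export
setGeneric("rightAnchor", function(x) standardGeneric("rightAnchor"))

#' @rdname LibraryStats-class
#' @param x An object.
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname LibraryStats-class
#' @export
setGeneric("pcrEfficiency", function(x) standardGeneric("pcrEfficiency"))
#' @rdname LibraryStats-class
#' @export
setGeneric("pcrCycles", function(x) standardGeneric("pcrCycles"))

#' @rdname LocusCounts-class
#' @param x An object.
#' @export
setGeneric("lociCounts", function(x) standardGeneric("lociCounts"))
#' @rdname LocusCounts-class
#' @export
setGeneric("totalRetained", function(x) standardGeneric("totalRetained"))
#' @rdname LocusCounts-class
#' @export
setGeneric("totalRecordsSeen", function(x) standardGeneric("totalRecordsSeen"))

#' Count loci from filtered records
#'
#' @param x Alignment records (a `DataFrame` from [readSamFile()]) or a
#'   `GRanges` of pre-extracted fragment coordinates.
#' @param ... Filter parameters passed to the methods.
#' @return A [LocusCounts-class] object.
#' @export
setGeneric("countLoci", function(x, ...) standardGeneric("countLoci"))

#' @rdname MaeCalls-class
#' @param x An object.
#' @export
setGeneric("callTable", function(x) standardGeneric("callTable"))
#' @rdname MaeCalls-class
#' @export
setGeneric("calledLoci", function(x) standardGeneric("calledLoci"))
#' @rdname MaeCalls-class
#' @export
setGeneric("modelParameters", function(x) standardGeneric("modelParameters"))

## ---- accessor methods ----

#' @rdname ConstructSpec-class
#' @export
setMethod("leftArm", "ConstructSpec", function(x) x@leftArm)
#' @rdname ConstructSpec-class
#' @export
setMethod("rightArm", "ConstructSpec", function(x) x@rightArm)
#' @rdname ConstructSpec-class
#' @export
setMethod("insertLength", "ConstructSpec", function(x) x@insertLength)
#' @rdname LocusCounts-class
#' @export
setMethod("insertLength", "LocusCounts", function(x) x@insertLength)
#' @rdname ConstructSpec-class
#' @export
setMethod("leftAnchor", "ConstructSpec", function(x)
  substr(x@leftArm, nchar(x@leftArm) - x@anchorLength + 1L, nchar(x@leftArm)))
#' @rdname ConstructSpec-class
#' @export
setMethod("rightAnchor", "ConstructSpec", function(x)
  substr(x@rightArm, 1L, x@anchorLength))

#' @rdname LibraryStats-class
#' @export
setMethod("totalReads", "LibraryStats", function(x) x@totalReads)
#' @rdname LibraryStats-class
#' @export
setMethod("pcrEfficiency", "LibraryStats", function(x) x@pcrEfficiency)
#' @rdname LibraryStats-class
#' @export
setMethod("pcrCycles", "LibraryStats", function(x) x@pcrCycles)

#' @rdname LocusCounts-class
#' @export
setMethod("lociCounts", "LocusCounts", function(x) x@loci)
#' @rdname LocusCounts-class
#' @export
setMethod("totalRetained", "LocusCounts", function(x) x@totalRetained)
#' @rdname LocusCounts-class
#' @export
setMethod("totalRecordsSeen", "LocusCounts", function(x) x@totalRecordsSeen)

#' @rdname MaeCalls-class
#' @export
setMethod("callTable", "MaeCalls", function(x) {
  gr <- x@calls
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # BED convention on output
    end = GenomicRanges::end(gr),
    as.data.frame(mcols(gr)),
    stringsAsFactors = FALSE
  )
})
#' @rdname MaeCalls-class
#' @export
setMethod("calledLoci", "MaeCalls", function(x) x@calls[x@calls$called])
#' @rdname MaeCalls-class
#' @export
setMethod("modelParameters", "MaeCalls", function(x) x@parameters)

## ---- show methods ----

setMethod("show", "ConstructSpec", function(object) {
  cat("ConstructSpec:", object@insertLength, "bp insert\n")
  cat("  left anchor : ", leftAnchor(object), "\n", sep = "")
  cat("  right anchor: ", rightAnchor(object), "\n", sep = "")
  cat("  max mismatches per anchor:", object@maxArmMismatches, "\n")
})

setMethod("show", "LibraryStats", function(object) {
  cat(sprintf("LibraryStats: N = %g, p = %g, c = %d cycles\n",
              object@totalReads, object@pcrEfficiency, object@pcrCycles))
})

setMethod("show", "PrepStats", function(object) {
  cat(sprintf(
    "PrepStats: %g reads; arms found %g; length pass %g; emitted %g\n",
    object@totalReads, object@armsFound, object@lengthPass, object@emitted))
})

setMethod("show", "LocusCounts", function(object) {
  cat(sprintf(
    "LocusCounts: %d loci of %d bp; %g retained of %g records\n",
    length(object@loci), object@insertLength, object@totalRetained,
    object@totalRecordsSeen))
})

setMethod("show", "MaeCalls", function(object) {
  p <- object@parameters
  cat("MaeCalls:", length(object@calls), "loci\n")
  cat(sprintf("  omega = %g (%s), coefIn = %g, coefOut = %g, kappa = %g\n",
              p$omega, p$omegaMode, p$coefIn, p$coefOut, p$kappa))
  cat(sprintf("  tested %d, called %d at Q < %g\n",
              p$nTested, p$nCalled, p$alpha))
})
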