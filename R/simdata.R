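#' Simulate a genome with an optional repeat family
#'
#' Bases are drawn i.i.d. uniform over A/C/G/T; then, when
#' `repeatFraction > 0`, the last `repeatFraction` of each chromosome is
#' overwritten with tandem copies of one independently drawn repeat unit, so
#' that k-mers inside the repeat region occur many times (non-uniquely
#' mappable) while the untouched portion stays essentially unique. At census
#' the unique-mapping rate is therefore close to `1 - repeatFraction`.
#'
#' @param genomeLength Total genome length in bp (split evenly over
#'   chromosomes).
#' @param nChroms Number of chromosomes (default 1).
#' @param repeatFraction Fraction of each chromosome overwritten by repeats,
#'   in `[0, 1)`.
#' @param repeatUnitLength Length of the repeat unit (default 500).
#' @param seed Optional integer seed.
#' @return List with `genome` (`DNAStringSet`, names `chr1..chrN`) and
#'   `repeats` (`GRanges` of the overwritten regions).
#' @export
simulateGenome <- function(genomeLength = 1e5, nChroms = 1L,
                           repeatFraction = 0, repeatUnitLength = 500L,
                           seed = NULL) {
  .assertScalarNumber(genomeLength, "genomeLength", min = 1)
  .assertScalarNumber(nChroms, "nChroms", min = 1)
  if (repeatFraction < 0 || repeatFraction >= 1)
    stop("'repeatFraction' must be in [0, 1)")
  withSeed(seed, {
    per <- floor(genomeLength / nChroms)
    bases <- c("A", "C", "G", "T")
    unit <- if (repeatFraction > 0)
      paste(sample(bases, repeatUnitLength, replace = TRUE), collapse = "")
    else NULL
    seqs <- character(nChroms)
    repGr <- GenomicRanges::GRanges()
    for (i in seq_len(nChroms)) {
      s <- paste(sample(bases, per, replace = TRUE), collapse = "")
      if (repeatFraction > 0) {
        nRep <- floor(per * repeatFraction)
        if (nRep > 0) {
          tandem <- substr(strrep(unit, ceiling(nRep / repeatUnitLength)),
                           1L, nRep)
          substr(s, per - nRep + 1L, per) <- tandem
          repGr <- c(repGr, GenomicRanges::GRanges(
            paste0("chr", i),
            IRanges::IRanges(per - nRep + 1L, per)))
        }
      }
      seqs[i] <- s
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- paste0("chr", seq_len(nChroms))
    list(genome = genome, repeats = repGr)
  })
}

#' Galton-Watson PCR amplification
#'
#' Each molecule duplicates independently with probability `p` at every
#' cycle: `m[t+1] = m[t] + Binomial(m[t], p)`. The expected amplification
#' after `c` cycles is `(1+p)^c`; with `p = 1` every count is exactly
#' `2^c` (duplication is certain).
#'
#' @param molecules Integer vector of starting molecule counts (one per
#'   fragment species).
#' @param p Per-cycle duplication probability in (0, 1].
#' @param cycles Number of cycles.
#' @return Numeric vector of post-PCR molecule counts.
#' @export
#' @importFrom stats rbinom
pcrAmplify <- function(molecules, p = 1, cycles) {
  .assertScalarNumber(p, "p", min = .Machine$double.xmin, max = 1)
  .assertScalarNumber(cycles, "cycles", min = 1)
  m <- as.numeric(molecules)
  for (i in seq_len(cycles)) {
    m <- m + stats::rbinom(length(m), size = m, prob = p)
  }
  m
}

#' Simulate a complete input/output enhancer screen
#'
#' Draws `nFragments` distinct fixed-length fragment loci from the genome,
#' plants `nEnhancers` of them as enhancers with the given enrichment fold,
#' amplifies each library by an independent Galton-Watson PCR (each molecule
#' duplicating with probability `pcrEfficiency` per cycle), and samples reads
#' multinomially: the input library over the post-PCR molecule counts, the
#' output library over post-PCR counts additionally weighted by each
#' fragment's enrichment fold. Defaults describe a screen of 5000 distinct
#' fragments sequenced to 5e5 reads per library with 15 PCR cycles on both
#' sides.
#'
#' @param genome `DNAStringSet` (e.g. from [simulateGenome()]).
#' @param nFragments Number of distinct fragment loci M.
#' @param nEnhancers Number of planted enhancers.
#' @param enrichmentFold Fold enrichment of enhancer fragments in the output
#'   sampling weights: a scalar, or a length-2 range sampled uniformly.
#' @param depthInput,depthOutput Total reads per library.
#' @param pcrEfficiency Per-cycle duplication probability p (default 1).
#' @param pcrCyclesInput,pcrCyclesOutput PCR cycles per library (default 15).
#' @param fragmentLength Fragment length in bp (default 25).
#' @param seed Optional integer seed.
#' @return List with:
#'   `paired` (`RangedSummarizedExperiment` from [pairCounts()]),
#'   `inputCounts`, `outputCounts` ([LocusCounts-class], zero-count loci
#'   dropped as in real data), `truth` (list: `enhancers` `GRanges` with
#'   `fold`, `fragments` `GRanges` with per-fragment molecule and read
#'   counts), `inputStats`, `outputStats` ([LibraryStats-class]).
#' @export
#' @importFrom stats rmultinom
simulateScreen <- function(genome,
                           nFragments = 5000L,
                           nEnhancers = 50L,
                           enrichmentFold = 20,
                           depthInput = 5e5,
                           depthOutput = 5e5,
                           pcrEfficiency = 1,
                           pcrCyclesInput = 15L,
                           pcrCyclesOutput = 15L,
                           fragmentLength = 25L,
                           seed = NULL) {
  stopifnot(is(genome, "DNAStringSet"))
  .assertScalarNumber(nFragments, "nFragments", min = 1)
  .assertScalarNumber(nEnhancers, "nEnhancers", min = 0)
  if (nEnhancers > nFragments)
    stop("'nEnhancers' cannot exceed 'nFragments'")
  if (any(enrichmentFold < 1))
    stop("'enrichmentFold' must be >= 1")
  w <- pmax(Biostrings::width(genome) - fragmentLength + 1L, 0L)
  if (nFragments > sum(w))
    stop("'nFragments' exceeds the ", sum(w),
         " distinct fragment positions available")
  withSeed(seed, {
    # distinct (chrom, offset) positions via one global index
    gidx <- sample.int(sum(w), nFragments)
    cum <- cumsum(w)
    ci <- findInterval(gidx - 1L, cum) + 1L
    off <- gidx - c(0L, cum)[ci]
    frags <- GenomicRanges::GRanges(
      names(genome)[ci], IRanges::IRanges(off, width = fragmentLength))
    frags <- sort(frags)

    fold <- rep(1, nFragments)
    enhIdx <- if (nEnhancers > 0) sample.int(nFragments, nEnhancers)
              else integer(0)
    fold[enhIdx] <- if (length(enrichmentFold) == 2L)
      stats::runif(nEnhancers, enrichmentFold[1L], enrichmentFold[2L])
    else enrichmentFold

    molsIn <- pcrAmplify(rep(1L, nFragments), pcrEfficiency, pcrCyclesInput)
    molsOut <- pcrAmplify(rep(1L, nFragments), pcrEfficiency,
                          pcrCyclesOutput)
    xv <- as.vector(stats::rmultinom(1L, depthInput, prob = molsIn))
    yv <- as.vector(stats::rmultinom(1L, depthOutput,
                                     prob = molsOut * fold))

    mkCounts <- function(counts, depth) {
      keep <- counts > 0L
      gr <- frags[keep]
      gr$count <- counts[keep]
      LocusCounts(gr, fragmentLength, totalRetained = depth,
                  totalRecordsSeen = depth)
    }
    inputCounts <- mkCounts(xv, depthInput)
    outputCounts <- mkCounts(yv, depthOutput)

    truthFrags <- frags
    truthFrags$fold <- fold
    truthFrags$moleculesInput <- molsIn
    truthFrags$moleculesOutput <- molsOut
    truthFrags$countInput <- xv
    truthFrags$countOutput <- yv
    enh <- frags[enhIdx]
    enh$fold <- fold[enhIdx]
    list(
      paired = pairCounts(inputCounts, outputCounts),
      inputCounts = inputCounts,
      outputCounts = outputCounts,
      truth = list(enhancers = sort(enh), fragments = truthFrags),
      inputStats = LibraryStats(depthInput, pcrEfficiency, pcrCyclesInput),
      outputStats = LibraryStats(depthOutput, pcrEfficiency,
                                 pcrCyclesOutput)
    )
  })
}

## Extract the sequences under GRanges from an in-memory DNAStringSet genome.
.getFragmentSeqs <- function(genome, gr) {
  chr <- as.character(GenomicRanges::seqnames(gr))
  out <- character(length(gr))
  for (cn in unique(chr)) {
    i <- which(chr == cn)
    v <- Biostrings::Views(genome[[cn]], GenomicRanges::start(gr)[i],
                           GenomicRanges::end(gr)[i])
    out[i] <- as.character(v)
  }
  Biostrings::DNAStringSet(out)
}

#' Emit construct-flanked reads for a simulated library
#'
#' One read per sequenced fragment copy: `leftArm + fragment + rightArm`
#' with constant quality, enabling the full extract-count-call path on the
#' simulated screen. Intended for small screens; read count equals the
#' library depth.
#'
#' @param screen Result of [simulateScreen()].
#' @param genome The `DNAStringSet` the screen was simulated from.
#' @param library `"input"` or `"output"`.
#' @param spec A [ConstructSpec-class]; its arms wrap each fragment.
#' @return A `QualityScaledDNAStringSet` of reads, ids
#'   `<library>_<fragIndex>_<copy>`.
#' @export
#' @importFrom Biostrings BStringSet PhredQuality
screenReads <- function(screen, genome, library = c("input", "output"),
                        spec = ConstructSpec()) {
  library <- match.arg(library)
  tf <- screen$truth$fragments
  counts <- if (library == "input") tf$countInput else tf$countOutput
  idx <- rep(seq_along(tf), counts)
  fragSeqs <- .getFragmentSeqs(genome, tf)
  reads <- buildConstructReads(fragSeqs[idx], spec)
  copy <- sequence(counts)
  names(reads) <- paste0(library, "_", idx, "_", copy)
  qual <- Biostrings::PhredQuality(
    Biostrings::BStringSet(strrep("I", Biostrings::width(reads))))
  Biostrings::QualityScaledDNAStringSet(reads, qual)
}

#' Write perfect alignments for a simulated library as SAM text
#'
#' Emits one mapped record per sequenced fragment copy at the fragment's
#' true position (`flag 0`, `mapq 60`, CIGAR `<L>M`, `NM:i:0`), plus `@SQ`
#' headers from the genome. This stands in for an external aligner when
#' exercising the counting stage on simulated data.
#'
#' @param screen Result of [simulateScreen()].
#' @param genome The `DNAStringSet` the screen was simulated from.
#' @param path Output SAM path.
#' @param library `"input"` or `"output"`.
#' @return The path, invisibly.
#' @export
writeScreenSam <- function(screen, genome, path,
                           library = c("input", "output")) {
  library <- match.arg(library)
  tf <- screen$truth$fragments
  counts <- if (library == "input") tf$countInput else tf$countOutput
  idx <- rep(seq_along(tf), counts)
  copy <- sequence(counts)
  L <- GenomicRanges::width(tf)[1L]
  seqs <- as.character(.getFragmentSeqs(genome, tf))[idx]
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(genome), "\tLN:",
                  Biostrings::width(genome)))
  body <- paste(
    paste0(library, "_", idx, "_", copy), 0L,
    as.character(GenomicRanges::seqnames(tf))[idx],
    GenomicRanges::start(tf)[idx], 60L, paste0(L, "M"), "*", 0L, 0L,
    seqs, strrep("I", L), "NM:i:0", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Evaluate calls against simulation truth
#'
#' A called locus is a true positive iff its interval coincides exactly with
#' a planted enhancer fragment. With zero calls, precision is reported as 1
#' and flagged.
#'
#' @param calls A [MaeCalls-class].
#' @param truth The `truth` element of [simulateScreen()] (or a `GRanges`
#'   of enhancer intervals).
#' @return List: `precision`, `recall`, `empiricalFdr`, `nCalled`,
#'   `nTruePositives`, `nEnhancers`, `zeroCalls`.
#' @export
evaluateCalls <- function(calls, truth) {
  enh <- if (is(truth, "GRanges")) truth else truth$enhancers
  called <- granges(calledLoci(calls))
  GenomicRanges::strand(called) <- "*"
  enhG <- granges(enh)
  GenomicRanges::strand(enhG) <- "*"
  tp <- sum(!is.na(GenomicRanges::match(called, enhG)))
  zero <- length(called) == 0L
  precision <- if (zero) 1 else tp / length(called)
  recall <- if (length(enhG) == 0L) NA_real_ else tp / length(enhG)
  list(precision = precision, recall = recall,
       empiricalFdr = 1 - precision, nCalled = length(called),
       nTruePositives = tp, nEnhancers = length(enhG), zeroCalls = zero)
}
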