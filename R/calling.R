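#' Zoom factor from the two library totals
#'
#' The zoom factor rescales normalized fragment frequencies back onto a count
#' scale where a Poisson test is meaningful. With `d = floor(log10(MIN)) + 1`
#' (the number of decimal digits of the smaller total), `mode = "power"`
#' returns `10^d` (the next power of ten above the smaller library) and
#' `mode = "literal"` returns `10 * d` (the formula read literally). Power
#' mode is the default: it is the only reading that restores count-scale
#' magnitudes; literal mode is retained for fidelity. Symmetric in its two
#' arguments.
#'
#' @param totalInput,totalOutput Total read counts of the two libraries
#'   (both >= 1).
#' @param mode `"power"` (default) or `"literal"`.
#' @return The zoom factor, a positive number.
#' @examples
#' zoomFactor(1e6, 1e8)             # 1e7
#' zoomFactor(1e6, 1e8, "literal")  # 70
#' @export
zoomFactor <- function(totalInput, totalOutput,
                       mode = c("power", "literal")) {
  mode <- match.arg(mode)
  .assertScalarNumber(totalInput, "totalInput", min = 1)
  .assertScalarNumber(totalOutput, "totalOutput", min = 1)
  d <- floor(log10(min(totalInput, totalOutput))) + 1
  if (mode == "power") 10^d else 10 * d
}

#' Normalization coefficient for one library
#'
#' The per-read normalized weight `coef = omega / (N * c * log(1 + p))`,
#' where N, p, c come from the library's [LibraryStats-class] and omega is
#' the shared zoom factor. The denominator is the log of the expected PCR
#' amplification factor `(1+p)^c` scaled by library size; a locus's
#' normalized value is then `f(x) = x * coef`.
#'
#' @param stats A [LibraryStats-class].
#' @param omega Zoom factor from [zoomFactor()].
#' @param logBase `"natural"` (default) or `"base10"`.
#' @return The coefficient, a positive number.
#' @examples
#' normalizationCoefficient(LibraryStats(1000, 1, 15), 1e4)  # ~0.96180
#' @export
normalizationCoefficient <- function(stats, omega,
                                     logBase = c("natural", "base10")) {
  stopifnot(is(stats, "LibraryStats"))
  logBase <- match.arg(logBase)
  .assertScalarNumber(omega, "omega", min = .Machine$double.xmin)
  lg <- if (logBase == "natural") log(1 + stats@pcrEfficiency)
        else log10(1 + stats@pcrEfficiency)
  denom <- stats@totalReads * stats@pcrCycles * lg
  if (denom <= 0)
    stop("normalization denominator is zero (pcrEfficiency must be > 0)")
  omega / denom
}

#' Normalize a raw fragment count
#'
#' `f(x) = x * coef`: linear, with `f(0) = 0`.
#'
#' @param x Raw count(s), non-negative.
#' @param coef Coefficient from [normalizationCoefficient()].
#' @return Normalized value(s).
#' @export
normalizeCount <- function(x, coef) {
  if (any(is.na(x)) || any(x < 0)) stop("'x' must be non-negative")
  x * coef
}

#' Upper-tail Poisson p-value
#'
#' `P(K >= k | lambda)`, computed via the stable survival function (never by
#' naive subtraction of a cumulative sum). `k = 0` gives 1 for any lambda.
#'
#' @param k Observed count(s), non-negative integers.
#' @param lambda Expected count(s), non-negative.
#' @return Probabilities in `[0, 1]`; vectorized with recycling.
#' @examples
#' poissonUpperPvalue(5, 2)  # ~0.052653
#' @export
#' @importFrom stats ppois
poissonUpperPvalue <- function(k, lambda) {
  if (any(is.na(k)) || any(is.na(lambda)))
    stop("'k' and 'lambda' must not contain NA/NaN")
  if (any(k < 0) || any(lambda < 0))
    stop("'k' and 'lambda' must be non-negative")
  # P(K >= k) = P(K > k - 1)
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]), returned in
#' the input order.
#'
#' @param pvalues Probabilities in `[0, 1]`.
#' @return Q-values, same length and order.
#' @examples
#' bhAdjust(c(0.002, 0.01, 0.03, 0.04))  # 0.008 0.02 0.04 0.04
#' @export
#' @importFrom stats p.adjust
bhAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

## Core caller over plain vectors; shared by both callEnhancers methods.
.callCore <- function(loci, x, y, inputStats, outputStats,
                      compensationMultiplier, alpha, omegaMode, logBase,
                      kMode) {
  stopifnot(is(inputStats, "LibraryStats"), is(outputStats, "LibraryStats"))
  .assertScalarNumber(compensationMultiplier, "compensationMultiplier",
                      min = .Machine$double.xmin)
  .assertScalarNumber(alpha, "alpha", min = 0, max = 1)
  omega <- zoomFactor(totalReads(inputStats), totalReads(outputStats),
                      mode = omegaMode)
  coefIn <- normalizationCoefficient(inputStats, omega, logBase)
  coefOut <- normalizationCoefficient(outputStats, omega, logBase)
  kappa <- compensationMultiplier * coefIn

  fIn <- normalizeCount(x, coefIn)
  fOut <- normalizeCount(y, coefOut)
  lambda <- ifelse(x > 0, fIn, kappa)
  k <- as.integer(roundHalfAwayFromZero(fOut))
  tested <- y > 0

  pvalue <- rep(NA_real_, length(x))
  if (kMode == "rounded") {
    pvalue[tested] <- poissonUpperPvalue(k[tested], lambda[tested])
  } else {
    # continuous survival: P(K >= kappa_cont) = pgamma(lambda, shape)
    pvalue[tested] <- stats::pgamma(lambda[tested], shape = fOut[tested],
                                    lower.tail = TRUE)
  }
  qvalue <- rep(NA_real_, length(x))
  qvalue[tested] <- bhAdjust(pvalue[tested])
  called <- tested & !is.na(qvalue) & qvalue < alpha

  mcols(loci) <- S4Vectors::DataFrame(
    x = x, y = y, fIn = fIn, fOut = fOut, lambda = lambda, k = k,
    pvalue = pvalue, qvalue = qvalue, called = called,
    compensated = x == 0 & y > 0)
  new("MaeCalls", calls = loci, parameters = list(
    omega = omega, coefIn = coefIn, coefOut = coefOut, kappa = kappa,
    alpha = alpha, omegaMode = omegaMode, logBase = logBase, kMode = kMode,
    compensationMultiplier = compensationMultiplier,
    nTested = sum(tested), nCalled = sum(called)))
}

#' Call enhancers from paired input/output counts
#'
#' The enrichment model: one zoom factor omega is computed from the pair of
#' library totals and shared by both sides; each library gets its own
#' normalization coefficient. For a locus with input count `x > 0` the
#' Poisson expectation is `lambda = f_in(x)`; loci present in the output but
#' absent from the input (`x = 0`) receive the compensation value
#' `kappa = compensationMultiplier * coefIn` (one normalized input read by
#' default) instead of a zero expectation, so they are tested rather than
#' silently dropped or trivially significant. The observation is the
#' normalized output count rounded half away from zero (`kMode = "rounded"`)
#' or used as a continuous gamma-survival tail (`kMode = "continuous"`).
#' The test is one-sided for enrichment in the output; loci with `y = 0` are
#' not tested. Benjamini-Hochberg adjustment is applied across all tested
#' loci and a locus is called when `Q < alpha`.
#'
#' @param paired A `RangedSummarizedExperiment` from [pairCounts()], or a
#'   data.frame with columns `chrom`, `start`, `end` (BED convention), `x`,
#'   `y`.
#' @param inputStats,outputStats [LibraryStats-class] for the two libraries.
#' @param compensationMultiplier Multiple of the input normalization
#'   coefficient used as the compensation value (default 1).
#' @param alpha Q-value threshold (default 0.05).
#' @param omegaMode,logBase See [zoomFactor()], [normalizationCoefficient()].
#' @param kMode `"rounded"` (default) or `"continuous"`.
#' @param ... Passed through between methods.
#' @return A [MaeCalls-class] object.
#' @export
setGeneric("callEnhancers", function(paired, inputStats, outputStats, ...)
  standardGeneric("callEnhancers"))

#' @rdname callEnhancers
#' @export
setMethod("callEnhancers", "RangedSummarizedExperiment",
  function(paired, inputStats, outputStats, compensationMultiplier = 1,
           alpha = 0.05, omegaMode = c("power", "literal"),
           logBase = c("natural", "base10"),
           kMode = c("rounded", "continuous")) {
    cnt <- SummarizedExperiment::assay(paired, "counts")
    .callCore(SummarizedExperiment::rowRanges(paired),
              x = as.numeric(cnt[, "input"]), y = as.numeric(cnt[, "output"]),
              inputStats = inputStats, outputStats = outputStats,
              compensationMultiplier = compensationMultiplier, alpha = alpha,
              omegaMode = match.arg(omegaMode),
              logBase = match.arg(logBase), kMode = match.arg(kMode))
  })

#' @rdname callEnhancers
#' @export
setMethod("callEnhancers", "data.frame",
  function(paired, inputStats, outputStats, compensationMultiplier = 1,
           alpha = 0.05, omegaMode = c("power", "literal"),
           logBase = c("natural", "base10"),
           kMode = c("rounded", "continuous")) {
    need <- c("chrom", "start", "end", "x", "y")
    if (!all(need %in% names(paired)))
      stop("paired table must have columns: ", paste(need, collapse = ", "))
    loci <- GenomicRanges::GRanges(
      paired$chrom, IRanges::IRanges(paired$start + 1, paired$end))
    .callCore(loci, as.numeric(paired$x), as.numeric(paired$y),
              inputStats, outputStats, compensationMultiplier, alpha,
              match.arg(omegaMode), match.arg(logBase), match.arg(kMode))
  })

#' Calibration sweep over compensation multipliers
#'
#' Re-runs [callEnhancers()] for each multiplier of the input normalization
#' coefficient and reports, per multiplier, the number of called loci and
#' the fraction of called loci overlapping none of the annotated regions.
#' The two quantities trade off: higher compensation values are more
#' rigorous (fewer, cleaner calls), lower values retain more signals.
#'
#' @param paired See [callEnhancers()].
#' @param inputStats,outputStats [LibraryStats-class] objects.
#' @param annotatedRegions Non-empty `GRanges` of annotated regions (e.g.
#'   union of chromatin-mark peaks).
#' @param multipliers Numeric vector of compensation multipliers
#'   (default `seq(0.1, 3, by = 0.1)`).
#' @param alpha Q-value threshold (default 0.05).
#' @param ... Further arguments for [callEnhancers()].
#' @return data.frame with columns `multiplier`, `nCalled`,
#'   `nonOverlapRate`. When nothing is called the rate is reported as 0
#'   with a warning.
#' @export
compensationSweep <- function(paired, inputStats, outputStats,
                              annotatedRegions,
                              multipliers = seq(0.1, 3, by = 0.1),
                              alpha = 0.05, ...) {
  if (length(multipliers) == 0L)
    stop("'multipliers' must be non-empty")
  if (!is(annotatedRegions, "GRanges") || length(annotatedRegions) == 0L)
    stop("'annotatedRegions' must be a non-empty GRanges")
  rows <- lapply(multipliers, function(m) {
    res <- callEnhancers(paired, inputStats, outputStats,
                         compensationMultiplier = m, alpha = alpha, ...)
    called <- calledLoci(res)
    if (length(called) == 0L) {
      warning("no loci called at multiplier ", m,
              "; nonOverlapRate reported as 0")
      rate <- 0
    } else {
      rate <- mean(GenomicRanges::countOverlaps(called,
                                                annotatedRegions) == 0L)
    }
    data.frame(multiplier = m, nCalled = length(called),
               nonOverlapRate = rate)
  })
  do.call(rbind, rows)
}

#' Write call records as TSV
#'
#' Columns: `chrom`, `start`, `end` (BED convention), `x`, `y`, `fIn`,
#' `fOut`, `lambda`, `k`, `pvalue`, `qvalue`, `called`, `compensated`.
#'
#' @param calls A [MaeCalls-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeCallsTable <- function(calls, path) {
  writeResultTable(callTable(calls), path)
}
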