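#' Sample fixed-length fragments from a genome
#'
#' Draws `n` substrings of length `fragmentLength` uniformly over all valid
#' (chromosome, offset) start positions on the forward strand. Windows
#' containing N are discarded and redrawn.
#'
#' @param genome A `DNAStringSet` (one element per chromosome).
#' @param fragmentLength Fragment length L in bp.
#' @param n Number of fragments to draw.
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @return A `DNAStringSet` of `n` fragments named `chrom:start` (1-based).
#' @export
#' @importFrom stats runif
sampleFragments <- function(genome, fragmentLength, n, seed = NULL) {
  stopifnot(is(genome, "DNAStringSet"))
  .assertScalarNumber(fragmentLength, "fragmentLength", min = 1)
  .assertScalarNumber(n, "n", min = 1)
  w <- pmax(Biostrings::width(genome) - fragmentLength + 1L, 0L)
  if (sum(w) == 0L)
    stop("no chromosome is long enough for fragments of ", fragmentLength,
         " bp")
  withSeed(seed, {
    draw <- function(m) {
      ci <- sample.int(length(genome), m, replace = TRUE, prob = w)
      off <- floor(stats::runif(m) * w[ci]) + 1L
      list(ci = ci, off = off)
    }
    d <- draw(n)
    frags <- character(n)
    pending <- seq_len(n)
    ci <- d$ci; off <- d$off
    repeat {
      seqs <- vapply(seq_along(pending), function(j) {
        as.character(Biostrings::subseq(genome[[ci[j]]], start = off[j],
                                        width = fragmentLength))
      }, "")
      hasN <- grepl("N", seqs, fixed = TRUE)
      frags[pending[!hasN]] <- seqs[!hasN]
      names(frags)[pending[!hasN]] <- paste0(
        names(genome)[ci[!hasN]], ":", off[!hasN])
      pending <- pending[hasN]
      if (length(pending) == 0L) break
      d <- draw(length(pending))
      ci <- d$ci; off <- d$off
    }
    out <- Biostrings::DNAStringSet(frags)
    names(out) <- names(frags)
    out
  })
}

#' Exact genome-wide occurrence count of fragments
#'
#' Counts exact occurrences of each fragment plus its reverse complement
#' across all chromosomes. A position where a palindromic fragment matches
#' both strands is counted once.
#'
#' @param genome A `DNAStringSet`.
#' @param fragments Character vector or `DNAStringSet` of fragments.
#' @return Integer vector of counts, one per fragment.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AAAA"))
#' occurrenceCount(g, "AA")  # 3
#' @export
#' @importFrom Biostrings PDict vcountPDict vcountPattern reverseComplement
occurrenceCount <- function(genome, fragments) {
  stopifnot(is(genome, "DNAStringSet"))
  frags <- Biostrings::DNAStringSet(fragments)
  if (length(frags) == 0L) return(integer(0))
  if (any(Biostrings::width(frags) == 0L))
    stop("fragments must be non-empty")
  names(frags) <- NULL
  rcs <- Biostrings::reverseComplement(frags)
  isPal <- as.character(frags) == as.character(rcs)
  sameWidth <- length(unique(Biostrings::width(frags))) == 1L
  clean <- !grepl("[^ACGT]", as.character(frags))
  if (sameWidth && all(clean) && length(frags) > 1L) {
    fwd <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(frags), genome))
    rev <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(rcs), genome))
  } else {
    fwd <- vapply(seq_along(frags), function(i)
      sum(Biostrings::vcountPattern(frags[[i]], genome)), integer(1))
    rev <- vapply(seq_along(frags), function(i)
      sum(Biostrings::vcountPattern(rcs[[i]], genome)), integer(1))
  }
  as.integer(fwd + ifelse(isPal, 0L, rev))
}

## Census unique rate for one length: every valid window is examined once.
## A window is uniquely mapping iff its canonical form (lexicographic min of
## the window and its reverse complement) occurs exactly once among all
## canonical windows -- equivalent to occurrenceCount(window) == 1.
.censusUniqueRate <- function(genome, L) {
  wins <- character(0)
  for (i in seq_along(genome)) {
    n <- Biostrings::width(genome)[i] - L + 1L
    if (n < 1L) next
    s <- as.character(genome[[i]])
    wins <- c(wins, substring(s, seq_len(n), seq_len(n) + L - 1L))
  }
  if (length(wins) == 0L)
    stop("no chromosome is long enough for length ", L)
  rcs <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(wins)))
  canon <- pmin(wins, rcs)
  tab <- table(canon)
  mean(tab[canon] == 1L)
}

#' Unique-mapping rate by fragment length
#'
#' For each fragment length, fragments are drawn from the genome and the
#' fraction mapping to exactly one genomic location (forward or reverse
#' complement, by exact occurrence counting) is reported per repetition,
#' together with the mean over repetitions. In census mode every valid
#' window is enumerated exactly once instead of sampling, which is
#' deterministic and seed-independent.
#'
#' @param genome A `DNAStringSet`.
#' @param lengths Integer vector of fragment lengths (e.g. `20:60`).
#' @param nPerRep Fragments drawn per repetition (default 10000).
#' @param reps Repetitions per length (default 3).
#' @param seed Optional integer seed.
#' @param census If TRUE, enumerate all windows (one deterministic "rep").
#' @return List with `rates` (data.frame: `length`, `rep`, `rate`) and
#'   `meanRates` (data.frame: `length`, `meanRate`).
#' @export
uniqueMappingRate <- function(genome, lengths = 20:60, nPerRep = 10000L,
                              reps = 3L, seed = NULL, census = FALSE) {
  stopifnot(is(genome, "DNAStringSet"))
  if (any(lengths < 1L)) stop("all lengths must be >= 1")
  if (census) {
    rates <- data.frame(
      length = lengths, rep = 1L,
      rate = vapply(lengths, function(L) .censusUniqueRate(genome, L),
                    numeric(1)))
  } else {
    .assertScalarNumber(nPerRep, "nPerRep", min = 1)
    .assertScalarNumber(reps, "reps", min = 1)
    rates <- withSeed(seed, {
      do.call(rbind, lapply(lengths, function(L) {
        do.call(rbind, lapply(seq_len(reps), function(r) {
          frags <- sampleFragments(genome, L, nPerRep)
          occ <- occurrenceCount(genome, frags)
          data.frame(length = L, rep = r, rate = mean(occ == 1L))
        }))
      }))
    })
  }
  meanRates <- stats::aggregate(rate ~ length, rates, mean)
  names(meanRates)[2L] <- "meanRate"
  list(rates = rates, meanRates = meanRates)
}
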