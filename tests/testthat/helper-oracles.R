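## Independent oracles and fixture builders, deliberately naive:
## brute-force scans and direct summations, never the package's own path.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## Upper-tail Poisson probability by direct pmf summation in log space.
poisUpperOracle <- function(k, lambda) {
  mapply(function(k, lambda) {
    if (lambda == 0) return(if (k == 0) 1 else 0)
    if (k == 0) return(1)
    j <- k:(k + max(200L, ceiling(10 * lambda + 10 * sqrt(lambda))))
    sum(exp(j * log(lambda) - lambda - lgamma(j + 1)))
  }, k, lambda)
}

## Reference Benjamini-Hochberg step-up, written from the definition.
bhStepUpOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

## O(n*m) interval overlap scan on plain vectors (>= 1 shared bp,
## 1-based closed coordinates).
bruteOverlapFlags <- function(lociDf, regionDf) {
  vapply(seq_len(nrow(lociDf)), function(i) {
    any(regionDf$chrom == lociDf$chrom[i] &
        regionDf$start <= lociDf$end[i] &
        regionDf$end >= lociDf$start[i])
  }, logical(1))
}

grToDf <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr), stringsAsFactors = FALSE)
}

## Brute-force genome-wide exact occurrence count (both strands, positions
## where the fragment or its reverse complement matches; counted once each).
bruteOccurrence <- function(chromStrings, frag) {
  rc <- as.character(reverseComplement(DNAString(frag)))
  L <- nchar(frag)
  total <- 0L
  for (s in chromStrings) {
    n <- nchar(s) - L + 1L
    if (n < 1L) next
    wins <- substring(s, seq_len(n), seq_len(n) + L - 1L)
    total <- total + sum(wins == frag | wins == rc)
  }
  total
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

randomLoci <- function(n, chroms = c("chr1", "chr2"), maxPos = 10000,
                       width = 25) {
  st <- sample.int(maxPos, n, replace = TRUE)
  GRanges(sample(chroms, n, replace = TRUE), IRanges(st, width = width))
}

randomRegions <- function(n, chroms = c("chr1", "chr2"), maxPos = 10000,
                          maxWidth = 500) {
  st <- sample.int(maxPos, n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  GRanges(sample(chroms, n, replace = TRUE), IRanges(st, width = w))
}

## Write a SAM file from a record table. Columns: qname, flag, chrom, pos,
## mapq, cigar, seq (optional), nm (NA = omit tag), xa (logical).
writeTestSam <- function(df, path, chromLens = c(chr1 = 100000,
                                                 chr2 = 100000)) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(chromLens), "\tLN:", chromLens))
  body <- vapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    seq <- if (!is.null(df$seq) && !is.na(r$seq)) r$seq
           else strrep("A", 25)
    fields <- c(r$qname, r$flag,
                if (is.na(r$chrom)) "*" else r$chrom,
                if (is.na(r$pos)) 0 else r$pos,
                if (is.na(r$mapq)) 0 else r$mapq,
                if (is.na(r$cigar)) "*" else r$cigar,
                "*", 0, 0, seq, strrep("I", nchar(seq)))
    if (!is.null(df$nm) && !is.na(r$nm))
      fields <- c(fields, paste0("NM:i:", r$nm))
    if (!is.null(df$xa) && isTRUE(r$xa))
      fields <- c(fields, "XA:Z:chr2,+500,25M,1;")
    paste(fields, collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}

## Minimal alignment DataFrame in readSamFile's schema, for filter tests
## that don't need file I/O.
alnRecord <- function(flag = 0L, chrom = "chr1", pos = 101L, mapq = 60L,
                      cigar = "25M", nm = 0L, hasAltHits = FALSE) {
  S4Vectors::DataFrame(qname = "r", flag = flag, chrom = chrom, pos = pos,
                       mapq = mapq, cigar = cigar, nm = nm,
                       hasAltHits = hasAltHits,
                       refSpan = maecall:::cigarReferenceSpan(cigar))
}
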