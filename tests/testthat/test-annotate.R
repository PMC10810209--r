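test_that("peak extension clamps, merges, and is identity at pad 0", {
  pk <- GRanges("chr1", IRanges(101, 125))          # BED [100,125)
  ext <- extendPeaks(pk, 2500)
  expect_equal(GenomicRanges::start(ext), 1L)       # clamped at the origin
  expect_equal(GenomicRanges::end(ext), 2625L)
  expect_equal(extendPeaks(pk, 0), pk)
  # two peaks 4000 bp apart merge under +/-2500
  two <- GRanges("chr1", IRanges(c(10001, 14101), width = 100))
  expect_equal(length(extendPeaks(two, 2500)), 1L)
  expect_equal(length(extendPeaks(two, 1000)), 2L)
})

test_that("extension agrees with a brute-force pad-and-merge oracle", {
  set.seed(13)
  for (i in 1:5) {
    pk <- randomRegions(40)
    pad <- sample(c(100, 2500), 1)
    got <- extendPeaks(pk, pad)
    df <- grToDf(pk)
    df$start <- pmax(1, df$start - pad)
    df$end <- df$end + pad
    df <- df[order(df$chrom, df$start), ]
    merged <- list()
    for (j in seq_len(nrow(df))) {
      last <- if (length(merged)) merged[[length(merged)]] else NULL
      if (!is.null(last) && last$chrom == df$chrom[j] &&
          df$start[j] <= last$end + 1) {
        merged[[length(merged)]]$end <- max(last$end, df$end[j])
      } else {
        merged[[length(merged) + 1L]] <- df[j, ]
      }
    }
    oracle <- do.call(rbind, merged)
    rownames(oracle) <- NULL
    gotDf <- grToDf(got)
    gotDf <- gotDf[order(gotDf$chrom, gotDf$start), ]
    rownames(gotDf) <- NULL
    expect_equal(gotDf, oracle)
  }
})

test_that("any-overlap uses >=1 shared base with half-open adjacency", {
  # BED locus [100,125) and region [124,200) share one base
  locus <- GRanges("chr1", IRanges(101, 125))
  expect_true(overlapAny(locus, GRanges("chr1", IRanges(125, 200)))$lociHit)
  # BED [125,200) is adjacent, not overlapping
  expect_false(overlapAny(locus, GRanges("chr1", IRanges(126, 200)))$lociHit)
})

test_that("overlap flags and fractions match the all-pairs scan", {
  set.seed(17)
  for (i in 1:5) {
    loci <- randomLoci(100)
    regions <- randomRegions(20)
    got <- overlapAny(loci, regions)
    expFlags <- bruteOverlapFlags(grToDf(loci), grToDf(regions))
    expect_equal(got$lociHit, expFlags)
    expect_equal(got$fractionLociHit, mean(expFlags))
    expect_equal(got$fractionRegionsHit,
                 mean(bruteOverlapFlags(grToDf(regions), grToDf(loci))))
  }
})

test_that("padding never decreases overlap fractions", {
  set.seed(19)
  loci <- randomLoci(100)
  regions <- randomRegions(15)
  fr <- vapply(c(0, 100, 1000, 2500), function(pad)
    overlapAny(loci, extendPeaks(regions, pad))$fractionLociHit, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("fraction-overlap thresholds divide by the locus length", {
  locus <- GRanges("chr1", IRanges(101, 125))       # 25 bp
  region <- GRanges("chr1", IRanges(118, 300))      # covers 8 bases
  expect_true(overlapFractionThreshold(locus, region, 0.3))   # 8/25 = 0.32
  expect_false(overlapFractionThreshold(locus, region, 0.9))
  inside <- GRanges("chr1", IRanges(50, 500))
  expect_true(overlapFractionThreshold(locus, inside, 1))
  # union semantics: two disjoint regions covering 5 bp each
  two <- GRanges("chr1", IRanges(c(101, 110), width = 5))
  expect_true(overlapFractionThreshold(locus, two, 0.4))      # 10/25
  expect_false(overlapFractionThreshold(locus, two, 0.41))
  expect_error(overlapFractionThreshold(locus, region, 0), "minFraction")
})

test_that("known/novel partitions loci against padded evidence", {
  loci <- GRanges("chr1", IRanges(c(5001, 12401, 50001), width = 25))
  atlas <- GRanges("chr1", IRanges(4000, 6000))     # covers locus 1
  k4me1 <- GRanges("chr1", IRanges(14901, 15000))   # 2476 bp from locus 2
  res <- classifyKnownNovel(loci, list(atlas = atlas, H3K4me1 = k4me1),
                            pads = c(atlas = 0, H3K4me1 = 2500))
  expect_equal(as.character(res$label), c("known", "known", "novel"))
  expect_equal(unname(res$hits[, "atlas"]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(res$hits[, "H3K4me1"]), c(FALSE, TRUE, FALSE))
  # every locus is exactly one of known/novel
  expect_false(any(is.na(res$label)))
  expect_error(classifyKnownNovel(loci, list()), "non-empty")
})

test_that("accessibility is the unpadded DNase/ATAC union", {
  loci <- GRanges("chr1", IRanges(c(101, 1001, 5001), width = 25))
  dhs <- GRanges("chr1", IRanges(90, 130))
  atac <- GRanges("chr1", IRanges(1010, 1200))
  got <- classifyAccessibility(loci, dhs = dhs, atac = atac)
  expect_equal(as.character(got), c("open", "open", "closed"))
  expect_equal(as.character(classifyAccessibility(loci, atac = atac)),
               c("closed", "open", "closed"))
  expect_error(classifyAccessibility(loci), "at least one")
})

test_that("loop-anchor overlap matches the all-pairs scan", {
  a1 <- GRanges("chr1", IRanges(c(1000, 9000), width = 500))
  a2 <- GRanges("chr1", IRanges(c(5000, 20000), width = 500))
  loci <- GRanges("chr1", IRanges(c(1100, 3000, 20100), width = 25))
  got <- overlapLoopAnchors(loci, list(anchor1 = a1, anchor2 = a2))
  expect_equal(got$anchorHit, c(TRUE, FALSE, TRUE))
  expect_equal(got$nHit, 2L)
  # spans are midpoint distances of the hit loops
  expect_setequal(got$hits$span[got$hits$locus == 3],
                  abs((20000 + 250) - (9000 + 250)))
  set.seed(23)
  loci <- randomLoci(50)
  l1 <- randomRegions(10); l2 <- randomRegions(10)
  got <- overlapLoopAnchors(loci, list(anchor1 = l1, anchor2 = l2))
  expFlag <- bruteOverlapFlags(grToDf(loci), grToDf(l1)) |
    bruteOverlapFlags(grToDf(loci), grToDf(l2))
  expect_equal(got$anchorHit, expFlag)
})

## BED12 fixture: two genes on chr1.
##  txA (+): chr1:2001-4000, 3 exons, CDS 2301-3700
##  txB (-): chr1:8001-9000, 2 exons, CDS 8201-8800
makeGeneModel <- function() {
  bed <- withr::local_tempfile(fileext = ".bed",
                               .local_envir = parent.frame())
  writeLines(c(
    paste("chr1", 2000, 4000, "txA", 0, "+", 2300, 3700, 0, 3,
          "400,300,500,", "0,700,1500,", sep = "\t"),
    paste("chr1", 8000, 9000, "txB", 0, "-", 8200, 8800, 0, 2,
          "300,400,", "0,600,", sep = "\t")), bed)
  geneModelFromBed12(bed)
}

test_that("BED12 gene models expose exons, UTRs, introns and ends", {
  gm <- makeGeneModel()
  expect_equal(length(gm@transcripts), 2L)
  # txA exons: 2001-2400, 2701-3000, 3501-4000 (1-based)
  exA <- gm@exons[gm@exons$transcript == 1L]
  expect_equal(GenomicRanges::start(exA), c(2001L, 2701L, 3501L))
  expect_equal(GenomicRanges::end(exA), c(2400L, 3000L, 4000L))
  # introns fill the gaps
  intA <- gm@introns[seqnames(gm@introns) == "chr1" &
                     start(gm@introns) < 8000]
  expect_equal(GenomicRanges::start(intA), c(2401L, 3001L))
  # 5'UTR of txA: exon bases before CDS start 2301
  expect_equal(grToDf(gm@utr5[1]),
               data.frame(chrom = "chr1", start = 2001L, end = 2300L))
  # 3'UTR of txA: exon bases after CDS end 3700
  expect_equal(grToDf(gm@utr3[1]),
               data.frame(chrom = "chr1", start = 3701L, end = 4000L))
  # on the minus strand the sides swap: txB 5'UTR is the right end
  expect_equal(grToDf(gm@utr5[2]),
               data.frame(chrom = "chr1", start = 8801L, end = 9000L))
  # TSS/TTS are strand-aware points
  expect_equal(GenomicRanges::start(gm@tss), c(2001L, 9000L))
  expect_equal(GenomicRanges::start(gm@tts), c(4000L, 8001L))
})

test_that("feature annotation follows the fixed priority order", {
  gm <- makeGeneModel()
  loci <- GRanges("chr1", IRanges(
    c(4051,   # 50 bp downstream of txA end -> TTS window
      2801,   # internal exon of txA
      2451,   # intron of txA
      2101,   # 5'UTR (also exon) -> 5UTR wins
      3951,   # 3'UTR + exon + TTS window -> TTS wins
      3801,   # 3'UTR (also exon) -> 3UTR wins over exon
      50001), # nothing
    width = 25))
  got <- annotateFeature(loci, gm)
  expect_equal(as.character(got),
               c("TTS", "exon", "intron", "5UTR", "TTS", "3UTR",
                 "intergenic"))
  # the minus-strand TTS window runs 100 bp right / 1 kb left of the TTS
  twin <- ttsWindows(gm)[2]
  expect_equal(GenomicRanges::start(twin), 8001L - 1000L)
  expect_equal(GenomicRanges::end(twin), 8001L + 100L)
  # empty model: everything is intergenic
  empty <- geneModelFromBed12(GenomicRanges::GRanges())
  expect_true(all(annotateFeature(loci, empty) == "intergenic"))
})

test_that("TSS distance is midpoint to nearest TSS, NA off-model", {
  gm <- makeGeneModel()   # TSS at 2001 (+) and 9000 (-)
  atTss <- GRanges("chr1", IRanges(2001 - 12, width = 25))  # midpoint 2001
  expect_equal(distanceToTss(atTss, gm), 0L)
  far <- GRanges("chr1", IRanges(1001 - 12, width = 25))    # midpoint 1001
  expect_equal(distanceToTss(far, gm), 1000L)
  # nearest of the two TSS wins
  mid <- GRanges("chr1", IRanges(8000 - 12, width = 25))    # midpoint 8000
  expect_equal(distanceToTss(mid, gm), min(8000 - 2001, 9000 - 8000))
  offChrom <- GRanges("chrX", IRanges(101, width = 25))
  expect_true(is.na(distanceToTss(offChrom, gm)))
})
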