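test_that("retention filters implement the uniquely-mapped 25-bp rule", {
  expect_true(alignmentPassesFilters(alnRecord(nm = 2L)))    # boundary
  expect_false(alignmentPassesFilters(alnRecord(nm = 3L)))   # one past it
  expect_false(alignmentPassesFilters(alnRecord(cigar = "24M1S")))
  expect_false(alignmentPassesFilters(alnRecord(flag = 4L, chrom = NA,
                                                pos = NA, mapq = NA,
                                                cigar = NA, nm = NA)))
  expect_false(alignmentPassesFilters(alnRecord(flag = 0x100L)))
  expect_false(alignmentPassesFilters(alnRecord(flag = 0x800L)))
  expect_false(alignmentPassesFilters(alnRecord(hasAltHits = TRUE)))
  expect_false(alignmentPassesFilters(alnRecord(mapq = 0L)))
  expect_true(alignmentPassesFilters(alnRecord(mapq = 0L), minMapq = 0L))
  # missing NM fails unless assumed perfect
  expect_false(alignmentPassesFilters(alnRecord(nm = NA)))
  expect_true(alignmentPassesFilters(alnRecord(nm = NA), assumeNm0 = TRUE))
})

test_that("PCR duplicates are retained and counted per locus", {
  aln <- do.call(rbind, rep(list(alnRecord()), 3))
  ct <- countLoci(aln)
  expect_equal(length(lociCounts(ct)), 1L)
  expect_equal(lociCounts(ct)$count, 3L)
  expect_equal(totalRetained(ct), 3)
  expect_equal(totalRecordsSeen(ct), 3)
})

test_that("counting conserves retained records on random streams", {
  set.seed(42)
  for (i in 1:5) {
    n <- 200L
    aln <- S4Vectors::DataFrame(
      qname = paste0("r", seq_len(n)),
      flag = sample(c(0L, 4L, 16L, 0x100L), n, replace = TRUE),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      pos = sample.int(5000L, n, replace = TRUE),
      mapq = sample(c(0L, 30L, 60L), n, replace = TRUE),
      cigar = sample(c("25M", "24M1S", "20M5S"), n, replace = TRUE),
      nm = sample(c(0L, 1L, 2L, 3L, NA), n, replace = TRUE),
      hasAltHits = sample(c(TRUE, FALSE), n, replace = TRUE))
    unmapped <- bitwAnd(aln$flag, 4L) == 4L
    aln$chrom[unmapped] <- NA
    aln$pos[unmapped] <- NA
    aln$refSpan <- maecall:::cigarReferenceSpan(aln$cigar)
    nPass <- sum(alignmentPassesFilters(aln))
    ct <- countLoci(aln)
    expect_equal(sum(lociCounts(ct)$count), nPass)
    expect_equal(totalRetained(ct), nPass)
    expect_equal(totalRecordsSeen(ct), n)
  }
})

test_that("strand is collapsed in the locus key", {
  fwd <- alnRecord(flag = 0L, pos = 101L)
  rev <- alnRecord(flag = 16L, pos = 101L)
  ct <- countLoci(rbind(fwd, rev))
  expect_equal(length(lociCounts(ct)), 1L)
  expect_equal(lociCounts(ct)$count, 2L)
})

test_that("counting from fragment coordinates enforces the locus width", {
  gr <- GRanges("chr1", IRanges(c(101, 101, 500), width = 25))
  ct <- countLoci(gr)
  expect_equal(sort(lociCounts(ct)$count), c(1L, 2L))
  bad <- GRanges("chr1", IRanges(1, width = 24))
  expect_error(countLoci(bad), "width 25")
})

test_that("records off the genome manifest warn but are counted", {
  aln <- rbind(alnRecord(chrom = "chr1"), alnRecord(chrom = "chrX"))
  expect_warning(ct <- countLoci(aln, knownChroms = "chr1"), "chrX")
  expect_equal(totalRetained(ct), 2)
})

test_that("pairing takes the union of loci with zeros for missing sides", {
  A <- GRanges("chr1", IRanges(101, width = 25))
  B <- GRanges("chr1", IRanges(201, width = 25))
  mk <- function(gr, counts) {
    gr$count <- counts
    LocusCounts(gr, 25L)
  }
  input <- mk(A, 2L)
  output <- mk(c(A, B), c(8L, 5L))
  se <- pairCounts(input, output)
  cnt <- SummarizedExperiment::assay(se, "counts")
  expect_equal(nrow(cnt), 2L)
  expect_equal(unname(cnt[, "input"]), c(2L, 0L))
  expect_equal(unname(cnt[, "output"]), c(8L, 5L))

  # disjoint tables: every row has one zero side
  se2 <- pairCounts(mk(A, 3L), mk(B, 4L))
  cnt2 <- SummarizedExperiment::assay(se2, "counts")
  expect_true(all(rowSums(cnt2 == 0L) == 1L))

  # identical tables: y == x for every row
  se3 <- pairCounts(mk(c(A, B), c(1L, 7L)), mk(c(A, B), c(1L, 7L)))
  cnt3 <- SummarizedExperiment::assay(se3, "counts")
  expect_equal(unname(cnt3[, "input"]), unname(cnt3[, "output"]))
})

test_that("pairing is symmetric up to the column swap", {
  set.seed(7)
  mk <- function() {
    gr <- unique(randomLoci(50, maxPos = 2000))
    gr$count <- sample.int(10L, length(gr), replace = TRUE)
    LocusCounts(gr, 25L)
  }
  a <- mk(); b <- mk()
  ab <- SummarizedExperiment::assay(pairCounts(a, b), "counts")
  ba <- SummarizedExperiment::assay(pairCounts(b, a), "counts")
  expect_equal(unname(ab[, "input"]), unname(ba[, "output"]))
  expect_equal(unname(ab[, "output"]), unname(ba[, "input"]))
})

test_that("pairing rejects mismatched insert lengths", {
  g24 <- GRanges("chr1", IRanges(1, width = 24)); g24$count <- 1L
  g25 <- GRanges("chr1", IRanges(1, width = 25)); g25$count <- 1L
  expect_error(pairCounts(LocusCounts(g24, 24L), LocusCounts(g25, 25L)),
               "insert length mismatch")
})

test_that("counts tables round-trip through TSV", {
  gr <- GRanges(c("chr1", "chr2"), IRanges(c(101, 51), width = 25))
  gr$count <- c(4L, 9L)
  ct <- LocusCounts(gr, 25L)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeCountsTable(ct, tmp)
  back <- readCountsTable(tmp)
  expect_equal(grToDf(lociCounts(back)), grToDf(lociCounts(ct)))
  expect_equal(lociCounts(back)$count, lociCounts(ct)$count)
})
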