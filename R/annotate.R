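#' Extend peaks symmetrically and merge
#'
#' Each peak grows by `pad` bp on both sides (clamped at position 1) and
#' overlapping padded peaks are merged. Used to compare narrow loci against
#' nucleosome-level marks: histone modifications flank rather than cover the
#' element itself, so peaks are conventionally extended by 2500 bp. With
#' `pad = 0` the input is returned unchanged (no merging).
#'
#' @param peaks A `GRanges`.
#' @param pad Non-negative padding in bp (default 2500).
#' @return A `GRanges` (merged when `pad > 0`).
#' @export
extendPeaks <- function(peaks, pad = 2500L) {
  .assertScalarNumber(pad, "pad", min = 0)
  if (pad == 0) return(peaks)
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(peaks) - as.integer(pad)),
                     GenomicRanges::end(peaks) + as.integer(pad)))
  GenomicRanges::reduce(out, ignore.strand = TRUE)
}

#' Any-overlap flags and summary fractions
#'
#' A locus is flagged iff it shares at least one base with any region
#' (half-open adjacency does not count). Both directions are summarized:
#' the fraction of loci hitting at least one region, and the fraction of
#' regions hit by at least one locus.
#'
#' @param loci,regions `GRanges`.
#' @return List with `lociHit` (logical per locus), `fractionLociHit`,
#'   `fractionRegionsHit` (0 when the respective set is empty).
#' @export
overlapAny <- function(loci, regions) {
  lociHit <- GenomicRanges::countOverlaps(loci, regions,
                                          ignore.strand = TRUE) > 0L
  regionsHit <- GenomicRanges::countOverlaps(regions, loci,
                                             ignore.strand = TRUE) > 0L
  list(lociHit = lociHit,
       fractionLociHit = if (length(loci)) mean(lociHit) else 0,
       fractionRegionsHit = if (length(regions)) mean(regionsHit) else 0)
}

#' Fraction-overlap threshold flags
#'
#' A locus is flagged iff the number of its bases covered by the union of
#' the regions, divided by the locus length, reaches `minFraction`.
#'
#' @param loci,regions `GRanges`.
#' @param minFraction Required covered fraction, in (0, 1].
#' @return Logical vector per locus.
#' @examples
#' loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 125))
#' regs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(118, 300))
#' overlapFractionThreshold(loci, regs, 0.3)  # 8/25 >= 0.3
#' @export
overlapFractionThreshold <- function(loci, regions, minFraction) {
  .assertScalarNumber(minFraction, "minFraction",
                      min = .Machine$double.xmin, max = 1)
  red <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(loci, red, ignore.strand = TRUE)
  covered <- numeric(length(loci))
  if (length(ov)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      granges(loci)[S4Vectors::queryHits(ov)],
      red[S4Vectors::subjectHits(ov)], ignore.strand = TRUE))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(agg))] <- agg
  }
  covered / GenomicRanges::width(loci) >= minFraction
}

#' Classify loci as known or novel
#'
#' A locus is "known" iff it overlaps at least one evidence set after
#' per-set padding (default ±2500 bp, the histone-mark convention); loci
#' overlapping none of the padded sets are "novel". Typical evidence sets:
#' curated enhancer atlases, DNase/ATAC peaks, H3K4me1/H3K27ac peaks.
#'
#' @param loci `GRanges` of called loci.
#' @param peakSets Named list of `GRanges` evidence sets (non-empty list).
#' @param pads Padding per set: a single number recycled, or a named/
#'   positional vector matching `peakSets` (default 2500).
#' @return List with `label` (factor `known`/`novel` per locus) and `hits`
#'   (logical matrix locus x set).
#' @export
classifyKnownNovel <- function(loci, peakSets, pads = 2500L) {
  if (!is.list(peakSets) || length(peakSets) == 0L)
    stop("'peakSets' must be a non-empty list of GRanges")
  if (length(pads) == 1L) pads <- rep(pads, length(peakSets))
  if (!is.null(names(pads)) && !is.null(names(peakSets)))
    pads <- pads[names(peakSets)]
  if (length(pads) != length(peakSets))
    stop("'pads' must match 'peakSets' in length")
  hits <- vapply(seq_along(peakSets), function(i) {
    GenomicRanges::countOverlaps(
      loci, extendPeaks(peakSets[[i]], pads[[i]]),
      ignore.strand = TRUE) > 0L
  }, logical(length(loci)))
  hits <- matrix(hits, nrow = length(loci),
                 dimnames = list(NULL, names(peakSets)))
  label <- factor(ifelse(rowSums(hits) > 0L, "known", "novel"),
                  levels = c("known", "novel"))
  list(label = label, hits = hits)
}

#' Classify loci by chromatin accessibility
#'
#' Open iff the locus overlaps an (unpadded) DNase or ATAC peak; closed
#' otherwise. At least one accessibility set must be supplied.
#'
#' @param loci `GRanges`.
#' @param dhs,atac `GRanges` of DNase / ATAC peaks (either may be NULL).
#' @return Factor `open`/`closed` per locus.
#' @export
classifyAccessibility <- function(loci, dhs = NULL, atac = NULL) {
  sets <- Filter(Negate(is.null), list(dhs, atac))
  if (length(sets) == 0L)
    stop("supply at least one of 'dhs' or 'atac'")
  acc <- do.call(c, lapply(sets, granges))
  open <- GenomicRanges::countOverlaps(loci, acc, ignore.strand = TRUE) > 0L
  factor(ifelse(open, "open", "closed"), levels = c("open", "closed"))
}

#' Flag loci overlapping chromatin-loop anchors
#'
#' A locus is flagged iff it overlaps either anchor of any loop. For each
#' (locus, loop) hit the loop span (distance between anchor midpoints) is
#' reported.
#'
#' @param loci `GRanges`.
#' @param loops A [S4Vectors::Pairs] of anchor `GRanges` (from
#'   [readBedpeFile()]) or a list with elements `anchor1`, `anchor2`.
#' @return List with `anchorHit` (logical per locus), `nHit`, and `hits`
#'   (data.frame: locus index, loop index, loop span in bp).
#' @export
#' @importFrom S4Vectors first second queryHits subjectHits
overlapLoopAnchors <- function(loci, loops) {
  if (is(loops, "Pairs")) {
    a1 <- S4Vectors::first(loops)
    a2 <- S4Vectors::second(loops)
  } else {
    a1 <- loops$anchor1
    a2 <- loops$anchor2
  }
  ov1 <- GenomicRanges::findOverlaps(loci, a1, ignore.strand = TRUE)
  ov2 <- GenomicRanges::findOverlaps(loci, a2, ignore.strand = TRUE)
  mid <- function(gr)
    GenomicRanges::start(gr) + GenomicRanges::width(gr) %/% 2L
  span <- abs(mid(a2) - mid(a1))
  hits <- unique(rbind(
    data.frame(locus = S4Vectors::queryHits(ov1),
               loop = S4Vectors::subjectHits(ov1)),
    data.frame(locus = S4Vectors::queryHits(ov2),
               loop = S4Vectors::subjectHits(ov2))))
  hits$span <- span[hits$loop]
  anchorHit <- logical(length(loci))
  anchorHit[hits$locus] <- TRUE
  list(anchorHit = anchorHit, nHit = sum(anchorHit), hits = hits)
}
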