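#' Gene model for feature annotation
#'
#' Transcript structures flattened into the feature tracks the annotator
#' needs: exons, introns, 5'/3' UTRs, TSS and TTS point positions. Built
#' from BED12 with [geneModelFromBed12()] (UTRs derived from the thick/CDS
#' coordinates; transcripts without a CDS contribute no UTRs).
#'
#' @slot transcripts `GRanges`, one per transcript, stranded.
#' @slot exons,utr5,utr3,introns `GRanges` feature tracks.
#' @slot tss,tts `GRanges` of width-1 point positions (strand-aware:
#'   TSS is the transcript 5' end, TTS the 3' end).
#' @export
setClass("GeneModel",
  representation(
    transcripts = "GRanges",
    exons = "GRanges",
    utr5 = "GRanges",
    utr3 = "GRanges",
    introns = "GRanges",
    tss = "GRanges",
    tts = "GRanges"
  )
)

setMethod("show", "GeneModel", function(object) {
  cat(sprintf(
    "GeneModel: %d transcripts; %d exons, %d introns, %d 5'UTR, %d 3'UTR\n",
    length(object@transcripts), length(object@exons),
    length(object@introns), length(object@utr5), length(object@utr3)))
})

#' Build a GeneModel from BED12
#'
#' @param x Path to a BED12 file, or a `GRanges` as returned by
#'   `rtracklayer::import` on one (with `blocks` and `thick` columns).
#' @return A [GeneModel-class].
#' @export
geneModelFromBed12 <- function(x) {
  tx <- if (is.character(x)) rtracklayer::import(x, format = "bed") else x
  if (length(tx) == 0L) {
    e <- GenomicRanges::GRanges()
    return(new("GeneModel", transcripts = e, exons = e, utr5 = e, utr3 = e,
               introns = e, tss = e, tts = e))
  }
  if (is.null(tx$blocks))
    stop("gene models require BED12 input (block columns missing)")
  strand <- as.character(GenomicRanges::strand(tx))
  if (any(strand == "*"))
    stop("gene-model transcripts must be stranded")

  exonsList <- lapply(seq_along(tx), function(i) {
    # blocks are 1-based relative to the transcript start
    abs <- IRanges::shift(tx$blocks[[i]], GenomicRanges::start(tx)[i] - 1L)
    GenomicRanges::GRanges(GenomicRanges::seqnames(tx)[i], abs,
                           strand = strand[i])
  })
  exons <- do.call(c, exonsList)
  exons$transcript <- rep(seq_along(tx), lengths(tx$blocks))

  intronsList <- lapply(seq_along(tx), function(i) {
    GenomicRanges::setdiff(granges(tx[i]), granges(exonsList[[i]]))
  })
  introns <- do.call(c, intronsList)

  # UTRs: exon parts outside the thick (CDS) span, sided by strand
  utr5 <- GenomicRanges::GRanges()
  utr3 <- GenomicRanges::GRanges()
  thick <- tx$thick
  for (i in seq_along(tx)) {
    if (is.null(thick) || IRanges::width(thick)[i] <= 0L) next
    ts <- IRanges::start(thick)[i]
    te <- IRanges::end(thick)[i]
    ex <- granges(exonsList[[i]])
    chr <- GenomicRanges::seqnames(tx)[i]
    left <- GenomicRanges::intersect(ex, GenomicRanges::GRanges(
      chr, IRanges::IRanges(GenomicRanges::start(tx)[i],
                            max(ts - 1L, GenomicRanges::start(tx)[i] - 1L)),
      strand = strand[i]))
    right <- GenomicRanges::intersect(ex, GenomicRanges::GRanges(
      chr, IRanges::IRanges(min(te + 1L, GenomicRanges::end(tx)[i] + 1L),
                            GenomicRanges::end(tx)[i]),
      strand = strand[i]))
    if (strand[i] == "+") {
      utr5 <- c(utr5, left); utr3 <- c(utr3, right)
    } else {
      utr5 <- c(utr5, right); utr3 <- c(utr3, left)
    }
  }

  point <- function(pos) GenomicRanges::GRanges(
    GenomicRanges::seqnames(tx), IRanges::IRanges(pos, width = 1L),
    strand = strand)
  tssPos <- ifelse(strand == "+", GenomicRanges::start(tx),
                   GenomicRanges::end(tx))
  ttsPos <- ifelse(strand == "+", GenomicRanges::end(tx),
                   GenomicRanges::start(tx))
  new("GeneModel", transcripts = tx, exons = exons, utr5 = utr5,
      utr3 = utr3, introns = introns, tss = point(tssPos),
      tts = point(ttsPos))
}

#' Strand-aware TTS windows
#'
#' The window around each transcription termination site, by default from
#' 100 bp upstream to 1 kb downstream of the TTS (in the transcript's
#' direction).
#'
#' @param model A [GeneModel-class].
#' @param upstream,downstream Window extent in bp (defaults 100 / 1000).
#' @return A `GRanges` of windows.
#' @export
ttsWindows <- function(model, upstream = 100L, downstream = 1000L) {
  tts <- model@tts
  if (length(tts) == 0L) return(GenomicRanges::GRanges())
  plus <- as.character(GenomicRanges::strand(tts)) == "+"
  pos <- GenomicRanges::start(tts)
  s <- ifelse(plus, pos - upstream, pos - downstream)
  e <- ifelse(plus, pos + downstream, pos + upstream)
  GenomicRanges::GRanges(GenomicRanges::seqnames(tts),
                         IRanges::IRanges(pmax(1, s), e))
}

#' Annotate loci by genomic feature
#'
#' Assigns each locus to exactly one category by overlap, resolving
#' multi-category hits with the fixed priority
#' `TTS > 5UTR > 3UTR > exon > intron > intergenic`. The TTS category is the
#' strand-aware window −100 bp to +1 kb around each transcription
#' termination site. With an empty model every locus is `intergenic`.
#'
#' @param loci `GRanges`.
#' @param model A [GeneModel-class].
#' @param ttsUpstream,ttsDownstream TTS window extent (defaults 100 / 1000).
#' @return Factor per locus with levels
#'   `TTS`, `5UTR`, `3UTR`, `exon`, `intron`, `intergenic`.
#' @export
annotateFeature <- function(loci, model, ttsUpstream = 100L,
                            ttsDownstream = 1000L) {
  stopifnot(is(model, "GeneModel"))
  lv <- c("TTS", "5UTR", "3UTR", "exon", "intron", "intergenic")
  cat <- rep("intergenic", length(loci))
  tracks <- list(
    TTS = ttsWindows(model, ttsUpstream, ttsDownstream),
    `5UTR` = model@utr5,
    `3UTR` = model@utr3,
    exon = model@exons,
    intron = model@introns)
  undecided <- rep(TRUE, length(loci))
  for (nm in names(tracks)) {
    trk <- tracks[[nm]]
    if (length(trk) == 0L) next
    hit <- GenomicRanges::countOverlaps(loci, trk, ignore.strand = TRUE) > 0L
    assign_ <- undecided & hit
    cat[assign_] <- nm
    undecided <- undecided & !hit
  }
  factor(cat, levels = lv)
}

#' Distance from locus midpoint to the nearest TSS
#'
#' The locus anchor is its midpoint (`start + floor(length/2)` in 0-based
#' coordinates). Distance is the absolute bp separation to the nearest
#' transcript TSS on the same chromosome; loci on chromosomes with no
#' transcript get `NA`.
#'
#' @param loci `GRanges`.
#' @param model A [GeneModel-class].
#' @return Non-negative integer vector (NA where unannotated).
#' @export
distanceToTss <- function(loci, model) {
  stopifnot(is(model, "GeneModel"))
  mid <- GenomicRanges::start(loci) + GenomicRanges::width(loci) %/% 2L
  chr <- as.character(GenomicRanges::seqnames(loci))
  tssChr <- as.character(GenomicRanges::seqnames(model@tss))
  tssPos <- GenomicRanges::start(model@tss)
  byChrom <- split(tssPos, tssChr)
  vapply(seq_along(loci), function(i) {
    pos <- byChrom[[chr[i]]]
    if (is.null(pos)) return(NA_integer_)
    as.integer(min(abs(pos - mid[i])))
  }, integer(1))
}
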