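---
title: "Calling active enhancers from 25-bp fragment reporter screens"
author: "maecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling active enhancers from 25-bp fragment reporter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maecall)
```

## The assay and the statistical problem

A pool of random 25-bp genomic fragments is cloned upstream of a minimal
promoter driving a fluorescent reporter and transfected into cells. Cells in
which the fragment activates transcription fluoresce; sorting those cells and
sequencing their fragments yields the **output** library. A second aliquot of
the same transfected population is sequenced without sorting — the **input**
library — and serves as the control distribution of fragment abundances.
A fragment with enhancer activity is *enriched* in the output relative to the
input; the computational task is to decide, per 25-bp genomic locus, whether
that enrichment is larger than sampling noise.

Two properties of the data shape the model:

* **PCR duplicates cannot be removed.** Fragments are exactly 25 bp, so two
  reads from independent molecules and two reads from one amplified molecule
  are indistinguishable. Counts are therefore kept as-is and amplification is
  absorbed into the normalization instead.
* **Counts are locus-level rare events.** The chance that a random fragment
  covers one particular genomic position is minute while the number of
  sequenced fragments is huge, so per-locus counts are modeled as Poisson.

## Normalization

Raw counts are put on a common scale with a linear function

$$ f(x) = \frac{x}{N \cdot c \cdot \log(1+p)}\,\omega $$

where \(x\) is the raw count at a locus, \(N\) the library's total read
count, \(p\) the per-cycle PCR efficiency (default 1, i.e. every molecule
duplicates every cycle), \(c\) the number of PCR cycles, and \(\omega\) a
*zoom factor* shared by both libraries. The denominator is library size times
the log of the expected amplification factor \((1+p)^c\); we read the
denominator as \(N \cdot c \cdot \log(1+p)\) because the alternative reading
\((\log(1+p))^c\) vanishes for realistic cycle numbers (e.g.
\(\ln(2)^{15} \approx 4\times10^{-3}\,^{\!5}\)) and would make normalized
values astronomically large. The natural logarithm is the default; base 10 is
selectable (`logBase = "base10"`) since the base only rescales both libraries
by the same constant and cancels from relative comparisons (it does change
the absolute Poisson scale, hence the option).

Without \(\omega\), \(x/(N c \log(1+p))\) is a tiny frequency and a Poisson
test at such means has essentially no power. The zoom factor restores a count
scale. With \(d = \lfloor \log_{10}(\min(N_\mathrm{in},
N_\mathrm{out}))\rfloor + 1\) (the digit count of the smaller library),

* `omegaMode = "power"` (default): \(\omega = 10^{d}\), the next power of
  ten above the smaller total — this makes \(f(x)\) of order \(x/(c
  \log(1+p))\), a genuine count scale;
* `omegaMode = "literal"`: \(\omega = 10\,d\), the formula read literally as
  ten times the digit count. Retained for fidelity, but at realistic depths
  it leaves normalized values of order \(10^{-5}\), where the Poisson test
  is inert; power mode is the only reading consistent with the factor's
  stated purpose.

Both modes coincide for totals below 10 and are symmetric in the two totals.

## The enrichment test

For each locus with input count \(x\) and output count \(y\):

* expectation \(\lambda = f_\mathrm{in}(x)\) when \(x > 0\);
* observation \(k = \mathrm{round}(f_\mathrm{out}(y))\), rounded half away
  from zero, because the Poisson tail needs an integer argument
  (`kMode = "rounded"`). A continuous reading via the regularized gamma
  survival function \(P(K \ge f_\mathrm{out}(y))\) is available
  (`kMode = "continuous"`) for sensitivity analysis; it avoids the rounding
  discontinuity at the cost of a non-standard test;
* p-value \(P(K \ge k \mid \lambda)\), the **upper tail** — the test is
  one-sided for enrichment in the output, which is the only direction that
  defines a positive (active-enhancer) signal. It is computed with the
  stable survival function, never by subtracting a cumulative sum from 1.

Loci with \(y = 0\) are not tested: absence from the output is never
evidence of activity. Loci with \(x = 0\) but \(y > 0\) would get
\(\lambda = 0\) and a p-value of exactly 0 regardless of \(y\) — a trivially
wrong call. These loci instead receive a **compensation value**
\(\kappa = m \cdot \mathrm{coef_{in}}\), i.e. \(m\) times the normalized
value of a single input read (default \(m = 1\)). Larger \(m\) makes the
test more rigorous for input-absent loci, smaller \(m\) more permissive.
`compensationSweep()` re-runs the caller over a grid of multipliers (default
0.1–3 in steps of 0.1) and reports, per multiplier, the number of calls and
the fraction of called loci overlapping none of a set of annotated regions —
the two diagnostics that justify the default of one normalization
coefficient, which balances retained signal against the non-overlap rate.

Benjamini–Hochberg adjustment is applied across all tested loci and a locus
is called at \(Q < 0.05\) (configurable `alpha`).

### Worked example

With \(N = 1000\) in both libraries, \(p = 1\), \(c = 15\):
\(\omega = 10^4\) and \(\mathrm{coef} = 10^4/(1000 \cdot 15 \cdot \ln 2)
\approx 0.96180\).

```{r worked}
stats <- LibraryStats(1000, 1, 15)
paired <- data.frame(chrom = "chr1", start = c(100, 200), end = c(125, 225),
                     x = c(2, 0), y = c(8, 8))
callTable(callEnhancers(paired, stats, stats))
```

The locus with \(x=2, y=8\) is tested at \(\lambda \approx 1.9236\) with
\(k = 8\) (p ≈ 8.6e-4); the input-absent locus is tested against
\(\kappa \approx 0.9618\) (p ≈ 7.8e-6) and flagged `compensated`.

## Counting and filters

Upstream of the test, reads are reduced to per-locus counts:

* the 25-bp insert is cut out of each read by locating a 20-base anchor
  (suffix of the left construct arm, prefix of the right arm) at up to one
  Hamming mismatch, with the insert length enforced exactly — the assay's
  published analysis used an adapter trimmer without stating parameters, so
  a deterministic, testable anchor match is used here;
* after external alignment, a record is retained iff it is a primary,
  mapped alignment with no alternate-hit (XA) tag and mapping quality ≥ 1
  (the operational definition of "uniquely mapped"; the threshold is
  configurable since aligners encode uniqueness differently), spans exactly
  25 reference bases, and has at most 2 mismatches (NM tag);
* the locus key is (chromosome, start, end) with strand collapsed, since
  enhancer activity is orientation-independent;
* identical records all count: duplicates are signal here, not artifact.

Coordinates are handled as `GRanges` (1-based, closed) internally; BED's
0-based half-open and SAM's 1-based conventions are converted at parse time,
and written back out in BED convention. Chromosome names are compared as
exact strings — no "chr" aliasing — because silent aliasing corrupts overlap
counts.

## Annotation of called loci

All downstream classifications are interval-overlap operations with a
shared-base predicate (adjacent half-open intervals do not overlap):

* **Chromatin marks**: peaks extended by ±2500 bp before overlap, because
  histone modifications sit on nucleosomes flanking the element rather than
  on it.
* **Known vs novel**: known iff the locus overlaps any of the padded
  evidence sets (enhancer atlas, DNase, ATAC, H3K4me1, H3K27ac); pads are
  per-dataset.
* **Open vs closed chromatin**: overlap with *unpadded* DNase/ATAC peaks —
  accessibility is positional, so no pad.
* **Genomic features**: TTS window (strand-aware −100 bp to +1 kb around
  the transcription termination site), 5′UTR, 3′UTR, exon, intron,
  intergenic, assigned by first hit in that priority order. The priority
  resolves multi-category hits deterministically; the upstream annotator the
  assay's analysis used does not document its tie-break, so one had to be
  fixed here. No promoter class is invented: the six listed categories are
  implemented exactly.
* **TSS distance**: from the locus midpoint (the anchor point is not
  specified by the assay's analysis; the midpoint is the symmetric choice
  for a 25-bp locus).
* **Loop anchors**: overlap with either anchor of BEDPE interactions, with
  the anchor-midpoint span reported.
* **Fraction thresholds**: motif-style comparisons use covered-bases /
  locus-length against the union of regions (e.g. 30% or 90%).

## Fragment-length mappability simulation

To justify a fragment length, `uniqueMappingRate()` draws fragments of each
length (20–60 bp by default) uniformly from a genome and reports the
fraction mapping to exactly one location. Uniqueness is decided by exact
occurrence counting on both strands (a palindromic fragment matching both
strands at one position counts once) rather than by wrapping an external
aligner: exact counting is deterministic, dependency-free, and admits an
exhaustive *census* mode (`census = TRUE`) that enumerates every window and
is the oracle the sampling mode is tested against. Fragments containing N
are redrawn, a choice the assay's description leaves open. An external
aligner can still be used upstream by counting mapq-unique SAM records.

## The synthetic screen generator

`simulateScreen()` generates the ground-truth datasets the test suite and
acceptance checks run on. It emulates:

1. a pool of M distinct 25-bp fragments drawn from a simulated genome
   (i.i.d. bases, optionally with a planted tandem-repeat family occupying a
   chosen fraction of each chromosome);
2. branching-process PCR: every molecule duplicates independently with
   probability \(p\) per cycle, so the expected amplification is exactly the
   \((1+p)^c\) the normalization assumes — this alignment between generator
   and model is deliberate, and the generator's moments are tested against
   it;
3. sorting enrichment: output reads are a multinomial draw over post-PCR
   molecule counts weighted by each fragment's enrichment fold (1 for
   neutral fragments), input reads an unweighted draw at the input depth.

Default conditions: M = 5000 fragments, 50 planted enhancers at fold 20,
5×10^5 reads per library, \(p = 1\), 15 cycles in both libraries. Fifteen
cycles matches the library-construction protocols the assay describes (the
output protocol spans 5–15 cycles); equal cycles on both sides is the
package's own choice, because with \(p = 1\) and depth-fixed multinomial
sampling, cycle number does not change count distributions, and asymmetric
cycle normalization would then inject a systematic input/output bias that
the generative process does not contain.

The generator does **not** model sequencing errors (a uniform substitution
flag could be added; errors mostly fail the exact-length unique-match
filters and are orthogonal to the statistics under test), transfection copy
number, sorting gate impurity, or episomal replication. Passing recovery
tests on these simulations therefore demonstrates correctness of the
*pipeline and model under the model's own assumptions* — not robustness to
every artifact of real screens.

`screenReads()` and `writeScreenSam()` materialize a screen as
construct-flanked FASTQ reads and perfect SAM alignments, so the entire
prep → count → call path can be exercised on files; the suite verifies that
this path reproduces the generator's internal count tables exactly.

## Numerical and degenerate-input choices

* Poisson tails via `ppois(k - 1, lambda, lower.tail = FALSE)`; the suite
  checks agreement with direct pmf summation to 1e-10 for \(\lambda \le 50\),
  \(k \le 200\).
* Rounding of \(f_\mathrm{out}(y)\) is half away from zero (not banker's
  rounding) so that the observation is monotone in \(y\) without parity
  artifacts.
* \(k = 0\) gives p-value 1; \(\lambda = 0\) cannot reach the test (it
  implies \(x = 0\), which routes to the compensation value).
* Zero-length BED intervals are parse errors, not silently empty ranges.
* An empty called set in a sweep reports a non-overlap rate of 0 with a
  warning rather than NaN.
* Ties in `annotateFeature` are impossible by construction (strict priority
  scan); loci on chromosomes absent from the gene model get `NA` TSS
  distance.

## Problem sizes in the checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen so the
whole suite completes in about a minute: genomes of 2–5×10^4 bp, screens of
300–5000 fragments, depths up to 5×10^5 reads, 5–10 seeds per stochastic
criterion. The null-screen criterion (called fraction ≤ 0.1% at fold 1) and
the recovery criterion (recall ≥ 0.9, empirical FDR ≤ 0.05 at fold 20) are
evaluated at the generator's default conditions given above.

## Known limitations

* Single input/output pair: no replicate-aware model, no dispersion
  estimation (a negative-binomial extension would relax the Poisson
  equal-mean-variance assumption).
* The plug-in \(\lambda = f_\mathrm{in}(x)\) ignores input sampling noise;
  with deep input coverage and a power-mode zoom factor below ~0.5 the test
  is conservative, while shallow input coverage can make it anticonservative
  in the extreme tail.
* Exact-occurrence mappability is stricter than aligner uniqueness with
  mismatches; the two converge for perfect reads.
* BAM, CRAM and bigWig are out of scope; SAM text, BED, BEDPE, FASTA and
  FASTQ (plain or gzip) are the supported interchange formats.
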