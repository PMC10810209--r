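test_that("zoom factor follows the digit count of the smaller total", {
  expect_equal(zoomFactor(1, 1), 10)                    # modes coincide
  expect_equal(zoomFactor(1, 5e8, "literal"), 10)
  expect_equal(zoomFactor(1e6, 1e8, "power"), 1e7)
  expect_equal(zoomFactor(1e6, 1e8, "literal"), 70)
  expect_equal(zoomFactor(999, 10), 1e2)                # d = 2
  # symmetric in its arguments
  expect_equal(zoomFactor(1234, 9e7), zoomFactor(9e7, 1234))
  expect_error(zoomFactor(0, 10), "totalInput")
})

test_that("normalization coefficient matches direct evaluation", {
  # omega / (N * c * log(1+p))
  expect_equal(normalizationCoefficient(LibraryStats(1000, 1, 15), 1e4),
               1e4 / (1000 * 15 * log(2)), tolerance = 1e-12)
  expect_equal(normalizationCoefficient(LibraryStats(1e6, 1, 15), 70),
               70 / (1e6 * 15 * log(2)), tolerance = 1e-12)
  expect_equal(normalizationCoefficient(LibraryStats(1e6, 1, 15), 70),
               6.7327e-6, tolerance = 1e-4)
  # linear in omega
  s <- LibraryStats(5e5, 0.8, 12)
  expect_equal(normalizationCoefficient(s, 2e6),
               2 * normalizationCoefficient(s, 1e6), tolerance = 1e-12)
  # base-10 denominator
  expect_equal(normalizationCoefficient(s, 1e6, logBase = "base10"),
               1e6 / (5e5 * 12 * log10(1.8)), tolerance = 1e-12)
  # p = 0 would zero the denominator; rejected at construction
  expect_error(LibraryStats(1000, 0, 15), "pcrEfficiency")
})

test_that("count normalization is linear with f(0) = 0", {
  coef <- 1e4 / (1000 * 15 * log(2))
  expect_equal(normalizeCount(0, coef), 0)
  expect_equal(normalizeCount(2, coef), 1.92359, tolerance = 1e-5)
  a <- 3; b <- 11
  expect_equal(normalizeCount(a + b, coef),
               normalizeCount(a, coef) + normalizeCount(b, coef))
  expect_error(normalizeCount(-1, coef), "non-negative")
})

test_that("upper-tail Poisson p-values agree with pmf summation", {
  expect_equal(poissonUpperPvalue(0, 7.3), 1)
  expect_equal(poissonUpperPvalue(1, 0), 0)
  expect_equal(poissonUpperPvalue(5, 2), 0.052653, tolerance = 1e-5)
  lambdas <- c(0.05, 0.5, 1, 2, 5, 10, 25, 50)
  ks <- c(0:10, 20, 50, 100, 200)
  for (lam in lambdas) {
    expect_lt(max(abs(poissonUpperPvalue(ks, lam) -
                      poisUpperOracle(ks, lam))), 1e-10)
  }
  # non-increasing in k at fixed lambda
  p <- poissonUpperPvalue(0:100, 7)
  expect_true(all(diff(p) <= 0))
  expect_error(poissonUpperPvalue(NaN, 1), "NA/NaN")
})

test_that("BH adjustment matches the reference step-up", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bhAdjust(rep(0.2, 9)), rep(0.2, 9))
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample.int(500L, 1))
    expect_equal(bhAdjust(p), bhStepUpOracle(p), tolerance = 1e-12)
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the worked toy screen reproduces the hand-computed calls", {
  stats <- LibraryStats(1000, 1, 15)
  paired <- data.frame(chrom = "chr1",
                       start = c(100, 200, 300),
                       end = c(125, 225, 325),
                       x = c(2, 0, 5), y = c(8, 8, 0))
  res <- callEnhancers(paired, stats, stats)
  p <- modelParameters(res)
  coef <- 1e4 / (1000 * 15 * log(2))        # ~0.9617967
  expect_equal(p$omega, 1e4)                 # MIN = 1000 -> 10^4
  expect_equal(p$coefIn, coef, tolerance = 1e-12)
  expect_equal(p$coefOut, coef, tolerance = 1e-12)
  expect_equal(p$kappa, coef, tolerance = 1e-12)
  tab <- callTable(res)

  # row 1: lambda = f_in(2), k = round(f_out(8)) = 8
  expect_equal(tab$lambda[1], 2 * coef, tolerance = 1e-12)
  expect_equal(tab$k[1], 8L)
  expect_equal(tab$pvalue[1], poisUpperOracle(8, 2 * coef),
               tolerance = 1e-12)
  expect_false(tab$compensated[1])

  # row 2: input-absent locus gets the compensation value
  expect_equal(tab$lambda[2], coef, tolerance = 1e-12)
  expect_true(tab$compensated[2])
  expect_equal(tab$pvalue[2], poisUpperOracle(8, coef), tolerance = 1e-12)
  expect_equal(tab$pvalue[2], 7.7e-6, tolerance = 1e-2)

  # row 3: absent from the output -> untested
  expect_true(is.na(tab$pvalue[3]) && is.na(tab$qvalue[3]))
  expect_false(tab$called[3])

  # continuous mode uses the gamma survival tail of the unrounded f_out
  cont <- callTable(callEnhancers(paired, stats, stats,
                                  kMode = "continuous"))
  expect_equal(cont$pvalue[1], pgamma(2 * coef, shape = 8 * coef),
               tolerance = 1e-12)
  expect_equal(cont$pvalue[1], 1.4e-3, tolerance = 0.05)
})

test_that("the test is one-sided for output enrichment; omega is symmetric", {
  inStats <- LibraryStats(2000, 1, 15)
  outStats <- LibraryStats(1000, 1, 10)
  paired <- data.frame(chrom = "chr1", start = c(100, 200),
                       end = c(125, 225), x = c(2, 10), y = c(30, 1))
  fwd <- callEnhancers(paired, inStats, outStats)
  swapped <- callEnhancers(
    transform(paired, x = paired$y, y = paired$x), outStats, inStats)
  expect_equal(modelParameters(fwd)$omega, modelParameters(swapped)$omega)
  expect_false(isTRUE(all.equal(callTable(fwd)$pvalue,
                                callTable(swapped)$pvalue)))
})

test_that("p-values are non-increasing in the output count at fixed input", {
  stats <- LibraryStats(1000, 1, 15)
  ys <- 1:40
  paired <- data.frame(chrom = "chr1", start = 100 * seq_along(ys),
                       end = 100 * seq_along(ys) + 25,
                       x = 3, y = ys)
  tab <- callTable(callEnhancers(paired, stats, stats))
  expect_true(all(diff(tab$pvalue) <= 1e-15))
})

test_that("compensation sweep trades calls against the non-overlap rate", {
  stats <- LibraryStats(1000, 1, 15)
  set.seed(21)
  n <- 60L
  paired <- data.frame(chrom = "chr1", start = 1000 * seq_len(n),
                       end = 1000 * seq_len(n) + 25,
                       x = 0, y = rpois(n, 4) + 1)   # all output-only
  regions <- GRanges("chr1", IRanges(1000 * seq_len(30) + 1, width = 25))
  mults <- c(0.1, 0.5, 1, 2, 3)
  sw <- compensationSweep(paired, stats, stats, regions,
                          multipliers = mults)
  expect_equal(sw$multiplier, mults)
  # larger compensation -> larger lambda -> fewer (or equal) calls
  expect_true(all(diff(sw$nCalled) <= 0))
  # multiplier 1 row reproduces the default caller exactly
  def <- callEnhancers(paired, stats, stats)
  expect_equal(sw$nCalled[sw$multiplier == 1],
               modelParameters(def)$nCalled)
  # rate agrees with a direct overlap count of the called loci
  called <- calledLoci(def)
  expect_equal(sw$nonOverlapRate[sw$multiplier == 1],
               mean(GenomicRanges::countOverlaps(called, regions) == 0))
  expect_error(compensationSweep(paired, stats, stats, regions,
                                 multipliers = numeric(0)), "non-empty")
  expect_warning(
    compensationSweep(paired, stats, stats, regions, multipliers = 3000),
    "nonOverlapRate reported as 0")
})

test_that("a global null screen stays near the nominal FDR", {
  # x, y i.i.d. Poisson with equal rates and equal library stats
  set.seed(31)
  stats <- LibraryStats(5e5, 1, 15)
  fracs <- vapply(1:5, function(i) {
    n <- 2000L
    paired <- data.frame(chrom = "chr1", start = 1000 * seq_len(n),
                         end = 1000 * seq_len(n) + 25,
                         x = rpois(n, 100), y = rpois(n, 100))
    res <- callEnhancers(paired, stats, stats)
    modelParameters(res)$nCalled / modelParameters(res)$nTested
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})
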