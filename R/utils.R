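## Internal helpers shared across modules.

## Reference-space span of a CIGAR string: sum of lengths of operations that
## consume the reference (M, D, N, =, X). NA cigar -> NA.
cigarReferenceSpan <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    m <- gregexpr("(\\d+)([MIDNSHP=X])", cg, perl = TRUE)[[1]]
    if (m[1] == -1L) stop("malformed CIGAR string: ", cg)
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    if (sum(nchar(toks)) != nchar(cg)) stop("malformed CIGAR string: ", cg)
    ops <- substr(toks, nchar(toks), nchar(toks))
    lens <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

## Commercial rounding (half away from zero); base round() rounds half to even.
roundHalfAwayFromZero <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## Restore RNG state on exit so functions taking an explicit seed do not
## perturb the caller's stream. seed = NULL leaves the RNG untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialization
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.assertScalarNumber <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x > max)
    stop("'", name, "' must be a single number in [", min, ", ", max, "]")
  invisible(x)
}
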