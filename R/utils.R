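## internal helpers shared across modules

## round half away from zero at `digits` decimals; base round() would give
## banker's rounding at .5 ties, which disagrees with the printed ratios
roundHalfAway <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

## coerce a reference to an upper-case character string of A/C/G/T and
## check its length
checkReference <- function(reference) {
  if (methods::is(reference, "DNAString") ||
      methods::is(reference, "DNAStringSet")) {
    if (methods::is(reference, "DNAStringSet")) {
      if (length(reference) != 1L)
        stop("reference must be a single sequence", call. = FALSE)
      reference <- reference[[1L]]
    }
    reference <- as.character(reference)
  }
  if (!is.character(reference) || length(reference) != 1L)
    stop("reference must be a single sequence", call. = FALSE)
  reference <- toupper(reference)
  if (nchar(reference) != MT_LENGTH)
    stop("reference must be ", MT_LENGTH, " nucleotides long, got ",
         nchar(reference), call. = FALSE)
  reference
}

refBase <- function(reference, locus) {
  substring(reference, locus, locus)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
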