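#' @importFrom stats dbinom median qt quantile rbinom rgeom rnbinom rnorm
#'   rpois runif sd setNames
#' @importFrom utils read.table write.table head tail
NULL

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed and a stage label, keeping the result
# within the 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_dna <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stopf("%s must be a non-empty character scalar", what)
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0L)
    stopf("%s contains a non-ACGT character at position %d", what, bad)
  invisible(sequence)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# scalar reverse complement without XString overhead (hot loops)
revcomp1 <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# Longest homopolymer run (bp) in a sequence.
max_homopolymer_run <- function(sequence) {
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1L]])
  max(r$lengths)
}

gc_fraction <- function(sequence) {
  n <- nchar(sequence)
  gc <- nchar(gsub("[^GC]", "", sequence))
  gc / n
}
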