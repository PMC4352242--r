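# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations do not
#' disturb the caller's RNG stream.
#'
#' @param seed Integer seed (must be < 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Base characters -> integer codes 0:3 (A,C,G,T); anything else -> NA.
baseCodes <- function(s) {
  codes <- rep(NA_integer_, 128L)
  codes[utf8ToInt("A")] <- 0L
  codes[utf8ToInt("C")] <- 1L
  codes[utf8ToInt("G")] <- 2L
  codes[utf8ToInt("T")] <- 3L
  codes[utf8ToInt(s)]
}

codesToBases <- function(codes) {
  intToUtf8(utf8ToInt("ACGT")[codes + 1L], multiple = FALSE)
}

# All k-mers of a character sequence as strings; windows containing non-ACGT
# letters are dropped.
seqKmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  km <- substring(s, starts, starts + k - 1L)
  km[!grepl("[^ACGT]", km)]
}

reverseComplement1 <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Count mismatching characters between two equal-length strings.
hammingMismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

checkScalarNumber <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("invalid configuration field '%s'", name), call. = FALSE)
  }
  invisible(TRUE)
}
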