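#' @importFrom stats rnorm runif rbinom rexp median sd cor.test pbinom
#' @importFrom utils head tail write.table read.table
NULL

BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# global RNG state. All stochastic operations in the package route through
# this, so there is no hidden global state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Fast random DNA string of length n (raw-byte sampling).
random_dna <- function(n) {
  if (n <= 0) return("")
  rawToChar(charToRaw(paste(BASES, collapse = ""))[sample.int(4L, n, replace = TRUE)])
}

#' Reverse complement of a DNA string
#'
#' @param x a single DNA string (A/C/G/T, case-insensitive).
#' @return the reverse complement as an upper-case string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Substitute bases at `idx` (1-based) of string `x` with random different bases.
mutate_bases <- function(x, idx) {
  if (length(idx) == 0L) return(x)
  r <- charToRaw(x)
  lookup <- charToRaw(paste(BASES, collapse = ""))
  for (i in idx) {
    cur <- r[i]
    repl <- lookup[sample.int(4L, 1L)]
    while (repl == cur) repl <- lookup[sample.int(4L, 1L)]
    r[i] <- repl
  }
  rawToChar(r)
}

# Vectorised: returns TRUE for strings containing a homopolymer run >= n.
has_homopolymer <- function(x, n = 5L) {
  pat <- paste(sprintf("%s{%d}", BASES, n), collapse = "|")
  grepl(pat, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
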