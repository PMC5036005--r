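#' @import methods
#' @importFrom stats quantile rbinom rpois runif setNames t.test cor.test
#'   fisher.test qbinom
#' @importFrom utils read.delim write.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

COMP <- c(A = "T", C = "G", G = "C", T = "A")

## reverse complement for a character vector of (short) DNA strings
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## deterministic 31-bit hash of arbitrary string pieces; used to derive
## per-record RNG substreams so results are independent of record order
mixSeed <- function(seed, ...) {
  s <- paste(c(seed, ...), collapse = "\r")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(s)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

## evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## coerce a reference argument (DNAStringSet, DNAString, or named character
## vector) to a named character vector of uppercase sequences
refAsCharacter <- function(reference) {
  if (is(reference, "DNAStringSet")) {
    out <- as.character(reference)
  } else if (is(reference, "DNAString")) {
    out <- setNames(as.character(reference), "ref")
  } else if (is.character(reference)) {
    out <- toupper(reference)
    if (is.null(names(out))) {
      if (length(out) == 1L) names(out) <- "ref"
      else stop("a multi-sequence character reference must be named")
    }
  } else {
    stop("reference must be a DNAStringSet, DNAString or named character vector")
  }
  if (anyDuplicated(names(out))) stop("duplicate sequence names in reference")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnotScalarIn <- function(x, nm, choices) {
  if (!is.character(x) || length(x) != 1L || !x %in% choices)
    stop(sprintf("'%s' must be one of: %s", nm, paste(choices, collapse = ", ")))
  invisible(x)
}
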