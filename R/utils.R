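#' @importFrom stats rmultinom rbinom runif setNames
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of plain character sequences
#'
#' Vectorised reverse complement over `{A,C,G,T,N}` plus the IUPAC ambiguity
#' codes, operating on ordinary character vectors (the package's working
#' representation; `Biostrings` handles file I/O).
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTNRYSWKMBDHVacgtn", "TGCANYRSWMKVHDBtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): sequences differ in length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# split a string into a character vector of single bases
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# deterministic per-call RNG scoping: all generators funnel through this so
# they are pure functions of (arguments, seed) and never touch the caller's
# RNG stream
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# uniform random DNA of length n (caller provides RNG scope)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# apply i.i.d. substitution errors at rate `rate` to a character vector of
# reads; substitutions always change the base
mutate_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    s <- chars(seqs[i])
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

usage_error <- function(...) stop(..., call. = FALSE)
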