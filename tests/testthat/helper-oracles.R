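# Independent brute-force oracles used to validate the package's
# implementations on small instances. These deliberately share no code with
# the package internals.

# -- IUPAC expansion oracle ---------------------------------------------------
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_iupac_match <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  all(mapply(function(base, sym) base %in% IUPAC_SETS[[sym]], s, p))
}

oracle_all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE])
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

# -- target-scan oracle: sliding window on both strands -----------------------
oracle_find_targets <- function(seq, pam, guide_len) {
  L <- nchar(seq)
  plen <- nchar(pam)
  hits <- list()
  scan <- function(sq, strand) {
    for (i in seq_len(nchar(sq) - plen + 1)) {
      window <- substr(sq, i, i + plen - 1)
      if (i - guide_len >= 1 && oracle_iupac_match(window, pam)) {
        proto <- substr(sq, i - guide_len, i - 1)
        if (strand == "+") {
          hits[[length(hits) + 1]] <<- c(start = i - guide_len, end = i + plen - 1,
                                         strand = strand, protospacer = proto, pam = window)
        } else {
          hits[[length(hits) + 1]] <<- c(start = L - (i + plen - 1) + 1,
                                         end = L - (i - guide_len) + 1,
                                         strand = strand, protospacer = proto, pam = window)
        }
      }
    }
  }
  scan(seq, "+")
  scan(oracle_revcomp(seq), "-")
  if (length(hits) == 0) return(NULL)
  df <- as.data.frame(do.call(rbind, hits), stringsAsFactors = FALSE)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df[order(df$start, df$strand), , drop = FALSE]
}

# -- global affine alignment score oracle (Gotoh) -----------------------------
# gap of length L costs open + L * ext (both positive), matching the
# package's stated scoring convention
oracle_nw_affine_score <- function(a, b, match = 2, mismatch = -4,
                                   open = 6, ext = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1); Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - (i - 1) * ext
  for (j in 2:(m + 1)) Iy[1, j] <- -open - (j - 1) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# -- exhaustive repeated-substring array oracle -------------------------------
# reports whether any substring of length >= min_repeat recurs at a distance
# compatible with the array geometry (used on short contigs only)
oracle_has_array <- function(seq, min_repeat = 18, max_repeat = 45,
                             min_spacer = 15, max_spacer = 45) {
  L <- nchar(seq)
  for (len in min_repeat:max_repeat) {
    if (len > L) break
    subs <- substring(seq, 1:(L - len + 1), len:L)
    for (i in seq_along(subs)) {
      lo <- i + len + min_spacer; hi <- min(i + len + max_spacer, length(subs))
      if (lo > hi) next
      if (any(subs[lo:hi] == subs[i])) return(TRUE)
    }
  }
  FALSE
}

# fixed random DNA helper for tests
rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a reference amplicon whose cut-site neighbourhood has no immediate base
# repeats, so default spectrum labels are already left-aligned
editing_ref <- function(len = 350, cut = 180, seed = 42) {
  ref <- rand_dna(len, seed)
  core <- "ACGTACGTACGT"  # distinct adjacent bases around the cut
  substr(ref, cut - 5, cut - 5 + nchar(core) - 1) <- core
  ref
}
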