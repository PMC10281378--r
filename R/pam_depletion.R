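#' Count PAM variants in screen reads
#'
#' Locates the fixed protospacer (anchor) in each read by best
#' substitution-only match with at most `max_anchor_mismatch` mismatches and
#' takes the pattern-length window immediately 3' of it (on the
#' spacer-matching strand) as the read's PAM variant. Reads that fail
#' anchoring, whose window runs off the read, or whose window does not match
#' the library pattern are counted as unassigned.
#'
#' @param reads Sequence-record data frame.
#' @param spec A [pam_library_spec()].
#' @param max_anchor_mismatch Substitutions tolerated when locating the
#'   anchor.
#' @param sample_label Label stored in the returned table.
#' @return A [pam_count_table()] over the library's full variant universe,
#'   with the unassigned read count as attribute `unassigned`.
#' @export
count_pams <- function(reads, spec, max_anchor_mismatch = 1,
                       sample_label = "sample") {
  stopifnot(inherits(spec, "pam_library_spec"))
  plen <- nchar(spec$pattern)
  if (nrow(reads) == 0)
    return(pam_count_table(setNames(numeric(0), character(0)), spec$pattern,
                           sample_label))
  subj <- Biostrings::DNAStringSet(reads$seq)
  hits <- Biostrings::vmatchPattern(spec$anchor, subj,
                                    max.mismatch = max_anchor_mismatch)
  starts <- lapply(Biostrings::startIndex(hits), function(x) x %||% integer(0))
  first <- vapply(starts, function(x) if (length(x)) x[1] else NA_integer_, integer(1))
  pam_start <- first + nchar(spec$anchor)
  window <- substr(reads$seq, pam_start, pam_start + plen - 1L)
  ok <- !is.na(first) & nchar(window) == plen & iupac_match_safe(window, spec$pattern)
  counts <- table(window[ok])
  pam_count_table(setNames(as.numeric(counts), names(counts)), spec$pattern,
                  sample_label, unassigned = sum(!ok))
}

# iupac_match() tolerant of NA / wrong-length entries (returns FALSE there)
iupac_match_safe <- function(seq, pattern) {
  ok <- !is.na(seq) & nchar(seq) == nchar(pattern) & grepl("^[ACGT]*$", seq)
  res <- rep(FALSE, length(seq))
  if (any(ok)) res[ok] <- iupac_match(seq[ok], pattern)
  res
}

#' Per-variant depletion scores (log2 fold-change) of a PAM screen
#'
#' For each variant, `log2fc = log2(f_control / f_treatment)` with
#' pseudocounted frequencies `f = (count + pseudocount) / (total +
#' pseudocount * V)`. The ratio is oriented so that a variant depleted from
#' the treatment (nuclease-expressing) arm scores high: a large positive
#' value marks a nuclease-permissive PAM. With `pseudocount > 0` all scores
#' are finite.
#'
#' @param treatment,control `pam_count_table`s over the same variant
#'   universe.
#' @param pseudocount Added to every count (default 1 read per variant).
#' @return A `depletion_scores` object: data frame with `variant` and
#'   `log2fc`, plus the pseudocount and arm labels as attributes.
#' @export
depletion_log2fc <- function(treatment, control, pseudocount = 1) {
  stopifnot(inherits(treatment, "pam_count_table"),
            inherits(control, "pam_count_table"))
  if (!identical(names(treatment$counts), names(control$counts)))
    usage_error("depletion_log2fc(): arms cover different variant universes")
  ft <- pam_freq(treatment, pseudocount)
  fc <- pam_freq(control, pseudocount)
  if (any(ft == 0) || any(fc == 0))
    usage_error("depletion_log2fc(): zero frequency with zero pseudocount; ",
                "set pseudocount > 0 or drop zero-count variants")
  scores <- data.frame(variant = names(ft), log2fc = as.numeric(log2(fc / ft)),
                       stringsAsFactors = FALSE)
  structure(scores, class = c("depletion_scores", "data.frame"),
            pseudocount = pseudocount,
            arms = c(treatment = treatment$sample, control = control$sample))
}

#' @export
print.depletion_scores <- function(x, ...) {
  arms <- attr(x, "arms")
  cat(sprintf("Depletion scores: log2(f_%s / f_%s), pseudocount %s; high = depleted = active PAM\n",
              arms["control"], arms["treatment"], format(attr(x, "pseudocount"))))
  print.data.frame(head(x[order(-x$log2fc), ], 5))
  invisible(x)
}

#' Select depleted (nuclease-permissive) PAM variants
#'
#' Variants whose depletion score is strictly greater than the threshold
#' (the screen's selection rule uses log2 fold-change > 7).
#'
#' @param scores A `depletion_scores` object.
#' @param threshold Strict lower bound on `log2fc`.
#' @return Character vector of selected variants (sorted).
#' @export
select_depleted <- function(scores, threshold = 7) {
  sort(scores$variant[scores$log2fc > threshold])
}

#' Position frequency matrix and information content of a variant set
#'
#' Builds the per-position nucleotide frequency matrix (PFM; columns sum to
#' 1) of a set of equal-length sequences, optionally weighted, and the
#' per-position information content `IC_j = 2 - H_j` where `H_j` is the
#' Shannon entropy of column `j` in bits. No small-sample correction is
#' applied.
#'
#' @param variants Character vector of equal-length sequences, or a named
#'   numeric vector of weights (names are the sequences).
#' @param weights Optional numeric weights, one per variant.
#' @return A `logo_matrix` object: list with `pfm` (4 x L matrix, rows
#'   A/C/G/T) and `ic` (length-L numeric, bits in `[0, 2]`).
#' @export
#' @examples
#' logo_matrix(c("TGGA", "TGGT", "TGGG", "TGGC"))$ic
logo_matrix <- function(variants, weights = NULL) {
  if (is.numeric(variants) && !is.null(names(variants))) {
    weights <- as.numeric(variants)
    variants <- names(variants)
  }
  if (length(variants) == 0) usage_error("logo_matrix(): empty input")
  if (length(unique(nchar(variants))) != 1)
    usage_error("logo_matrix(): variants must be equal length")
  if (is.null(weights)) weights <- rep(1, length(variants))
  if (any(weights < 0) || sum(weights) == 0)
    usage_error("logo_matrix(): weights must be non-negative with positive sum")
  L <- nchar(variants[1])
  m <- matrix(unlist(strsplit(variants, "", fixed = TRUE)), ncol = L, byrow = TRUE)
  pfm <- vapply(seq_len(L), function(j) {
    v <- vapply(c("A", "C", "G", "T"), function(b) sum(weights[m[, j] == b]), numeric(1))
    v / sum(weights)
  }, numeric(4))
  rownames(pfm) <- c("A", "C", "G", "T")
  colnames(pfm) <- seq_len(L)
  ent <- apply(pfm, 2, function(p) { p <- p[p > 0]; -sum(p * log2(p)) })
  structure(list(pfm = pfm, ic = 2 - ent), class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("Logo matrix (PFM + information content, bits):\n")
  print(round(rbind(x$pfm, IC = x$ic), 3))
  invisible(x)
}

#' Write a logo matrix as TSV
#'
#' One row per position: frequencies of A, C, G, T and the information
#' content in bits.
#'
#' @param x A `logo_matrix`.
#' @param path Output path.
#' @export
write_logo_tsv <- function(x, path) {
  tb <- data.frame(position = seq_along(x$ic), t(x$pfm), IC = x$ic)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
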