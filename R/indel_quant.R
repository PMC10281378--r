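#' Globally align an amplicon read to its reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties (match +2,
#' mismatch -4, gap open -6, gap extend -1, so a length-`L` gap costs
#' `6 + L`), computed with [Biostrings::pairwiseAlignment()]. Reads
#' identical to the reference short-circuit to a trivial gapless alignment.
#' Indels extracted from the alignment are left-normalized against the
#' reference (shifted to their 5'-most equivalent placement), making event
#' coordinates deterministic regardless of traceback tie-breaking.
#'
#' @param read,ref Sequence strings or one-row sequence-record data frames.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @return An `amplicon_alignment` object: `score`, `events` (data frame of
#'   `type` (`"D"`/`"I"`/`"S"`), `ref_pos`, `len`, `bases`), and the aligned
#'   strings.
#' @export
align_amplicon <- function(read, ref, match = 2, mismatch = -4,
                           gap_open = -6, gap_ext = -1) {
  rd <- toupper(if (is.data.frame(read)) read$seq[1] else read)
  rf <- toupper(if (is.data.frame(ref)) ref$seq[1] else ref)
  if (rd == rf) {
    return(structure(list(score = match * nchar(rf),
                          events = empty_events(),
                          aligned_read = rd, aligned_ref = rf),
                     class = "amplicon_alignment"))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(rd, rf, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = abs(gap_open),
                                       gapExtension = abs(gap_ext))
  a_read <- as.character(Biostrings::alignedPattern(aln))
  a_ref <- as.character(Biostrings::alignedSubject(aln))
  events <- extract_events(a_read, a_ref)
  events <- left_normalize_events(events, rf)
  structure(list(score = Biostrings::score(aln), events = events,
                 aligned_read = a_read, aligned_ref = a_ref),
            class = "amplicon_alignment")
}

empty_events <- function() {
  data.frame(type = character(0), ref_pos = integer(0), len = integer(0),
             bases = character(0), stringsAsFactors = FALSE)
}

# walk a gapped alignment and list substitution / insertion / deletion runs;
# ref_pos is the 1-based reference start of a deletion or substitution, and
# the reference base *preceding* an insertion (0 for an insertion before
# base 1)
extract_events <- function(a_read, a_ref) {
  r <- chars(a_read); f <- chars(a_ref)
  ev <- list()
  ref_pos <- 0L
  i <- 1L
  n <- length(r)
  while (i <= n) {
    if (f[i] == "-") {          # insertion run
      j <- i
      while (j <= n && f[j] == "-") j <- j + 1L
      ev[[length(ev) + 1]] <- data.frame(type = "I", ref_pos = ref_pos,
                                         len = j - i,
                                         bases = paste(r[i:(j - 1)], collapse = ""),
                                         stringsAsFactors = FALSE)
      i <- j
    } else if (r[i] == "-") {   # deletion run
      j <- i
      while (j <= n && r[j] == "-" && f[j] != "-") j <- j + 1L
      ev[[length(ev) + 1]] <- data.frame(type = "D", ref_pos = ref_pos + 1L,
                                         len = j - i,
                                         bases = paste(f[i:(j - 1)], collapse = ""),
                                         stringsAsFactors = FALSE)
      ref_pos <- ref_pos + (j - i)
      i <- j
    } else {
      if (r[i] != f[i]) {
        ev[[length(ev) + 1]] <- data.frame(type = "S", ref_pos = ref_pos + 1L,
                                           len = 1L, bases = r[i],
                                           stringsAsFactors = FALSE)
      }
      ref_pos <- ref_pos + 1L
      i <- i + 1L
    }
  }
  if (length(ev)) do.call(rbind, ev) else empty_events()
}

# VCF-style left alignment: shift each indel to its 5'-most equivalent
# placement on the reference
left_normalize_events <- function(events, refseq) {
  if (nrow(events) == 0) return(events)
  for (k in seq_len(nrow(events))) {
    if (events$type[k] == "D") {
      p <- events$ref_pos[k]; l <- events$len[k]
      while (p > 1 && substr(refseq, p - 1, p - 1) == substr(refseq, p + l - 1, p + l - 1))
        p <- p - 1L
      events$ref_pos[k] <- p
      events$bases[k] <- substr(refseq, p, p + l - 1)
    } else if (events$type[k] == "I") {
      p <- events$ref_pos[k]  # anchor: ref base preceding the insertion
      b <- events$bases[k]; l <- events$len[k]
      while (p > 0 && substr(refseq, p, p) == substr(b, l, l)) {
        b <- paste0(substr(refseq, p, p), substr(b, 1, l - 1))
        p <- p - 1L
      }
      events$ref_pos[k] <- p
      events$bases[k] <- b
    }
  }
  events
}

#' Classify a read's editing outcome around the cut site
#'
#' Labels indel events overlapping the scoring window
#' `[cut_pos - window, cut_pos + window]` in cut-relative notation
#' (`"-2:1D"` = 1-nt deletion starting 2 nt 5' of the cut; `"+1:2I"` = 2-nt
#' insertion anchored at the cut; see [parse_allele_label()]). A read is
#' class `indel` iff at least one indel overlaps the window; reads with
#' substitutions but no in-window indel are `snv_only`; otherwise `wt`.
#' Indels outside the window do not change the class but are kept in
#' `events`.
#'
#' @param alignment An `amplicon_alignment`.
#' @param cut_pos Expected cut site (break between `cut_pos` and
#'   `cut_pos + 1` on the reference).
#' @param window Half-width of the scoring window in nt.
#' @param id Read identifier carried into the call.
#' @return An `allele_call` object: `id`, `class`, `labels` (in-window
#'   indel labels, `";"`-joined composite for multi-indel reads), `score`,
#'   `events`.
#' @export
call_allele <- function(alignment, cut_pos, window = 5, id = NA_character_) {
  ev <- alignment$events
  lab <- character(0)
  in_window <- logical(nrow(ev))
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      if (ev$type[k] == "D") {
        span <- c(ev$ref_pos[k], ev$ref_pos[k] + ev$len[k] - 1L)
        in_window[k] <- span[1] <= cut_pos + window && span[2] >= cut_pos - window
        if (in_window[k])
          lab <- c(lab, sprintf("%+d:%dD", ref_to_rel(ev$ref_pos[k], cut_pos), ev$len[k]))
      } else if (ev$type[k] == "I") {
        pos <- ev$ref_pos[k] + 1L  # first ref base displaced by the insertion
        in_window[k] <- pos >= cut_pos - window && pos <= cut_pos + window + 1L
        if (in_window[k])
          lab <- c(lab, sprintf("%+d:%dI", ref_to_rel(pos, cut_pos), ev$len[k]))
      }
    }
  }
  cls <- if (length(lab)) "indel" else if (any(ev$type == "S")) "snv_only" else "wt"
  structure(list(id = id, class = cls, labels = lab,
                 label = if (length(lab)) paste(lab, collapse = ";") else NA_character_,
                 score = alignment$score, events = ev),
            class = "allele_call")
}

#' Align and classify a whole amplicon read set
#'
#' Convenience wrapper: aligns every read to the reference and calls
#' [call_allele()] on each.
#'
#' @param reads Sequence-record data frame.
#' @param ref Reference amplicon.
#' @param cut_pos Expected cut site.
#' @param window Scoring window half-width.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring parameters,
#'   as in [align_amplicon()].
#' @return List of `allele_call` objects.
#' @details Reads are deduplicated before alignment and identical-to-
#'   reference reads bypass the aligner, so cost scales with the number of
#'   distinct edited sequences rather than the read count.
#' @export
call_alleles <- function(reads, ref, cut_pos, window = 5, match = 2,
                         mismatch = -4, gap_open = -6, gap_ext = -1) {
  rf <- toupper(if (is.data.frame(ref)) ref$seq[1] else ref)
  seqs <- toupper(reads$seq)
  wt_aln <- structure(list(score = match * nchar(rf), events = empty_events(),
                           aligned_read = rf, aligned_ref = rf),
                      class = "amplicon_alignment")
  uniq <- unique(seqs[seqs != rf])
  alns <- list()
  if (length(uniq)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch,
                                                    baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(uniq), rf,
                                        type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = abs(gap_open),
                                        gapExtension = abs(gap_ext))
    a_read <- as.character(Biostrings::alignedPattern(pa))
    a_ref <- as.character(Biostrings::alignedSubject(pa))
    scores <- Biostrings::score(pa)
    alns <- lapply(seq_along(uniq), function(k) {
      ev <- left_normalize_events(extract_events(a_read[k], a_ref[k]), rf)
      structure(list(score = scores[k], events = ev,
                     aligned_read = a_read[k], aligned_ref = a_ref[k]),
                class = "amplicon_alignment")
    })
    names(alns) <- uniq
  }
  lapply(seq_len(nrow(reads)), function(i) {
    aln <- if (seqs[i] == rf) wt_aln else alns[[seqs[i]]]
    call_allele(aln, cut_pos, window, id = reads$id[i])
  })
}

#' Summarize editing outcomes of an amplicon sample
#'
#' Editing efficiency is the percentage of reads whose class is `indel`;
#' SNV-only reads are excluded from the numerator (sequence variation
#' without an indel is not counted as editing) but remain in the
#' denominator. Reads below the minimum alignment score are dropped from
#' both and reported. The allele table lists label sets by descending
#' frequency (frequency denominator = classified reads).
#'
#' @param calls List of `allele_call` objects (or a single one).
#' @param min_score Reads with alignment score below this are dropped,
#'   not classified.
#' @param top Number of allele-table rows retained.
#' @return An `editing_summary`: `n_reads`, `n_indel`, `n_snv_only`,
#'   `n_dropped`, `percent_indel`, `alleles` (data frame label / count /
#'   frequency).
#' @export
summarize_editing <- function(calls, min_score = 0, top = 10) {
  if (inherits(calls, "allele_call")) calls <- list(calls)
  if (length(calls) == 0) usage_error("summarize_editing(): empty input")
  cls <- vapply(calls, function(x) x$class, character(1))
  sc <- vapply(calls, function(x) x$score, numeric(1))
  lab <- vapply(calls, function(x) x$label, character(1))
  keep <- sc >= min_score
  n <- sum(keep)
  if (n == 0) usage_error("summarize_editing(): all reads dropped by min_score")
  n_indel <- sum(cls[keep] == "indel")
  alleles <- sort(table(lab[keep & cls == "indel"]), decreasing = TRUE)
  alleles <- utils::head(data.frame(label = names(alleles),
                                    count = as.integer(alleles),
                                    frequency = as.numeric(alleles) / n,
                                    stringsAsFactors = FALSE), top)
  structure(list(n_reads = n, n_indel = n_indel,
                 n_snv_only = sum(cls[keep] == "snv_only"),
                 n_dropped = sum(!keep),
                 percent_indel = 100 * n_indel / n,
                 alleles = alleles),
            class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf("Editing summary: %d reads, %d with indels (%.2f%%), %d SNV-only excluded, %d dropped\n",
              x$n_reads, x$n_indel, x$percent_indel, x$n_snv_only, x$n_dropped))
  if (nrow(x$alleles)) {
    cat("  top alleles:\n")
    print(x$alleles, row.names = FALSE)
  }
  invisible(x)
}
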