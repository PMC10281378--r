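#' Detect CRISPR repeat-spacer arrays on a contig
#'
#' Seed-and-extend detector: exact 12-mers recurring at an admissible
#' periodicity (repeat + spacer length within the configured bounds) seed
#' candidate repeat pairs, each pair is extended to the maximal exactly
#' repeated span, and candidates are chained into arrays and validated
#' against the geometry bounds. Repeats within an array are exact or
#' near-exact copies (at most `max_mismatch` substitutions against the
#' consensus when chaining additional units). Arrays are reported 5'->3' by
#' start; ties break leftmost.
#'
#' @param contig A sequence string or a one-row sequence-record data frame.
#' @param min_repeat,max_repeat Repeat-unit length bounds (nt).
#' @param min_spacer,max_spacer Spacer length bounds (nt).
#' @param min_units Minimum repeat units per reported array.
#' @param max_mismatch Substitution budget when chaining further units.
#' @return List of `crispr_array` objects, each with `repeat_consensus`,
#'   `repeat_len`, `units` (data frame of 1-based closed coordinates),
#'   `spacers` (sequences plus coordinates). Empty list if none.
#' @export
find_crispr_arrays <- function(contig, min_repeat = 18, max_repeat = 45,
                               min_spacer = 15, max_spacer = 45,
                               min_units = 2, max_mismatch = 2) {
  seq <- toupper(if (is.data.frame(contig)) contig$seq[1] else contig)
  L <- nchar(seq)
  k <- 12L
  if (L < 2 * min_repeat + min_spacer) return(list())
  s <- chars(seq)
  kmers <- substring(seq, 1:(L - k + 1), k:L)
  occ <- split(seq_len(L - k + 1), kmers)
  occ <- occ[lengths(occ) > 1]
  d_min <- min_repeat + min_spacer
  d_max <- max_repeat + max_spacer
  cand <- list()
  seen <- character(0)
  for (pos in occ) {
    for (a in seq_len(length(pos) - 1)) {
      for (b in (a + 1):length(pos)) {
        i <- pos[a]; j <- pos[b]; d <- j - i
        if (d < d_min || d > d_max) next
        # extend the exact match maximally in both directions
        l <- 0L
        while (i - l - 1 >= 1 && s[i - l - 1] == s[j - l - 1]) l <- l + 1L
        r <- 0L
        while (j + k + r <= L && s[i + k + r] == s[j + k + r]) r <- r + 1L
        s1 <- i - l; replen <- k + l + r
        key <- paste(s1, s1 + d, replen)
        if (key %in% seen) next
        seen <- c(seen, key)
        if (replen < min_repeat || replen > max_repeat) next
        sp <- d - replen
        if (sp < min_spacer || sp > max_spacer) next
        cand[[length(cand) + 1]] <- c(s1 = s1, s2 = s1 + d, replen = replen)
      }
    }
  }
  if (length(cand) == 0) return(list())
  cand <- unique(do.call(rbind, cand))
  cand <- cand[order(cand[, "s1"], cand[, "s2"]), , drop = FALSE]
  # chain pairs sharing a unit into arrays, then extend greedily rightward
  arrays <- list()
  used <- rep(FALSE, nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    if (used[ci]) next
    starts <- unname(c(cand[ci, "s1"], cand[ci, "s2"]))
    replen <- unname(cand[ci, "replen"])
    consensus <- substr(seq, starts[1], starts[1] + replen - 1)
    repeat {
      last <- starts[length(starts)]
      nxt <- which(!used & cand[, "s1"] == last & cand[, "replen"] == replen)
      if (length(nxt) == 0) {
        # tolerate degenerate further units within the mismatch budget
        lo <- last + replen + min_spacer; hi <- min(last + replen + max_spacer, L - replen + 1)
        found <- NA
        if (lo <= hi) for (p in lo:hi) {
          if (hamming(substr(seq, p, p + replen - 1), consensus) <= max_mismatch) {
            found <- p; break
          }
        }
        if (is.na(found)) break
        starts <- c(starts, found)
      } else {
        used[nxt] <- TRUE
        starts <- c(starts, cand[nxt[1], "s2"])
      }
    }
    used[ci] <- TRUE
    used[cand[, "s1"] %in% starts & cand[, "s2"] %in% starts] <- TRUE
    if (length(starts) < min_units) next
    units <- data.frame(start = as.integer(starts),
                        end = as.integer(starts + replen - 1L))
    rownames(units) <- NULL
    spacers <- data.frame(
      seq = substring(seq, units$end[-nrow(units)] + 1, units$start[-1] - 1),
      start = units$end[-nrow(units)] + 1L, end = units$start[-1] - 1L,
      stringsAsFactors = FALSE)
    rownames(spacers) <- NULL
    arrays[[length(arrays) + 1]] <- structure(
      list(repeat_consensus = consensus, repeat_len = replen,
           units = units, spacers = spacers),
      class = "crispr_array")
  }
  # drop arrays nested inside an earlier (leftmost) one
  if (length(arrays) > 1) {
    spans <- vapply(arrays, function(a) c(a$units$start[1], a$units$end[nrow(a$units)]),
                    numeric(2))
    keep <- rep(TRUE, length(arrays))
    for (i in seq_along(arrays)) for (j in seq_along(arrays)) {
      if (i != j && keep[j] &&
          spans[1, i] >= spans[1, j] && spans[2, i] <= spans[2, j] &&
          !(spans[1, i] == spans[1, j] && spans[2, i] == spans[2, j] && i < j))
        keep[i] <- FALSE
    }
    arrays <- arrays[keep]
  }
  arrays[order(vapply(arrays, function(a) a$units$start[1], numeric(1)))]
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("CRISPR array: %d units of %d bp, spacers %s bp\n",
              nrow(x$units), x$repeat_len,
              paste(nchar(x$spacers$seq), collapse = "/")))
  cat("  consensus:", x$repeat_consensus, "\n")
  invisible(x)
}

#' Find open reading frames in all six frames
#'
#' ORFs are maximal ATG-to-stop spans: for each stop codon, the span starts
#' at the first ATG after the previous in-frame stop. By default open-ended
#' spans at contig edges (no terminating stop) are excluded so counts on
#' fixtures are reproducible. Translation uses the standard genetic code.
#'
#' @param contig A sequence string or a one-row sequence-record data frame.
#' @param min_len_aa Minimum protein length in residues (stop excluded).
#' @param include_open Also report stop-less spans running off the contig.
#' @return Data frame with `start`, `end` (1-based closed, forward-strand
#'   coordinates, stop codon included), `strand`, `len_aa`, `protein`.
#' @export
find_orfs <- function(contig, min_len_aa = 100, include_open = FALSE) {
  seq <- toupper(if (is.data.frame(contig)) contig$seq[1] else contig)
  L <- nchar(seq)
  scan_strand <- function(sq, strand) {
    out <- list()
    Ls <- nchar(sq)
    for (frame in 0:2) {
      n_cod <- (Ls - frame) %/% 3
      if (n_cod < 2) next
      starts <- frame + 1 + 3 * (0:(n_cod - 1))
      cods <- substring(sq, starts, starts + 2)
      is_stop <- cods %in% c("TAA", "TAG", "TGA")
      is_atg <- cods == "ATG"
      prev_stop <- 0L
      i <- 1L
      while (i <= n_cod) {
        if (is_stop[i]) { prev_stop <- i; i <- i + 1L; next }
        if (is_atg[i]) {
          # first ATG after the previous stop opens the maximal span
          stop_at <- if (any(is_stop[i:n_cod])) i - 1L + which(is_stop[i:n_cod])[1] else NA
          if (!is.na(stop_at)) {
            len_aa <- stop_at - i
            if (len_aa >= min_len_aa) {
              prot <- paste(GENETIC_CODE_TABLE[cods[i:(stop_at - 1)]], collapse = "")
              out[[length(out) + 1]] <- data.frame(
                start = starts[i], end = starts[stop_at] + 2L, strand = strand,
                len_aa = len_aa, protein = prot, stringsAsFactors = FALSE)
            }
            i <- stop_at + 1L
            prev_stop <- stop_at
          } else {
            if (include_open && n_cod - i + 1 >= min_len_aa) {
              prot <- paste(GENETIC_CODE_TABLE[cods[i:n_cod]], collapse = "")
              out[[length(out) + 1]] <- data.frame(
                start = starts[i], end = starts[n_cod] + 2L, strand = strand,
                len_aa = n_cod - i + 1L, protein = prot, stringsAsFactors = FALSE)
            }
            break
          }
        } else i <- i + 1L
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  fwd <- scan_strand(seq, "+")
  rev <- scan_strand(revcomp(seq), "-")
  if (!is.null(rev)) {
    tmp <- L - rev$end + 1L
    rev$end <- L - rev$start + 1L
    rev$start <- tmp
  }
  res <- rbind(fwd, rev)
  if (is.null(res)) {
    return(data.frame(start = integer(0), end = integer(0), strand = character(0),
                      len_aa = integer(0), protein = character(0)))
  }
  res[order(res$start, res$end), , drop = FALSE]
}

# standard genetic code, codon -> single-letter amino acid
GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  gc[gc == "*"] <- "*"
  gc
})

#' Search for an anti-repeat (tracrRNA candidate) near an array
#'
#' Gapless (substitution-only) scan of a window on each side of the array
#' for approximate matches to the repeat consensus or its reverse
#' complement; array units themselves are excluded. Candidates are sorted
#' by mismatch count, then by distance to the array.
#'
#' @param contig A sequence string or a one-row sequence-record data frame.
#' @param array A `crispr_array` (or a list with `repeat_consensus` and
#'   `units`).
#' @param window Search window on each side of the array, nt (clipped at
#'   contig ends).
#' @param max_mismatch Maximum substitutions allowed.
#' @return Data frame with `start`, `end`, `strand` (`"-"` when the reverse
#'   complement of the repeat matches, i.e. the repeat matches the minus
#'   strand), `mismatches`, `distance_to_array`.
#' @export
find_anti_repeat <- function(contig, array, window = 2000, max_mismatch = 6) {
  seq <- toupper(if (is.data.frame(contig)) contig$seq[1] else contig)
  L <- nchar(seq)
  rep_c <- array$repeat_consensus
  rl <- nchar(rep_c)
  arr_lo <- min(array$units$start); arr_hi <- max(array$units$end)
  lo <- max(1L, arr_lo - window); hi <- min(L, arr_hi + window)
  if (hi - rl + 1 < lo) return(empty_anti())
  starts <- lo:(hi - rl + 1)
  wins <- substring(seq, starts, starts + rl - 1)
  mm_fwd <- colSums(matrix(unlist(strsplit(wins, "", fixed = TRUE)), nrow = rl) != chars(rep_c))
  mm_rev <- colSums(matrix(unlist(strsplit(wins, "", fixed = TRUE)), nrow = rl) != chars(revcomp(rep_c)))
  strand <- ifelse(mm_rev < mm_fwd, "-", "+")
  mm <- pmin(mm_fwd, mm_rev)
  keep <- mm <= max_mismatch
  # exclude any window overlapping an array unit
  for (u in seq_len(nrow(array$units))) {
    keep <- keep & !(starts <= array$units$end[u] & starts + rl - 1 >= array$units$start[u])
  }
  if (!any(keep)) return(empty_anti())
  st <- starts[keep]
  dist <- pmax(0L, pmax(arr_lo - (st + rl - 1L), st - arr_hi) - 1L)
  res <- data.frame(start = st, end = st + rl - 1L, strand = strand[keep],
                    mismatches = mm[keep], distance_to_array = dist,
                    stringsAsFactors = FALSE)
  res[order(res$mismatches, res$distance_to_array, res$start), , drop = FALSE]
}

empty_anti <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             mismatches = integer(0), distance_to_array = integer(0))
}

#' Assemble a single-guide RNA scaffold
#'
#' Concatenates, 5' to 3': the spacer, the 3'-truncated repeat (its first
#' `keep_repeat` nt, the crRNA-retained portion adjoining the
#' spacer-repeat junction), the tetraloop linker and the first `keep_tracr`
#' nt of the tracrRNA fragment (whose 5' end is the anti-repeat). With the
#' packaged defaults (23-nt spacer, 18-nt repeat, GAAA, 73-nt tracr
#' fragment) this yields a 118-nt guide over a 95-nt constant backbone.
#' The repeat part and the anti-repeat region of the tracr part are checked
#' for duplex formation (reverse-complement alignment, substitution
#' mismatches counted against `duplex_budget`).
#'
#' @param repeat_seq CRISPR repeat sequence.
#' @param tracr tracrRNA fragment, 5' end at the anti-repeat.
#' @param spacer Spacer sequence (may be empty for a backbone-only design).
#' @param keep_repeat Repeat nt retained (from the 5' end).
#' @param linker Tetraloop linker.
#' @param keep_tracr tracr nt retained (from the 5' end).
#' @param duplex_budget Maximum repeat:anti-repeat mismatches tolerated
#'   before a warning is raised.
#' @return An `sgrna_design` object: components, their coordinates in the
#'   assembled guide (1-based closed), `full_sequence`, and the duplex
#'   mismatch count.
#' @export
#' @examples
#' p <- eh_preset()
#' d <- design_sgrna(p$`repeat`, p$tracr, strrep("A", 23))
#' nchar(d$full_sequence)  # 118
design_sgrna <- function(repeat_seq, tracr, spacer = "",
                         keep_repeat = 18, linker = "GAAA", keep_tracr = 73,
                         duplex_budget = 6) {
  repeat_seq <- toupper(repeat_seq); tracr <- toupper(tracr); spacer <- toupper(spacer)
  if (keep_repeat > nchar(repeat_seq))
    usage_error("design_sgrna(): keep_repeat exceeds the repeat length")
  if (keep_tracr > nchar(tracr))
    usage_error("design_sgrna(): keep_tracr exceeds the tracrRNA fragment length")
  repeat_part <- substr(repeat_seq, 1, keep_repeat)
  tracr_part <- substr(tracr, 1, keep_tracr)
  full <- paste0(spacer, repeat_part, linker, tracr_part)
  lens <- c(spacer = nchar(spacer), repeat_part = keep_repeat,
            linker = nchar(linker), tracr_part = keep_tracr)
  ends <- cumsum(lens)
  coords <- data.frame(component = names(lens),
                       start = unname(ends - lens + 1L), end = unname(ends),
                       stringsAsFactors = FALSE)
  rownames(coords) <- NULL
  n_dup <- min(keep_repeat, keep_tracr)
  mm <- hamming(substr(repeat_part, keep_repeat - n_dup + 1, keep_repeat),
                revcomp(substr(tracr_part, 1, n_dup)))
  if (mm > duplex_budget)
    warning("design_sgrna(): repeat:anti-repeat duplex has ", mm,
            " mismatches (budget ", duplex_budget, ")")
  structure(list(spacer = spacer, repeat_part = repeat_part, linker = linker,
                 tracr_part = tracr_part, full_sequence = full,
                 coords = coords, duplex_mismatches = mm),
            class = "sgrna_design")
}

#' @export
print.sgrna_design <- function(x, ...) {
  cat(sprintf("sgRNA design: %d nt (spacer %d + backbone %d)\n",
              nchar(x$full_sequence), nchar(x$spacer),
              nchar(x$full_sequence) - nchar(x$spacer)))
  cat("  ", x$full_sequence, "\n")
  cat("  repeat:anti-repeat duplex mismatches:", x$duplex_mismatches, "\n")
  invisible(x)
}

#' Enumerate PAM-constrained target sites in a sequence
#'
#' Scans both strands for the PAM pattern; each hit's protospacer is the
#' `guide_len` nt immediately 5' of the PAM on the spacer-matching strand.
#' Coordinates are 1-based closed on the forward strand and span the
#' protospacer plus PAM footprint.
#'
#' @param genome A sequence string or a one-row sequence-record data frame.
#' @param pam IUPAC PAM pattern (default `"TGGN"`, the motif used for
#'   target selection with this nuclease).
#' @param guide_len Protospacer length (default 23).
#' @return Data frame with `start`, `end`, `strand`, `protospacer`, `pam`.
#' @export
find_targets <- function(genome, pam = "TGGN", guide_len = 23) {
  seq <- toupper(if (is.data.frame(genome)) genome$seq[1] else genome)
  L <- nchar(seq)
  if (L < guide_len + nchar(pam))
    usage_error("find_targets(): sequence shorter than guide + PAM")
  scan <- function(sq) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pam),
                                     Biostrings::DNAString(sq),
                                     fixed = c(pattern = FALSE, subject = TRUE))
    st <- Biostrings::start(hits)
    st[st - guide_len >= 1]
  }
  plen <- nchar(pam)
  fw <- scan(seq)
  rc <- scan(revcomp(seq))
  res <- list()
  if (length(fw)) {
    res[[1]] <- data.frame(
      start = fw - guide_len, end = fw + plen - 1L, strand = "+",
      protospacer = substring(seq, fw - guide_len, fw - 1),
      pam = substring(seq, fw, fw + plen - 1), stringsAsFactors = FALSE)
  }
  if (length(rc)) {
    rcseq <- revcomp(seq)
    res[[length(res) + 1]] <- data.frame(
      start = L - (rc + plen - 1L) + 1L, end = L - (rc - guide_len) + 1L,
      strand = "-",
      protospacer = substring(rcseq, rc - guide_len, rc - 1),
      pam = substring(rcseq, rc, rc + plen - 1), stringsAsFactors = FALSE)
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(0), end = integer(0), strand = character(0),
                      protospacer = character(0), pam = character(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Build a linear recombineering template from two homology arms
#'
#' The template is the direct concatenation `upstream + downstream`; Lambda
#' Red-style recombination of such a template against a locus deletes the
#' segment between the two arm-matching regions. With the arm lengths used
#' for the pyrF deletion (145 + 163 bp) the template is 308 bp.
#'
#' @param upstream_arm,downstream_arm Homology arm sequences (non-empty).
#' @return A one-row sequence-record data frame with attribute `arms`
#'   giving the arm boundaries within the template.
#' @export
build_recomb_template <- function(upstream_arm, downstream_arm) {
  if (nchar(upstream_arm) == 0 || nchar(downstream_arm) == 0)
    usage_error("build_recomb_template(): arms must be non-empty")
  upstream_arm <- toupper(upstream_arm); downstream_arm <- toupper(downstream_arm)
  tmpl <- seq_records("recomb_template", paste0(upstream_arm, downstream_arm))
  attr(tmpl, "arms") <- data.frame(
    arm = c("upstream", "downstream"),
    start = c(1L, nchar(upstream_arm) + 1L),
    end = c(nchar(upstream_arm), nchar(upstream_arm) + nchar(downstream_arm)))
  tmpl
}

#' In silico recombination of a two-arm template against a locus
#'
#' Locates the exact, unique occurrences of the template's arms on the
#' locus (upstream arm first) and returns the sequence with the between-arm
#' segment deleted -- the expected Lambda Red editing outcome.
#'
#' @param locus A sequence string or one-row sequence-record data frame.
#' @param template Output of [build_recomb_template()].
#' @return List with `edited` (sequence string), `deleted` (the removed
#'   segment) and its coordinates.
#' @export
apply_recomb_template <- function(locus, template) {
  seq <- toupper(if (is.data.frame(locus)) locus$seq[1] else locus)
  arms <- attr(template, "arms")
  up <- substr(template$seq[1], arms$start[1], arms$end[1])
  down <- substr(template$seq[1], arms$start[2], arms$end[2])
  up_pos <- gregexpr(up, seq, fixed = TRUE)[[1]]
  down_pos <- gregexpr(down, seq, fixed = TRUE)[[1]]
  if (length(up_pos) != 1 || up_pos[1] == -1 ||
      length(down_pos) != 1 || down_pos[1] == -1)
    usage_error("apply_recomb_template(): arms must match the locus exactly once")
  if (down_pos[1] <= up_pos[1] + nchar(up) - 1)
    usage_error("apply_recomb_template(): downstream arm precedes upstream arm")
  del_start <- up_pos[1] + nchar(up)
  del_end <- down_pos[1] - 1L
  list(edited = paste0(substr(seq, 1, del_start - 1),
                       substr(seq, del_end + 1, nchar(seq))),
       deleted = substr(seq, del_start, del_end),
       deleted_start = del_start, deleted_end = del_end)
}
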