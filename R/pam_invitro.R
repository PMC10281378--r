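#' Normalize in vitro PAM occurrence against the control library
#'
#' Applies the cleavage-screen correction for library composition:
#' `norm(v) = f_T(v) * mean(f_C) / f_C(v)`, where `f_T` is the variant's
#' frequency among cleavage-fragment reads (treatment), `f_C` its frequency
#' in the no-nuclease control, and `mean(f_C)` the average control frequency
#' over all variants (a constant `1/V` for a complete library). When the
#' control composition is uniform the output equals the treatment frequency.
#' The pseudocount is applied to control counts only, guarding against
#' division by zero while leaving treatment frequencies untouched.
#'
#' @param treatment,control `pam_count_table`s over the same variant
#'   universe.
#' @param pseudocount Added to control counts (default 1).
#' @return A `normalized_occurrence` object: data frame with `variant` and
#'   `norm`, input frequencies kept as attributes.
#' @export
normalize_occurrence <- function(treatment, control, pseudocount = 1) {
  stopifnot(inherits(treatment, "pam_count_table"),
            inherits(control, "pam_count_table"))
  if (!identical(names(treatment$counts), names(control$counts)))
    usage_error("normalize_occurrence(): arms cover different variant universes")
  ft <- pam_freq(treatment, 0)
  fc <- pam_freq(control, pseudocount)
  if (any(fc == 0))
    usage_error("normalize_occurrence(): zero control frequency for ",
                names(fc)[which(fc == 0)[1]], "; use a pseudocount > 0")
  norm <- as.numeric(ft * mean(fc) / fc)
  structure(data.frame(variant = names(ft), norm = norm, stringsAsFactors = FALSE),
            class = c("normalized_occurrence", "data.frame"),
            treatment_freq = ft, control_freq = fc, mean_control_freq = mean(fc))
}

#' Top fraction of variants by normalized occurrence
#'
#' Retains the `floor(fraction * V)` variants with the highest normalized
#' occurrence (the screen's logo set uses the top 10%). Ties at the cutoff
#' break lexicographically, smaller variant retained.
#'
#' @param norm A `normalized_occurrence` object (or data frame with
#'   `variant`, `norm`).
#' @param fraction Fraction of the variant universe to retain, in `(0, 1]`.
#' @return Named numeric vector: normalized occurrence of the retained
#'   variants, in rank order.
#' @export
top_fraction <- function(norm, fraction = 0.10) {
  if (nrow(norm) == 0) usage_error("top_fraction(): empty table")
  if (fraction <= 0 || fraction > 1)
    usage_error("top_fraction(): fraction must be in (0, 1]")
  k <- floor(fraction * nrow(norm))
  ord <- order(-norm$norm, norm$variant)
  sel <- norm[ord[seq_len(k)], ]
  setNames(sel$norm, sel$variant)
}

# reverse IUPAC map: sorted base set -> degenerate code
IUPAC_FROM_SET <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  setNames(names(map),
           vapply(map, function(x) paste(sort(strsplit(x, "")[[1]]), collapse = ""),
                  character(1)))
})

#' Call IUPAC consensus strings from a position frequency matrix
#'
#' Produces the two consensus readings of a PAM logo:
#'
#' * **required**: positions where a single base reaches `require_freq`
#'   show that base; all others are `N`.
#' * **preferred**: positions with a dominant base (>= `require_freq`) show
#'   it; otherwise, if any base reaches `prefer_freq` the IUPAC code of the
#'   preferred base(s) is shown; otherwise bases at or below `exclude_freq`
#'   are excluded and the IUPAC code of the remainder is shown (`N` when
#'   nothing is excluded).
#'
#' On a screen where guanines at positions 2-3 are indispensable, cytosine
#' is discriminated against at 4 and thymine preferred at 5, this yields
#' `"NGGNNNN"` (required) and `"NGGDTNN"` (preferred).
#'
#' @param pfm A `logo_matrix` or a 4 x L matrix with rows A/C/G/T.
#' @param require_freq Frequency at which a base becomes required.
#' @param exclude_freq Frequency at or below which a base is excluded.
#' @param prefer_freq Frequency at which a base becomes preferred.
#' @return Named character vector with elements `required` and `preferred`.
#' @export
consensus_from_pfm <- function(pfm, require_freq = 0.9, exclude_freq = 0.05,
                               prefer_freq = 0.5) {
  m <- if (inherits(pfm, "logo_matrix")) pfm$pfm else pfm
  if (!is.matrix(m) || nrow(m) != 4 || is.null(rownames(m)) ||
      !identical(sort(rownames(m)), c("A", "C", "G", "T")))
    usage_error("consensus_from_pfm(): need a 4 x L matrix with rows A/C/G/T")
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  code_of <- function(set) {
    if (length(set) == 0) return("N")
    IUPAC_FROM_SET[[paste(sort(set), collapse = "")]]
  }
  required <- preferred <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    p <- m[, j]
    dominant <- names(p)[p >= require_freq]
    required[j] <- if (length(dominant) == 1) dominant else "N"
    if (length(dominant) == 1) {
      preferred[j] <- dominant
    } else if (any(p >= prefer_freq)) {
      preferred[j] <- code_of(names(p)[p >= prefer_freq])
    } else {
      preferred[j] <- code_of(names(p)[p > exclude_freq])
    }
  }
  c(required = paste(required, collapse = ""),
    preferred = paste(preferred, collapse = ""))
}

#' Infer the double-strand-break site from fragment termini
#'
#' Strips the ligated adapter from each read, maps the junction (the first
#' template base) onto the target context, and builds per-strand histograms
#' of terminus positions expressed as offsets from the PAM-proximal end of
#' the protospacer: the scissile phosphate `k` nt into the protospacer has
#' offset `k`, so a cut between the 3rd and 4th positions from the PAM is
#' offset 3 on that strand. Reads whose junction k-mer does not map
#' uniquely (the randomized PAM window is matched as `N`) are dropped. The
#' modal offset is reported per strand; the overhang is the absolute
#' difference of the two modes and the end type is blunt iff it is zero.
#'
#' @param reads Sequence-record data frame of adapter-ligated fragment
#'   reads.
#' @param context Target context with PAM coordinates, as returned by
#'   [target_context_from_spec()] (fields `seq`, `protospacer_end`).
#' @param adapter Adapter sequence expected at the 5' end of every read.
#' @param junction_k Junction k-mer length used for mapping.
#' @return A `cutsite_profile` object: per-strand offset histograms, modal
#'   offsets, `overhang`, `end_type` (`"blunt"`/`"staggered"`), an
#'   ambiguity flag per strand for tied modes, and the mapped read count.
#' @export
infer_cut_site <- function(reads, context, adapter = eh_preset()$screen$adapter,
                           junction_k = 12) {
  if (nrow(reads) == 0) usage_error("infer_cut_site(): no cleavage evidence (no reads)")
  ctx <- toupper(context$seq)
  pe <- context$protospacer_end
  L <- nchar(ctx)
  has_ad <- startsWith(reads$seq, adapter)
  template <- substr(reads$seq[has_ad], nchar(adapter) + 1L,
                     nchar(reads$seq[has_ad]))
  key <- substr(template, 1, junction_k)
  key <- key[nchar(key) == junction_k]
  uk <- unique(key)
  if (length(uk) == 0) usage_error("infer_cut_site(): no cleavage evidence")
  map_one <- function(k, subject) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(k),
                                     Biostrings::DNAString(subject),
                                     fixed = c(pattern = TRUE, subject = FALSE))
    if (length(hits) == 1) Biostrings::start(hits) else NA_integer_
  }
  fwd_pos <- vapply(uk, map_one, integer(1), subject = ctx)
  rev_pos <- vapply(uk, map_one, integer(1), subject = revcomp(ctx))
  # a key must map to exactly one strand to be used
  strand <- ifelse(!is.na(fwd_pos) & is.na(rev_pos), "+",
                   ifelse(is.na(fwd_pos) & !is.na(rev_pos), "-", NA))
  offset <- ifelse(strand == "+", pe - fwd_pos + 1L,
                   pe - (L - rev_pos + 1L))
  idx <- match(key, uk)
  read_strand <- strand[idx]
  read_offset <- offset[idx]
  keep <- !is.na(read_strand)
  if (!any(keep)) usage_error("infer_cut_site(): no cleavage evidence")
  tab <- function(str) {
    o <- read_offset[keep & read_strand == str]
    if (length(o) == 0) return(NULL)
    table(o)
  }
  modal <- function(h) {
    if (is.null(h)) return(list(mode = NA_integer_, ambiguous = FALSE))
    top <- which(h == max(h))
    list(mode = as.integer(names(h)[top[1]]), ambiguous = length(top) > 1)
  }
  h_top <- tab("+"); h_bot <- tab("-")
  m_top <- modal(h_top); m_bot <- modal(h_bot)
  overhang <- if (is.na(m_top$mode) || is.na(m_bot$mode)) NA_integer_ else
    abs(m_top$mode - m_bot$mode)
  structure(list(
    histogram = list(top = h_top, bottom = h_bot),
    modal_offset = c(top = m_top$mode, bottom = m_bot$mode),
    ambiguous = c(top = m_top$ambiguous, bottom = m_bot$ambiguous),
    overhang = overhang,
    end_type = if (!is.na(overhang) && overhang == 0) "blunt" else "staggered",
    n_mapped = sum(keep), n_reads = nrow(reads)),
    class = "cutsite_profile")
}

#' @export
print.cutsite_profile <- function(x, ...) {
  cat(sprintf("Cut-site profile (%d/%d reads mapped)\n", x$n_mapped, x$n_reads))
  cat(sprintf("  modal offset from PAM: top %s, bottom %s%s\n",
              x$modal_offset["top"], x$modal_offset["bottom"],
              if (any(x$ambiguous)) " (ambiguous mode)" else ""))
  cat(sprintf("  overhang %s nt -> %s ends\n", x$overhang, x$end_type))
  invisible(x)
}

#' Predicted fragment sizes of a linear substrate cut at a given offset
#'
#' Utility for checking cleavage products on a gel: a linear substrate of
#' length `substrate_len` whose PAM-proximal protospacer end sits at
#' `pe` (1-based) and is cut `offset` nt into the protospacer yields
#' fragments of `pe - offset` and `substrate_len - (pe - offset)` bp.
#'
#' @param substrate_len Substrate length in bp.
#' @param pe 1-based position of the PAM-proximal protospacer end.
#' @param offset Cut offset, nt from the PAM-proximal protospacer end.
#' @return Integer vector of the two fragment lengths.
#' @export
predict_fragment_sizes <- function(substrate_len, pe, offset = 3) {
  cut <- pe - offset
  if (cut < 1 || cut >= substrate_len)
    usage_error("predict_fragment_sizes(): cut outside the substrate")
  c(cut, substrate_len - cut)
}
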