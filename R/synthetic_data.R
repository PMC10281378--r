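#' Simulate a PAM-randomized plasmid library
#'
#' Draws per-variant molecule counts for a randomized-PAM plasmid pool by
#' multinomial sampling over the complete variant universe of the library
#' pattern. `skew = 0` gives a uniform composition (the default, matching a
#' well-made randomized library); `skew > 0` draws the composition from a
#' symmetric Dirichlet with concentration `1/skew`, so larger values give a
#' more uneven pool.
#'
#' @param spec A [pam_library_spec()].
#' @param depth Total number of molecules (default 1e5, the order of the
#'   pooled-transformant scale the screens operate at).
#' @param skew Composition skew (see above).
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @return List with `table` (a [pam_count_table()]) and `truth` (the
#'   sampled composition probabilities).
#' @export
#' @examples
#' gen_pam_library(eh_library_spec("invivo"), depth = 6400, seed = 1)$table
gen_pam_library <- function(spec, depth = 1e5, skew = 0, seed = 0) {
  stopifnot(inherits(spec, "pam_library_spec"))
  if (depth <= 0) usage_error("gen_pam_library(): depth must be positive")
  variants <- enumerate_pam_variants(spec$pattern)
  V <- length(variants)
  if (depth < V)
    warning("gen_pam_library(): depth ", depth, " below the number of variants (", V, ")")
  with_seed(seed, {
    probs <- if (skew == 0) rep(1 / V, V) else {
      g <- stats::rgamma(V, shape = 1 / skew, rate = 1)
      g / sum(g)
    }
    counts <- as.vector(rmultinom(1, depth, probs))
  })
  list(table = pam_count_table(setNames(counts, variants), spec$pattern, "library"),
       truth = list(probs = setNames(probs, variants)))
}

# layout of one screen read: flank5 + anchor + PAM variant + flank3
screen_read_seq <- function(spec, variants) {
  paste0(spec$flank5, spec$anchor, variants, spec$flank3)
}

#' Simulate treatment/control read pools of an in vivo depletion screen
#'
#' The control arm draws reads from the library composition; the treatment
#' arm draws from the composition reweighted by per-variant survival (the
#' probability that a plasmid carrying that PAM yields a transformant under
#' nuclease interference) and renormalized. Each read is
#' `flank5 + anchor + PAM + flank3` with i.i.d. substitution errors.
#'
#' @param library A `pam_count_table` describing the input pool.
#' @param activity Named survival vector over (at least) the library's
#'   variant universe, values in `[0, 1]`.
#' @param n_reads Reads per arm (default 1e5).
#' @param error_rate Per-base substitution probability, in `[0, 0.1]`
#'   (default 5e-4, a conservative short-read substitution rate; note that
#'   errors inside the PAM window cap the measurable depletion of a fully
#'   depleted variant at roughly `-log2(4 * error_rate)` log2 units).
#' @param spec The [pam_library_spec()] providing anchor and flanks.
#' @param seed Integer seed.
#' @return List with `treatment` and `control` (sequence-record data frames)
#'   and `truth` (planted per-variant read counts for each arm).
#' @export
gen_screen_reads <- function(library, activity, n_reads = 1e5,
                             error_rate = 5e-4, spec = eh_library_spec("invivo"),
                             seed = 0) {
  stopifnot(inherits(library, "pam_count_table"))
  if (error_rate < 0 || error_rate > 0.1)
    usage_error("gen_screen_reads(): error_rate must be in [0, 0.1]")
  variants <- names(library$counts)
  if (!all(variants %in% names(activity)))
    usage_error("gen_screen_reads(): activity model missing variants: ",
                paste(head(setdiff(variants, names(activity))), collapse = ", "))
  surv <- activity[variants]
  if (any(surv < 0 | surv > 1)) usage_error("gen_screen_reads(): survival outside [0, 1]")
  f <- library$counts / library$total
  w <- f * surv
  if (sum(w) == 0) usage_error("gen_screen_reads(): no variant survives treatment")
  with_seed(seed, {
    ct <- as.vector(rmultinom(1, n_reads, w / sum(w)))
    cc <- as.vector(rmultinom(1, n_reads, f))
    make_arm <- function(counts, arm) {
      v <- sample(rep(variants, counts))
      seqs <- mutate_substitutions(screen_read_seq(spec, v), error_rate)
      seq_records(sprintf("%s_%06d", arm, seq_along(seqs)), seqs,
                  strrep("I", nchar(seqs)))
    }
    treatment <- make_arm(ct, "trt")
    control <- make_arm(cc, "ctl")
  })
  list(treatment = treatment, control = control,
       truth = list(treatment_counts = setNames(ct, variants),
                    control_counts = setNames(cc, variants)))
}

#' Target context of a screen substrate, with PAM coordinates
#'
#' Builds the constant substrate layout `flank5 + anchor + PAM-region +
#' flank3` with the randomized PAM window rendered as `N`s, and records the
#' 1-based coordinates of the protospacer and PAM region. This is the
#' reference frame that [infer_cut_site()] maps fragment termini onto.
#'
#' @param spec A [pam_library_spec()].
#' @return List with `seq`, `protospacer_start`, `protospacer_end`,
#'   `pam_start`, `pam_end`.
#' @export
target_context_from_spec <- function(spec) {
  stopifnot(inherits(spec, "pam_library_spec"))
  plen <- nchar(spec$pattern)
  ps <- nchar(spec$flank5) + 1L
  pe <- nchar(spec$flank5) + nchar(spec$anchor)
  list(seq = paste0(spec$flank5, spec$anchor, strrep("N", plen), spec$flank3),
       protospacer_start = ps, protospacer_end = pe,
       pam_start = pe + 1L, pam_end = pe + plen)
}

#' Simulate adapter-ligated cleavage-fragment reads
#'
#' Models the in vitro screen's readout: molecules drawn from the library are
#' cleaved with probability `1 - survival`; adapters are ligated to the
#' resulting fragment ends and each cleaved molecule yields one read per
#' strand starting at the adapter-fragment junction, so the first template
#' base of a read marks a cut terminus on its strand. The top (spacer-
#' matching) strand is cut `cut_offset` nt from the PAM-proximal protospacer
#' end; the bottom strand at `cut_offset + overhang` (`overhang = 0` is a
#' blunt cut).
#'
#' @param library A `pam_count_table` for the input pool.
#' @param activity Named survival vector (probability of escaping cleavage).
#' @param cut_offset Top-strand cut position, nt from the PAM-proximal
#'   protospacer end (>= 1).
#' @param overhang Stagger between the two strand cuts in nt (0 = blunt).
#' @param adapter Ligated adapter sequence (>= 8 nt so junctions are
#'   anchorable).
#' @param spec The [pam_library_spec()] providing anchor and flanks.
#' @param n Number of library molecules to draw.
#' @param read_len Read length cap (adapter included).
#' @param seed Integer seed.
#' @return List with `reads` (sequence-record data frame), `truth` (planted
#'   per-strand termini offsets, per-read strand/variant, cleaved count) and
#'   `context` (see [target_context_from_spec()]).
#' @export
gen_cleavage_fragments <- function(library, activity, cut_offset = 3,
                                   overhang = 0,
                                   adapter = eh_preset()$screen$adapter,
                                   spec = eh_library_spec("invivo"),
                                   n = 1e4, read_len = 100, seed = 0) {
  stopifnot(inherits(library, "pam_count_table"))
  if (nchar(adapter) < 8)
    usage_error("gen_cleavage_fragments(): adapter shorter than 8 nt is unanchorable")
  if (cut_offset < 1) usage_error("gen_cleavage_fragments(): cut_offset must be >= 1")
  if (overhang < 0) usage_error("gen_cleavage_fragments(): overhang must be >= 0")
  variants <- names(library$counts)
  if (!all(variants %in% names(activity)))
    usage_error("gen_cleavage_fragments(): activity model missing variants")
  surv <- activity[variants]
  ctx <- target_context_from_spec(spec)
  pe <- ctx$protospacer_end
  m_bottom <- pe - cut_offset - overhang
  if (m_bottom < 1 || pe - cut_offset + 1 < 1)
    usage_error("gen_cleavage_fragments(): cut falls outside the substrate")
  with_seed(seed, {
    f <- library$counts / library$total
    mol <- as.vector(rmultinom(1, n, f))
    cleaved <- rbinom(length(mol), mol, 1 - surv)
    v <- rep(variants, cleaved)
    full <- screen_read_seq(spec, v)
    L <- if (length(full)) nchar(full[1]) else 0L
    top <- paste0(adapter, substr(full, pe - cut_offset + 1, L))
    bottom <- paste0(adapter, revcomp(substr(full, 1, m_bottom)))
    seqs <- substr(c(top, bottom), 1, read_len)
    strand <- rep(c("+", "-"), each = length(v))
    ids <- sprintf("frag_%s_%06d", ifelse(strand == "+", "top", "bot"),
                   seq_along(seqs))
    reads <- seq_records(ids, seqs, strrep("I", nchar(seqs)))
  })
  list(reads = reads,
       truth = list(top_offset = cut_offset, bottom_offset = cut_offset + overhang,
                    overhang = overhang, variant = rep(v, 2), strand = strand,
                    cleaved_counts = setNames(cleaved, variants)),
       context = ctx)
}

#' Parse / apply an allele label of the form "-2:1D" or "+1:2I"
#'
#' Labels locate indels relative to the expected cleavage site: positions
#' `-1, -2, ...` are the bases immediately 5' of the cut on the reference,
#' `+1, +2, ...` immediately 3'. `"-2:1D"` is a 1-nt deletion starting at
#' position -2; `"+1:2I"` a 2-nt insertion anchored before position +1
#' (i.e. at the cut). The cut itself sits between reference positions
#' `cut_pos` and `cut_pos + 1` (1-based).
#'
#' @param label Allele label string.
#' @return `parse_allele_label()`: list with `rel` (signed start), `len`,
#'   `type` (`"D"` or `"I"`).
#' @export
#' @examples
#' parse_allele_label("-2:1D")
parse_allele_label <- function(label) {
  m <- regmatches(label, regexec("^([+-][0-9]+):([0-9]+)([DI])$", label))[[1]]
  if (length(m) == 0) usage_error("invalid allele label: ", label)
  rel <- as.integer(m[2])
  if (rel == 0) usage_error("invalid allele label (no position 0): ", label)
  list(rel = rel, len = as.integer(m[3]), type = m[4])
}

# signed relative position -> 1-based reference position
rel_to_ref <- function(rel, cut_pos) ifelse(rel < 0, cut_pos + rel + 1L, cut_pos + rel)

# 1-based reference position -> signed relative position
ref_to_rel <- function(pos, cut_pos) ifelse(pos <= cut_pos, pos - cut_pos - 1L, pos - cut_pos)

#' @rdname parse_allele_label
#' @param refseq Reference amplicon sequence.
#' @param cut_pos Cut site: the break lies between `cut_pos` and
#'   `cut_pos + 1`.
#' @param insert_bases For insertions, the inserted bases (random if `NULL`;
#'   caller provides RNG scope).
#' @return `apply_allele()`: the edited sequence.
#' @export
apply_allele <- function(refseq, cut_pos, label, insert_bases = NULL) {
  al <- parse_allele_label(label)
  p <- rel_to_ref(al$rel, cut_pos)
  L <- nchar(refseq)
  if (al$type == "D") {
    if (p < 1 || p + al$len - 1 > L)
      usage_error("allele label outside the amplicon: ", label)
    paste0(substr(refseq, 1, p - 1), substr(refseq, p + al$len, L))
  } else {
    if (p < 1 || p > L + 1)
      usage_error("allele label outside the amplicon: ", label)
    ins <- insert_bases %||% random_dna(al$len)
    if (nchar(ins) != al$len) usage_error("insert_bases length mismatch for ", label)
    paste0(substr(refseq, 1, p - 1), ins, substr(refseq, p, L))
  }
}

# canonical (left-aligned) form of a deletion label on a given reference;
# insertion labels are already canonical when the inserted bases do not end
# with the anchor base (which the generator guarantees)
canonical_label <- function(refseq, cut_pos, label) {
  al <- parse_allele_label(label)
  if (al$type == "I") return(label)
  p <- rel_to_ref(al$rel, cut_pos)
  while (p > 1 && substr(refseq, p - 1, p - 1) == substr(refseq, p + al$len - 1, p + al$len - 1))
    p <- p - 1L
  sprintf("%+d:%dD", ref_to_rel(p, cut_pos), al$len)
}

#' Simulate edited amplicon reads with a planted indel spectrum
#'
#' Each read is the reference amplicon carrying either exactly one labelled
#' indel allele (with probability `indel_rate`, allele drawn from
#' `spectrum`), or a single substitution (an SNV-only read, probability
#' `snv_rate` among non-indel reads), or nothing (wild type). Sequencing
#' errors are substitution-free here so that planted classes are exact
#' ground truth.
#'
#' @param ref Reference amplicon: a single sequence string or a one-row
#'   sequence-record data frame.
#' @param cut_pos Expected cleavage position (break between `cut_pos` and
#'   `cut_pos + 1`).
#' @param indel_rate Probability a read carries an indel allele.
#' @param spectrum Named numeric vector, allele label -> probability
#'   (must sum to 1).
#' @param snv_rate Probability a non-indel read carries one substitution.
#' @param n Number of reads.
#' @param seed Integer seed.
#' @return List with `reads` (sequence-record data frame) and `truth`
#'   (per-read class `indel`/`snv_only`/`wt` and allele label).
#' @export
gen_editing_amplicons <- function(ref, cut_pos, indel_rate = 0.1,
                                  spectrum = c("-2:1D" = 0.4, "-1:1D" = 0.25,
                                               "+1:1I" = 0.2, "-4:2D" = 0.15),
                                  snv_rate = 0.01, n = 1e4, seed = 0) {
  refseq <- if (is.data.frame(ref)) ref$seq[1] else ref
  refseq <- toupper(refseq)
  if (abs(sum(spectrum) - 1) > 1e-8)
    usage_error("gen_editing_amplicons(): spectrum probabilities must sum to 1")
  for (lab in names(spectrum)) apply_allele(refseq, cut_pos, lab, strrep("A", parse_allele_label(lab)$len))
  # report labels in their canonical left-aligned form so downstream calls
  # (which left-normalize indels) are comparable label-for-label
  canon <- vapply(names(spectrum), canonical_label, character(1),
                  refseq = refseq, cut_pos = cut_pos)
  if (anyDuplicated(canon))
    warning("gen_editing_amplicons(): spectrum labels collide after left-alignment")
  ins_content <- function(lab) {
    al <- parse_allele_label(lab)
    if (al$type != "I") return(NULL)
    anchor <- substr(refseq, rel_to_ref(al$rel, cut_pos) - 1L,
                     rel_to_ref(al$rel, cut_pos) - 1L)
    last <- sample(setdiff(c("A", "C", "G", "T"), anchor), 1)
    paste0(if (al$len > 1) random_dna(al$len - 1) else "", last)
  }
  with_seed(seed, {
    is_indel <- runif(n) < indel_rate
    is_snv <- !is_indel & runif(n) < snv_rate
    label <- rep(NA_character_, n)
    label[is_indel] <- sample(names(spectrum), sum(is_indel), replace = TRUE,
                              prob = spectrum)
    seqs <- rep(refseq, n)
    for (i in which(is_indel))
      seqs[i] <- apply_allele(refseq, cut_pos, label[i], ins_content(label[i]))
    label[is_indel] <- canon[label[is_indel]]
    for (i in which(is_snv)) {
      p <- sample.int(nchar(refseq), 1)
      b <- sample(setdiff(c("A", "C", "G", "T"), substr(seqs[i], p, p)), 1)
      substr(seqs[i], p, p) <- b
    }
    reads <- seq_records(sprintf("amp_%06d", seq_len(n)), seqs, strrep("I", nchar(seqs)))
  })
  cls <- ifelse(is_indel, "indel", ifelse(is_snv, "snv_only", "wt"))
  list(reads = reads, truth = data.frame(id = reads$id, class = cls,
                                         label = label, stringsAsFactors = FALSE))
}

# mutate exactly k positions of a sequence (substitutions to different bases)
mutate_exactly <- function(seq, k) {
  s <- chars(seq)
  pos <- sample(seq_along(s), k)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

#' Simulate a contig carrying a CRISPR locus
#'
#' Plants, at recorded coordinates on an i.i.d. random background:
#' a repeat-spacer array (`length(spacers) + 1` repeat units), an ORF of
#' exactly `orf_len_aa` codons (ATG start, in-frame stop, no internal stops)
#' and one copy of the repeat's reverse complement carrying exactly
#' `anti_repeat_mismatches` substitutions (the anti-repeat / tracrRNA
#' candidate), placed outside the array. Background bases immediately
#' flanking the array are chosen so the repeat units are not spuriously
#' extendable, keeping the planted repeat length exactly recoverable.
#'
#' @param repeat_seq CRISPR repeat (>= 18 nt).
#' @param spacers Character vector of spacer sequences (>= 1).
#' @param orf_len_aa ORF length in codons (>= 100; the translated protein
#'   has this many residues).
#' @param anti_repeat_mismatches Substitutions planted in the anti-repeat.
#' @param orf_strand Strand the ORF is planted on.
#' @param bg_lens Background segment lengths (before anti-repeat / before
#'   ORF / before array / after array).
#' @param seed Integer seed.
#' @return List with `record` (one-row sequence-record data frame) and
#'   `truth` (1-based closed coordinates of all planted features).
#' @export
#' @examples
#' p <- eh_preset()
#' ctg <- gen_locus_contig(p$`repeat`, p$spacer, orf_len_aa = 120, seed = 1)
#' ctg$truth$array$units
gen_locus_contig <- function(repeat_seq, spacers, orf_len_aa = 1070,
                             anti_repeat_mismatches = 4, orf_strand = "+",
                             bg_lens = c(400, 150, 150, 120), seed = 0) {
  if (nchar(repeat_seq) < 18) usage_error("gen_locus_contig(): repeat must be >= 18 nt")
  if (orf_len_aa < 100) usage_error("gen_locus_contig(): orf_len_aa must be >= 100")
  if (length(spacers) < 1) usage_error("gen_locus_contig(): at least one spacer required")
  repeat_seq <- toupper(repeat_seq); spacers <- toupper(spacers)
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, stops)
  with_seed(seed, {
    bg <- lapply(bg_lens, random_dna)
    anti <- mutate_exactly(revcomp(repeat_seq), anti_repeat_mismatches)
    orf <- paste0("ATG", paste(sample(sense, orf_len_aa - 1, replace = TRUE),
                               collapse = ""), "TAA")
    # in-frame stop directly upstream keeps the planted ATG the ORF start
    orf_block <- paste0("TAA", orf)
    if (orf_strand == "-") orf_block <- revcomp(orf_block)
    array_seq <- paste0(repeat_seq,
                        paste0(vapply(spacers, function(s) paste0(s, repeat_seq),
                                      character(1)), collapse = ""))
    # forbid spurious repeat extension into the background at the array edges
    last_sp <- substr(spacers[1], nchar(spacers[1]), nchar(spacers[1]))
    b3 <- bg[[3]]
    if (substr(b3, nchar(b3), nchar(b3)) == last_sp)
      substr(b3, nchar(b3), nchar(b3)) <- sample(setdiff(c("A", "C", "G", "T"), last_sp), 1)
    bg[[3]] <- b3
    first_sp <- substr(spacers[length(spacers)], 1, 1)
    b4 <- bg[[4]]
    if (substr(b4, 1, 1) == first_sp)
      substr(b4, 1, 1) <- sample(setdiff(c("A", "C", "G", "T"), first_sp), 1)
    bg[[4]] <- b4
  })
  # order mirrors the natural locus: cas ORF, then the tracrRNA candidate
  # (anti-repeat) in the intergenic region, then the repeat-spacer array --
  # keeping the anti-repeat within the default search window of the array
  parts <- c(bg[[1]], orf_block, bg[[2]], anti, bg[[3]], array_seq, bg[[4]])
  contig <- paste(parts, collapse = "")
  off <- cumsum(c(0, nchar(parts)))  # start offset of each part
  anti_start <- off[4] + 1L
  orf_block_start <- off[2] + 1L
  orf_start <- if (orf_strand == "+") orf_block_start + 3L else orf_block_start
  orf_end <- orf_start + nchar(orf) - 1L
  arr_start <- off[6] + 1L
  rl <- nchar(repeat_seq)
  unit_starts <- arr_start + c(0L, cumsum(rl + nchar(spacers)))
  units <- data.frame(start = unit_starts, end = unit_starts + rl - 1L)
  spacer_df <- data.frame(seq = spacers,
                          start = units$end[-nrow(units)] + 1L,
                          end = unit_starts[-1] - 1L, stringsAsFactors = FALSE)
  list(record = seq_records("synthetic_locus", contig),
       truth = list(
         anti_repeat = list(start = anti_start, end = anti_start + rl - 1L,
                            strand = "-", mismatches = anti_repeat_mismatches),
         orf = list(start = orf_start, end = orf_end, strand = orf_strand,
                    len_aa = orf_len_aa),
         array = list(repeat_consensus = repeat_seq, repeat_len = rl,
                      units = units, spacers = spacer_df)))
}
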