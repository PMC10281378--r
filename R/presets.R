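#' Packaged EH system presets
#'
#' Loads the packaged preset describing the EH CRISPR-Cas9 system geometry:
#' the 36-bp repeat / 29-bp spacer array, the 80-nt tracrRNA region whose 5'
#' end is the anti-repeat, the sgRNA recipe (23-nt spacer, 18-nt truncated
#' repeat, GAAA tetraloop, 73-nt tracrRNA fragment), the PAM patterns of the
#' two screens (`TNNN` in vivo, `NNNNNNN` in vitro), the blunt cut at offset
#' 3 nt from the PAM, and the recombineering arm lengths (145/163 bp).
#'
#' The element lengths and motif strings are the system's published geometry;
#' the repeat/spacer/tracr/flank nucleotide sequences are synthetic stand-ins
#' with that geometry (the real ones are not bundled). The in vivo screen
#' anchor is the published 29-nt target sequence.
#'
#' @return Nested list of preset values.
#' @export
#' @examples
#' nchar(eh_preset()$repeat)  # 36
eh_preset <- function() {
  path <- system.file("extdata", "eh_presets.yaml", package = "ehcastools")
  yaml::read_yaml(path)$eh
}

#' Library specification for a PAM-randomized plasmid screen
#'
#' Describes the randomized PAM region relative to the fixed protospacer
#' (anchor): the IUPAC pattern of the randomized window (placed immediately
#' 3' of the anchor on the spacer-matching strand) and the constant flanks
#' used when reads are synthesized.
#'
#' @param pattern IUPAC pattern of the PAM region (e.g. `"TNNN"` for the
#'   in vivo screen, `"NNNNNNN"` for the in vitro screen).
#' @param anchor Fixed protospacer/target sequence 5' of the PAM region.
#' @param flank5,flank3 Constant sequences placed around `anchor + PAM` in
#'   synthesized reads.
#' @return An object of class `pam_library_spec`.
#' @export
pam_library_spec <- function(pattern, anchor,
                             flank5 = eh_preset()$screen$flank5,
                             flank3 = eh_preset()$screen$flank3) {
  stopifnot(nchar(anchor) > 0)
  sets <- lapply(chars(pattern), iupac_expand)  # validates symbols
  structure(list(pattern = toupper(pattern), anchor = toupper(anchor),
                 flank5 = toupper(flank5), flank3 = toupper(flank3),
                 n_variants = prod(lengths(sets))),
            class = "pam_library_spec")
}

#' @export
print.pam_library_spec <- function(x, ...) {
  cat("PAM library spec\n")
  cat("  pattern:", x$pattern, sprintf("(%d variants)\n", x$n_variants))
  cat("  anchor: ", x$anchor, "\n")
  invisible(x)
}

#' @rdname pam_library_spec
#' @param screen `"invivo"` (TNNN, 64 variants) or `"invitro"`
#'   (NNNNNNN, 16384 variants).
#' @export
eh_library_spec <- function(screen = c("invivo", "invitro")) {
  screen <- match.arg(screen)
  p <- eh_preset()
  pattern <- if (screen == "invivo") p$pam$invivo_pattern else p$pam$invitro_pattern
  pam_library_spec(pattern, p$anchor, p$screen$flank5, p$screen$flank3)
}

#' Survival models for screen simulations
#'
#' An activity model maps every PAM variant to a survival probability: the
#' chance that a plasmid carrying it escapes interference (in vivo) or
#' escapes cleavage (in vitro). `eh_activity()` encodes the characterized
#' PAM rule of the EH nuclease:
#'
#' * `"invivo"`: survival `active_survival` (default 1e-4, i.e. the observed
#'   4-5 orders of magnitude drop in transformation efficiency) iff positions
#'   2-3 of the PAM region are `GG`, else 1.
#' * `"invitro"`: cleavage probability
#'   `0.65 * [GG at 2-3] * (0.02 if C at 4 else 1) * (1 if T at 5 else 0.25)`,
#'   survival = 1 - cleavage. This reproduces the screen's graded readout:
#'   guanines at 2-3 indispensable, cytosine discriminated against at 4,
#'   thymine preferred at 5.
#'
#' @param variants Character vector of PAM variants (the library universe).
#' @param screen Which rule to apply.
#' @param active_survival In vivo survival of cleavable variants.
#' @return Named numeric vector of survival probabilities in `[0, 1]`.
#' @export
eh_activity <- function(variants, screen = c("invivo", "invitro"),
                        active_survival = 1e-4) {
  screen <- match.arg(screen)
  g23 <- substr(variants, 2, 2) == "G" & substr(variants, 3, 3) == "G"
  if (screen == "invivo") {
    s <- ifelse(g23, active_survival, 1)
  } else {
    stopifnot(all(nchar(variants) >= 5))
    cleave <- 0.65 * as.numeric(g23) *
      ifelse(substr(variants, 4, 4) == "C", 0.02, 1) *
      ifelse(substr(variants, 5, 5) == "T", 1, 0.25)
    s <- 1 - cleave
  }
  setNames(s, variants)
}
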