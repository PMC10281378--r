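---
title: "Characterizing a compact Cas9: methods behind the ehcastools pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a compact Cas9: methods behind the ehcastools pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehcastools)
```

## Scope

`ehcastools` implements, as desk-scale reusable code, the computational
stages with which a newly mined compact type II-C Cas9 nuclease (the EH
system, a roughly 1070-residue protein guided by a 118-nt sgRNA) is
characterized:

1. **In vivo PAM depletion screen** — per-variant counting, log2
   fold-change depletion scoring, threshold selection, sequence-logo
   matrices (`count_pams()`, `depletion_log2fc()`, `select_depleted()`,
   `logo_matrix()`).
2. **In vitro cleavage screen** — library-composition normalization, top
   fraction selection, IUPAC consensus calling, and cut-site inference from
   cleavage-fragment termini (`normalize_occurrence()`, `top_fraction()`,
   `consensus_from_pfm()`, `infer_cut_site()`).
3. **Locus mining** — CRISPR repeat-spacer array detection, six-frame ORF
   scanning, anti-repeat (tracrRNA candidate) search, sgRNA scaffold
   assembly, PAM-constrained target enumeration, and recombineering
   template construction (`find_crispr_arrays()`, `find_orfs()`,
   `find_anti_repeat()`, `design_sgrna()`, `find_targets()`,
   `build_recomb_template()`).
4. **Amplicon INDEL quantification** — global affine alignment, allele
   labelling relative to the expected cut, and editing-efficiency
   summaries (`align_amplicon()`, `call_allele()`, `summarize_editing()`).

Every input class has a seeded synthetic generator that records ground
truth (`gen_pam_library()`, `gen_screen_reads()`,
`gen_cleavage_fragments()`, `gen_editing_amplicons()`,
`gen_locus_contig()`), so each analysis stage is validated by a recovery
test rather than by fixed fixtures.

Out of scope by design: metagenome assembly and read QC, HMM-based cas-gene
classification, phylogeny, promoter/terminator and RNA secondary-structure
prediction, and any wet-lab quantity (gel densitometry, transformation
efficiencies, cell toxicity).

## Coordinate conventions

All coordinates are **1-based closed**, the R/Bioconductor convention; this
differs from 0-based half-open conventions common elsewhere, and is applied
uniformly across detectors, generators and ground-truth records.

The cut-site frame: PAM positions are numbered 1, 2, ... moving 3' from the
end of the protospacer on the spacer-matching strand. A strand's **cut
offset** is the distance in nucleotides from the PAM-proximal protospacer
boundary to the scissile phosphate, so a cut "between the 3rd and 4th
positions from the PAM" is offset 3:

```
 5'-[protospacer .....  N  N  N | N  N  N][PAM]-3'   top strand
                position:  6  5  4   3  2  1          | = cut, offset 3
```

The overhang is the absolute difference between the two strands' modal
offsets; a blunt cut has overhang 0. Allele labels for editing outcomes use
the same frame: `-2:1D` is a 1-nt deletion starting at the second base 5'
of the cut, `+1:2I` a 2-nt insertion anchored at the cut.

## The screen statistics

**Depletion score.** For each PAM variant,
\[
\mathrm{log2FC}(v) \;=\; \log_2 \frac{f_C(v)}{f_T(v)}, \qquad
f(v) = \frac{n(v) + c}{N + cV},
\]
with treatment arm \(T\) (nuclease-expressing host), control arm \(C\),
pseudocount \(c = 1\) read per variant and \(V\) the library size. The sign
is chosen so that depletion from the treatment arm — i.e. a cleavable,
nuclease-permissive PAM — scores high; the selection rule keeps variants
strictly above 7. The ratio's orientation is a package convention (the
selection threshold is symmetric under it) and is printed by the pipeline.
Whether the original analysis pseudocounted or excluded zero-count variants
is not documented; both modes exist here (`pseudocount = 0` errors on zero
counts rather than producing infinities silently).

**Depletion ceiling under sequencing error.** With per-base substitution
rate \(\varepsilon\), reads from abundant undepleted variants are misread
into a fully depleted variant at rate \(\approx 4\varepsilon/3 \cdot
3 = 4\varepsilon\) per window position set (each variant has \(3k\)
one-substitution neighbours over a \(k\)-nt window). The measurable
log2 fold-change of a fully depleted variant is therefore capped near
\(-\log_2(4\varepsilon)\): at \(\varepsilon = 2\times10^{-3}\) the ceiling
(~7) sits *below* the selection threshold. The generator's default
substitution rate is \(5\times10^{-4}\) — a conservative short-read rate —
whose ceiling (~9) clears the threshold with margin; the effect itself is
real and worth knowing about when choosing thresholds for deeper screens.

**In vitro normalization.** The cleavage screen corrects the PAM occurrence
among cleavage fragments for library composition:
\[
\mathrm{norm}(v) = f_T(v)\cdot\frac{\overline{f_C}}{f_C(v)},
\]
with \(\overline{f_C}\) the *mean control frequency over variants*
(\(1/V\) for a complete library — the other reading, a mean over
replicates, is not implemented and the choice is flagged here). The
pseudocount applies to control counts only, so a uniform control reduces
the formula to the identity exactly. Logos for the cleavage screen are
built from the top 10% of variants by normalized occurrence
(`floor(0.1 V)` variants, ties broken lexicographically), **weighted** by
normalized occurrence; an unweighted mode is a one-liner
(`logo_matrix(names(top))`).

**Consensus thresholds.** `consensus_from_pfm()` renders a PFM into a
required string (single base at frequency ≥ 0.9, else `N`) and a preferred
string (preferred bases at ≥ 0.5; otherwise bases ≤ 0.05 are excluded and
the remainder coded, e.g. `{A,G,T}` → `D`). The 0.9/0.05/0.5 values are
this package's defaults — the characterization being reproduced reports
only the resulting strings (`NGGNNNN` required, `NGGDTNN` preferred) — and
all three are exposed as config keys.

## Information content

`logo_matrix()` reports per-column information content
\(IC_j = 2 - H_j\) bits, \(H_j\) the Shannon entropy of the column's
nucleotide frequencies, with no small-sample correction: the screens
summarized here weight thousands of reads per column, where the correction
is negligible, and the uncorrected identity is what the recovery tests
check (single base → 2 bits, uniform column → 0).

## Array detection

`find_crispr_arrays()` is a seed-and-extend detector: exact 12-mers
recurring at a period compatible with the geometry bounds
(repeat 18–45 nt, spacer 15–45 nt) seed candidate unit pairs; each pair is
extended to the maximal exactly repeated span; pairs chain into arrays
(further units may diverge by ≤ 2 substitutions from the consensus); ties
break leftmost. With only two units the repeat/spacer boundary is formally
ambiguous — a flanking base that happens to match would extend the repeated
span — so the contig generator resamples the four boundary-adjacent
background bases to keep the planted boundary maximal. On real two-unit
arrays (including truncated arrays at contig ends, as here) the reported
repeat may be off by the same ambiguity; with three or more units the
boundary is determined by the data.

The anti-repeat search is a gapless Hamming scan of the repeat and its
reverse complement over a ±2 kb window around the array (array units
excluded), ranked by mismatches then distance. Gapless is a deliberate
choice: the original search was a manual degenerate-repeat scan, and a
substitution-only model is deterministic and directly checkable against an
oracle; a bulged anti-repeat would need an affine-gap variant. No
promoter/terminator prediction is attempted — candidates are ranked by
sequence evidence only.

## sgRNA assembly

The guide recipe follows the validated single-guide architecture:
23-nt spacer + 18-nt truncated repeat + `GAAA` tetraloop + 73-nt tracrRNA
fragment = 118 nt over a 95-nt constant backbone. Two open details are
resolved as configurable defaults: the retained 18 nt are the repeat's
5' half (the crRNA-retained portion at the spacer-repeat junction), and the
spacer for a 29-nt protospacer is its PAM-proximal 23 nt. The packaged
repeat/tracr sequences are synthetic stand-ins with the published geometry
(the real sequences appear only in figure panels); the assembled duplex
between the repeat part and the anti-repeat region is checked by
reverse-complement alignment with a 6-mismatch budget.

## INDEL quantification

Reads are aligned globally with affine gaps (match +2, mismatch −4, gap
open −6, extension −1; a length-\(L\) gap costs \(6+L\)) via
`Biostrings::pairwiseAlignment`, with identical-to-reference reads
bypassing the aligner and duplicate reads aligned once. Extracted indels
are then **left-normalized** (shifted to their 5'-most equivalent
placement), which makes allele labels deterministic regardless of how the
aligner breaks traceback ties — the same canonicalization VCF tooling
applies. A read is an editing event iff an indel overlaps
`cut ± 5` nt (the window is configurable; the external variant counter the
original analysis used does not document one); reads with substitutions
only are excluded from the numerator but kept in the denominator,
mirroring "reads with INDELs, excluding other sequence variations". Reads
scoring below 0 are dropped and reported. Two labels that collapse to the
same molecule (e.g. deleting either of two identical adjacent bases) are
counted as one allele — the generator warns when a requested spectrum
collides this way.

## The synthetic generators: what they emulate, and what not

All generators are pure functions of their arguments and a seed (RNG state
is scoped and restored). Defaults follow the screens' published scale:
library depth 1e5 molecules (the pooled-colony scale), 1e5 reads per arm,
in vivo survival 1e-4 for cleavable PAMs (the observed 4–5 order drop in
transformation efficiency), blunt cut at offset 3, 36-bp repeat / 29-bp
spacer / 1070-codon ORF locus geometry. Library skew and true read depths
were not reported; uniform composition and the depths above are this
package's documented choices.

The simulations are deliberately sharp in places real data is not:
sequencing error is substitution-only (so indel calls cannot be confounded
by indel-type noise), reads are single-end and fully cover the PAM region,
qualities are constant, there are no PCR duplicates or chimeras, and the
in vivo interference biology is collapsed into one Bernoulli survival per
molecule. Passing recovery tests therefore demonstrates the *statistics
and bookkeeping* are right — anchoring, counting, normalization, mode
finding, labelling — not that the pipeline is robust to artefacts the
generators do not model (adapter read-through, indel sequencing errors,
context-dependent error rates, library cross-contamination).

## Numerical and degenerate-input choices

* Barcode demultiplexing is exact-prefix (0 mismatches): no tolerance was
  documented and exactness is reproducible.
* Anchors are located by best substitution-only match with ≤ 1 mismatch;
  reads failing anchoring, or whose PAM window leaves the read or violates
  the library pattern, are counted unassigned, never guessed.
* `top_fraction()` keeps exactly `floor(fraction * V)` variants; boundary
  ties resolve to the lexicographically smaller variant.
* Tied terminus modes are reported with an ambiguity flag rather than an
  error; zero mappable junctions are an error ("no cleavage evidence").
* ORFs must be stop-terminated within the contig by default
  (`include_open = TRUE` reports open spans at contig edges).
* Empty inputs: empty read sets demultiplex to empty bins; a contig
  shorter than the minimum array geometry yields an empty list, not an
  error.

## Problem sizes used by the test-suite

The recovery suite runs the screens at 5e4–1e5 reads per arm, cut-site
recovery at 1e4 molecules over 20 random geometries, array recovery over
10 contig seeds, and amplicon quantification at 1e4 reads — sizes at which
every binomial tolerance in the tests is a 3-standard-deviation band of
the planted value, and the whole suite completes in a couple of minutes on
one CPU.

## Known limitations

* The anti-repeat scan cannot represent bulged repeat:anti-repeat duplexes
  (substitutions only).
* Array detection reports substitution-divergent units but not
  insertion/deletion-divergent ones, and two-unit boundary ambiguity is
  inherent (see above).
* The editing summary's control-sample background subtraction is limited
  to SNV-only exclusion; a paired non-transfected control mode would
  subtract allele-level background instead.
* PAM screens assume the randomized window is adjacent to a fixed anchor;
  split or gapped PAM architectures are not supported.
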