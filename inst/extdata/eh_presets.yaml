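# Packaged presets for the EH CRISPR-Cas9 system.
#
# Geometry (element lengths, motif strings, cut offset, arm lengths) follows
# the published characterization of the system.  The repeat, spacer, tracrRNA
# and flank NUCLEOTIDE SEQUENCES themselves are SYNTHETIC stand-ins with the
# correct geometry: the real sequences are only available as figure panels /
# the deposited contig, neither of which is bundled.  The in vivo screen
# target (anchor) is the published 29-nt protospacer and is used verbatim.
eh:
  # 36-bp CRISPR repeat (synthetic stand-in)
  repeat: "GTTGTAGCTCCCTTTCTCATTTCGGAAACACCCCGC"
  # 29-bp spacer between the two repeat units (synthetic stand-in)
  spacer: "AGGTCGTCATGGTACCAATCGTTCAGCTA"
  # tracrRNA fragment, 80 nt, 5' end = anti-repeat (revcomp of the first
  # 18 repeat nt carrying 2 substitutions), then stem-loop-like filler
  tracr: "GAGATAGGGAGGTACAACAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGCTTTTTTGCTAGGCCAA"
  # published in vivo screen target sequence (spacer-matching strand)
  anchor: "CCTGTATATCGTGCGAAAAAGGATGGATA"
  sgrna:
    spacer_len: 23
    keep_repeat: 18
    linker: "GAAA"
    keep_tracr: 73
    duplex_budget: 6
  pam:
    invivo_pattern: "TNNN"
    invitro_pattern: "NNNNNNN"
    target_search: "TGGN"
    guide_len: 23
  cut:
    offset: 3        # nt from the PAM-proximal protospacer end (blunt)
    overhang: 0
  screen:
    flank5: "ACGCTCAGTGGAACGAAAAC"
    flank3: "TCCTGTTACCAGTGGCTGCT"
    adapter: "AGATCGGAAGAGCACACGTC"
  recomb:
    upstream_arm_len: 145
    downstream_arm_len: 163
  array_geometry:
    repeat_len: 36
    spacer_len: 29
    n_units: 2
  orf_len_aa: 1070
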