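p <- eh_preset()

test_that("array detection recovers the planted geometry across seeds", {
  for (seed in 1:10) {
    ctg <- gen_locus_contig(p$`repeat`, p$spacer, orf_len_aa = 110, seed = seed)
    arr <- find_crispr_arrays(ctg$record)
    expect_length(arr, 1)
    expect_equal(arr[[1]]$repeat_len, 36)
    expect_equal(nchar(arr[[1]]$spacers$seq), 29)
    expect_equal(nrow(arr[[1]]$units), 2)
    expect_equal(arr[[1]]$units, ctg$truth$array$units)
    expect_equal(arr[[1]]$repeat_consensus, p$`repeat`)
  }
})

test_that("multi-unit arrays chain into a single call", {
  ctg <- gen_locus_contig(p$`repeat`, c(p$spacer, "TTACGGATCAATGCCAGTA"),
                          orf_len_aa = 110, seed = 3)
  arr <- find_crispr_arrays(ctg$record)
  expect_length(arr, 1)
  expect_equal(nrow(arr[[1]]$units), 3)
  expect_equal(nchar(arr[[1]]$spacers$seq), c(29L, 19L))
})

test_that("random contigs yield no arrays, matching the brute-force oracle", {
  for (seed in c(11, 12, 13)) {
    seq <- rand_dna(2000, seed)
    expect_false(oracle_has_array(seq))
    expect_length(find_crispr_arrays(seq), 0)
  }
  # contig shorter than the minimum geometry -> empty
  expect_length(find_crispr_arrays(rand_dna(40, 1)), 0)
})

test_that("ORF scan finds maximal stop-terminated spans on both strands", {
  ctg <- gen_locus_contig(p$`repeat`, p$spacer, orf_len_aa = 150, seed = 21)
  orfs <- find_orfs(ctg$record, min_len_aa = 100)
  hit <- orfs[orfs$start == ctg$truth$orf$start, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$end, ctg$truth$orf$end)
  expect_equal(hit$strand, "+")
  expect_equal(hit$len_aa, 150)
  expect_equal(nchar(hit$protein), 150)
  expect_equal(substr(hit$protein, 1, 1), "M")

  # reverse-strand planting maps back to the same forward coordinates
  ctg_rev <- gen_locus_contig(p$`repeat`, p$spacer, orf_len_aa = 150,
                              orf_strand = "-", seed = 21)
  orfs_rev <- find_orfs(ctg_rev$record, min_len_aa = 100)
  hit_rev <- orfs_rev[orfs_rev$strand == "-" &
                        orfs_rev$start == ctg_rev$truth$orf$start, ]
  expect_equal(nrow(hit_rev), 1)
  expect_equal(hit_rev$end, ctg_rev$truth$orf$end)
  expect_equal(hit_rev$len_aa, 150)

  # no start codon anywhere -> no ORFs under either policy
  expect_equal(nrow(find_orfs(strrep("A", 600), min_len_aa = 100)), 0)
  # started but never stop-terminated: excluded by default, reported with
  # the open-span flag
  open_orf <- paste0("ATG", strrep("AAA", 150))
  expect_equal(nrow(find_orfs(open_orf, min_len_aa = 100)), 0)
  expect_equal(nrow(find_orfs(open_orf, min_len_aa = 100, include_open = TRUE)), 1)
})

test_that("anti-repeat search reports planted candidates and excludes array units", {
  ctg <- gen_locus_contig(p$`repeat`, p$spacer, orf_len_aa = 110,
                          anti_repeat_mismatches = 4, seed = 31)
  arr <- find_crispr_arrays(ctg$record)[[1]]
  anti <- find_anti_repeat(ctg$record, arr, window = 2000, max_mismatch = 6)
  expect_equal(nrow(anti), 1)
  expect_equal(anti$start, ctg$truth$anti_repeat$start)
  expect_equal(anti$end, ctg$truth$anti_repeat$end)
  expect_equal(anti$mismatches, 4)
  expect_equal(anti$strand, "-")

  # tighter budget excludes the 4-mismatch candidate
  expect_equal(nrow(find_anti_repeat(ctg$record, arr, max_mismatch = 2)), 0)

  # array units themselves are never reported even at budget 0
  anti0 <- find_anti_repeat(ctg$record, arr, max_mismatch = 0)
  expect_false(any(anti0$start %in% arr$units$start))
})

test_that("sgRNA assembly is additive and duplex-checked", {
  d <- design_sgrna(p$`repeat`, p$tracr, strrep("A", 23))
  expect_equal(nchar(d$full_sequence), 118)
  expect_equal(nchar(d$full_sequence) - nchar(d$spacer), 95)
  expect_equal(d$full_sequence,
               paste0(d$spacer, d$repeat_part, d$linker, d$tracr_part))
  expect_equal(d$coords$end[4], 118)
  expect_lte(d$duplex_mismatches, 6)

  # backbone-only design
  d0 <- design_sgrna(p$`repeat`, p$tracr, "")
  expect_equal(nchar(d0$full_sequence), 95)
  # alternative truncations stay additive; shifting the duplex register
  # out of the anti-repeat raises a mismatch-budget warning
  expect_warning(
    d2 <- design_sgrna(p$`repeat`, p$tracr, strrep("A", 20),
                       keep_repeat = 20, keep_tracr = 70),
    "duplex")
  expect_equal(nchar(d2$full_sequence), 20 + 20 + 4 + 70)

  expect_error(design_sgrna("ACGT", p$tracr, "", keep_repeat = 18), "keep_repeat")
  expect_error(design_sgrna(p$`repeat`, "ACGT", "", keep_tracr = 73), "keep_tracr")
})

test_that("target enumeration equals the sliding-window oracle on both strands", {
  for (seed in c(3, 4, 5, 6)) {
    seq <- rand_dna(300, seed)
    for (pam in c("TGGN", "NGGN")) {
      got <- find_targets(seq, pam, guide_len = 23)
      want <- oracle_find_targets(seq, pam, guide_len = 23)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got, want)
      }
    }
  }

  # minus-strand hits appear verbatim as reverse complements on the forward strand
  seq <- rand_dna(400, 9)
  hits <- find_targets(seq, "TGGN", 23)
  minus <- hits[hits$strand == "-", ]
  for (i in seq_len(nrow(minus))) {
    site <- paste0(minus$protospacer[i], minus$pam[i])
    expect_equal(substr(seq, minus$start[i], minus$end[i]), oracle_revcomp(site))
  }

  # no GG or CC anywhere -> no TGGN hits
  expect_equal(nrow(find_targets(strrep("ACGT", 30), "TGGN", 23)), 0)
})

test_that("recombineering templates concatenate arms and excise the target", {
  up <- rand_dna(145, 51)
  down <- rand_dna(163, 52)
  tmpl <- build_recomb_template(up, down)
  expect_equal(nchar(tmpl$seq), 308)
  expect_equal(build_recomb_template("AAA", "TTT")$seq, "AAATTT")
  expect_error(build_recomb_template("", "TTT"), "non-empty")

  # in silico recombination deletes exactly the between-arm segment
  mid <- rand_dna(607, 53)
  locus <- paste0(rand_dna(80, 54), up, mid, down, rand_dna(90, 55))
  res <- apply_recomb_template(locus, tmpl)
  expect_equal(res$deleted, mid)
  expect_equal(res$edited, sub(mid, "", locus, fixed = TRUE))
  expect_equal(nchar(res$edited), nchar(locus) - 607)
})
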