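spec_vivo <- eh_library_spec("invivo")

test_that("PAM library generation conserves depth and is seed-deterministic", {
  lib <- gen_pam_library(spec_vivo, depth = 6400, skew = 0, seed = 1)
  expect_length(lib$table$counts, 64)
  expect_equal(lib$table$total, 6400)
  expect_identical(names(lib$table$counts), enumerate_pam_variants("TNNN"))

  lib2 <- gen_pam_library(spec_vivo, depth = 6400, skew = 0, seed = 1)
  expect_identical(lib$table$counts, lib2$table$counts)
  lib3 <- gen_pam_library(spec_vivo, depth = 6400, skew = 0, seed = 2)
  expect_false(identical(lib$table$counts, lib3$table$counts))

  expect_error(gen_pam_library(spec_vivo, depth = 0), "positive")
  expect_warning(gen_pam_library(spec_vivo, depth = 10, seed = 1), "below")
})

test_that("uniform library composition passes a chi-square uniformity test", {
  lib <- gen_pam_library(spec_vivo, depth = 1e6, skew = 0, seed = 3)
  p <- stats::chisq.test(lib$table$counts)$p.value
  expect_gt(p, 0.001)
  # skewed composition is detectably non-uniform at the same depth
  lib_sk <- gen_pam_library(spec_vivo, depth = 1e6, skew = 2, seed = 3)
  expect_lt(stats::chisq.test(lib_sk$table$counts)$p.value, 1e-10)
})

test_that("screen reads reflect survival reweighting and exact bookkeeping", {
  lib <- gen_pam_library(spec_vivo, depth = 2e4, seed = 4)
  # neutral survival: arms differ only by sampling noise
  act1 <- setNames(rep(1, 64), names(lib$table$counts))
  sim <- gen_screen_reads(lib$table, act1, n_reads = 5000, error_rate = 0,
                          spec = spec_vivo, seed = 5)
  expect_equal(sum(sim$truth$treatment_counts), 5000)
  expect_equal(sum(sim$truth$control_counts), 5000)
  f_t <- sim$truth$treatment_counts / 5000
  f_c <- sim$truth$control_counts / 5000
  expect_lt(max(abs(f_t - f_c)), 0.02)  # ~6 SD at these depths

  # error-free reads tally exactly to the planted ground truth
  trt <- count_pams(sim$treatment, spec_vivo)
  expect_equal(trt$counts, sim$truth$treatment_counts)
  expect_equal(attr(trt, "unassigned"), 0L)

  # missing variants in the activity model are a config error
  expect_error(gen_screen_reads(lib$table, act1[-1], 100, 0, spec_vivo, 1),
               "missing variants")
  expect_error(gen_screen_reads(lib$table, act1, 100, 0.5, spec_vivo, 1),
               "error_rate")
})

test_that("strong survival rules force depletion scores past the threshold", {
  lib <- gen_pam_library(spec_vivo, depth = 1e5, seed = 6)
  act <- eh_activity(names(lib$table$counts), "invivo", active_survival = 1e-4)
  sim <- gen_screen_reads(lib$table, act, n_reads = 1e5, error_rate = 0,
                          spec = spec_vivo, seed = 7)
  trt <- count_pams(sim$treatment, spec_vivo)
  ctl <- count_pams(sim$control, spec_vivo)
  sc <- depletion_log2fc(trt, ctl, pseudocount = 1)
  active <- names(act)[act < 1]
  expect_true(all(sc$log2fc[sc$variant %in% active] > 7))
  expect_true(all(sc$log2fc[!sc$variant %in% active] < 2))
})

test_that("cleavage fragments encode the planted cut geometry", {
  lib <- gen_pam_library(spec_vivo, depth = 1e4, seed = 8)
  surv <- setNames(rep(1, 64), names(lib$table$counts))
  surv["TGGA"] <- 0
  frag <- gen_cleavage_fragments(lib$table, surv, cut_offset = 3, overhang = 0,
                                 spec = spec_vivo, n = 2000, seed = 9)
  # only the cleaved variant contributes junction reads
  expect_true(all(frag$truth$variant == "TGGA"))
  expect_equal(sum(frag$truth$cleaved_counts > 0), 1L)
  # read pairs: one top-strand and one bottom-strand junction per molecule
  expect_equal(sum(frag$truth$strand == "+"), sum(frag$truth$strand == "-"))

  # blunt: both strand termini at the same duplex position
  prof <- infer_cut_site(frag$reads, frag$context)
  expect_equal(unname(prof$modal_offset), c(3L, 3L))
  expect_equal(prof$overhang, 0L)
  expect_equal(prof$end_type, "blunt")

  # staggered: strand modal termini differ by the overhang
  frag2 <- gen_cleavage_fragments(lib$table, surv, cut_offset = 3, overhang = 4,
                                  spec = spec_vivo, n = 2000, seed = 10)
  prof2 <- infer_cut_site(frag2$reads, frag2$context)
  expect_equal(unname(prof2$modal_offset), c(3L, 7L))
  expect_equal(prof2$overhang, 4L)
  expect_equal(prof2$end_type, "staggered")

  expect_error(gen_cleavage_fragments(lib$table, surv, adapter = "ACGT",
                                      spec = spec_vivo), "unanchorable")
})

test_that("edited amplicons carry exactly their planted alleles", {
  ref <- editing_ref()
  cut <- 180
  # no editing, no noise: all reads identical to the reference
  sim0 <- gen_editing_amplicons(ref, cut, indel_rate = 0, snv_rate = 0,
                                n = 50, seed = 11)
  expect_true(all(sim0$reads$seq == ref))
  expect_true(all(sim0$truth$class == "wt"))

  # pure single-deletion spectrum: every read is ref minus the base at -2
  sim1 <- gen_editing_amplicons(ref, cut, indel_rate = 1,
                                spectrum = c("-2:1D" = 1), snv_rate = 0,
                                n = 20, seed = 12)
  expected <- paste0(substr(ref, 1, cut - 2), substr(ref, cut, nchar(ref)))
  expect_true(all(sim1$reads$seq == expected))
  expect_true(all(sim1$truth$label == "-2:1D"))

  # planted indel count is binomial around n * rate
  sim2 <- gen_editing_amplicons(ref, cut, indel_rate = 0.1, snv_rate = 0,
                                n = 1e4, seed = 13)
  n_indel <- sum(sim2$truth$class == "indel")
  expect_lt(abs(n_indel - 1000), 3 * sqrt(1e4 * 0.1 * 0.9))

  expect_error(gen_editing_amplicons(ref, cut, spectrum = c("-2:1D" = 0.5)),
               "sum to 1")
  expect_error(gen_editing_amplicons(ref, 2, indel_rate = 1,
                                     spectrum = c("-300:5D" = 1)),
               "outside the amplicon")
})

test_that("locus contigs plant array, ORF and anti-repeat at recorded coordinates", {
  p <- eh_preset()
  ctg <- gen_locus_contig(p$`repeat`, p$spacer, orf_len_aa = 120,
                          anti_repeat_mismatches = 4, seed = 14)
  seq <- ctg$record$seq
  tr <- ctg$truth
  # repeats verbatim at the recorded unit coordinates
  for (u in seq_len(nrow(tr$array$units)))
    expect_equal(substr(seq, tr$array$units$start[u], tr$array$units$end[u]),
                 p$`repeat`)
  expect_equal(substr(seq, tr$array$spacers$start[1], tr$array$spacers$end[1]),
               p$spacer)
  # anti-repeat: revcomp of the repeat at exactly the planted mismatch count
  anti <- substr(seq, tr$anti_repeat$start, tr$anti_repeat$end)
  mm <- sum(strsplit(anti, "")[[1]] != strsplit(oracle_revcomp(p$`repeat`), "")[[1]])
  expect_equal(mm, 4)
  # ORF translates to the requested protein length
  orf <- substr(seq, tr$orf$start, tr$orf$end)
  expect_equal(substr(orf, 1, 3), "ATG")
  expect_true(substr(orf, nchar(orf) - 2, nchar(orf)) %in% c("TAA", "TAG", "TGA"))
  expect_equal(nchar(orf) / 3 - 1, 120)

  expect_identical(gen_locus_contig(p$`repeat`, p$spacer, 120, seed = 15)$record,
                   gen_locus_contig(p$`repeat`, p$spacer, 120, seed = 15)$record)
  expect_error(gen_locus_contig("ACGT", p$spacer, 120), ">= 18")
})
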