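test_that("identical read and reference align without events", {
  ref <- rand_dna(60, 1)
  aln <- align_amplicon(ref, ref)
  expect_equal(nrow(aln$events), 0)
  expect_equal(aln$score, 2 * 60)
})

test_that("a planted deletion is recovered at its leftmost placement", {
  ref <- "ACGTACCGGTTACGATCGGATCCTAGGAT"
  # delete one base inside the GG run: alignment must report the leftmost G
  read <- paste0(substr(ref, 1, 8), substr(ref, 10, nchar(ref)))
  aln <- align_amplicon(read, ref)
  expect_equal(aln$events$type, "D")
  expect_equal(aln$events$len, 1L)
  expect_equal(aln$events$ref_pos, 8L)  # leftmost of the two equivalent Gs
})

test_that("alignment scores match the affine-gap DP oracle on random pairs", {
  set.seed(5)
  for (k in 1:50) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    a <- paste(sample(c("A", "C", "G", "T"), n1, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), n2, replace = TRUE), collapse = "")
    expect_equal(align_amplicon(a, b)$score, oracle_nw_affine_score(a, b),
                 info = paste(a, b))
  }
})

test_that("allele calls classify indel / snv_only / wt around the cut", {
  ref <- editing_ref()
  cut <- 180

  # planted -2:1D
  rd <- apply_allele(ref, cut, "-2:1D")
  call <- call_allele(align_amplicon(rd, ref), cut)
  expect_equal(call$class, "indel")
  expect_equal(call$labels, "-2:1D")

  # planted insertion at the cut
  rd_i <- apply_allele(ref, cut, "+1:2I", "GG")
  call_i <- call_allele(align_amplicon(rd_i, ref), cut)
  expect_equal(call_i$class, "indel")
  expect_equal(call_i$labels, "+1:2I")

  # substitution at cut-1, no gaps -> snv_only
  rd_s <- ref
  b <- substr(rd_s, cut, cut)
  substr(rd_s, cut, cut) <- setdiff(c("A", "C", "G", "T"), b)[1]
  call_s <- call_allele(align_amplicon(rd_s, ref), cut)
  expect_equal(call_s$class, "snv_only")

  # indel 20 nt away with window 5 -> wt for editing purposes, event retained
  rd_far <- paste0(substr(ref, 1, cut - 21), substr(ref, cut - 19, nchar(ref)))
  call_far <- call_allele(align_amplicon(rd_far, ref), cut, window = 5)
  expect_equal(call_far$class, "wt")
  expect_equal(nrow(call_far$events), 1)

  # multi-indel reads get a composite label
  rd_m <- apply_allele(apply_allele(ref, cut, "-2:1D"), cut - 1, "+4:1I", "C")
  call_m <- call_allele(align_amplicon(rd_m, ref), cut)
  expect_equal(call_m$class, "indel")
  expect_length(call_m$labels, 2)
})

test_that("editing summaries count only indel reads and respect invariance", {
  ref <- editing_ref()
  cut <- 180
  sim <- gen_editing_amplicons(ref, cut, indel_rate = 0.1, snv_rate = 0.05,
                               n = 1e4, seed = 71)
  calls <- call_alleles(sim$reads, ref, cut)
  s <- summarize_editing(calls)
  expect_equal(s$n_reads, 1e4)
  # percent within 3 binomial SD of the planted 10%, SNV-only excluded
  expect_lt(abs(s$percent_indel - 10), 300 * sqrt(0.1 * 0.9 / 1e4))
  expect_equal(s$n_indel, sum(sim$truth$class == "indel"))
  expect_equal(s$n_snv_only, sum(sim$truth$class == "snv_only"))

  # order invariance and duplication invariance of the percentage
  s_rev <- summarize_editing(rev(calls))
  expect_equal(s_rev$percent_indel, s$percent_indel)
  s_dup <- summarize_editing(c(calls, calls))
  expect_equal(s_dup$percent_indel, s$percent_indel)

  # all wild type -> 0 %
  sim0 <- gen_editing_amplicons(ref, cut, indel_rate = 0, snv_rate = 0,
                                n = 100, seed = 72)
  s0 <- summarize_editing(call_alleles(sim0$reads, ref, cut))
  expect_equal(s0$percent_indel, 0)

  # single-allele population -> 100 % and a one-row allele table
  sim1 <- gen_editing_amplicons(ref, cut, indel_rate = 1,
                                spectrum = c("-2:1D" = 1), snv_rate = 0,
                                n = 50, seed = 73)
  s1 <- summarize_editing(call_alleles(sim1$reads, ref, cut))
  expect_equal(s1$percent_indel, 100)
  expect_equal(s1$alleles$label, "-2:1D")
  expect_equal(s1$alleles$frequency, 1)

  expect_error(summarize_editing(list()), "empty")
})

test_that("mixture spectra are recovered within binomial tolerance", {
  ref <- editing_ref()
  cut <- 180
  labels <- c("-2:1D", "-1:1D", "+1:1I")
  for (seed in 1:5) {
    set.seed(1000 + seed)
    w <- as.vector(stats::rmultinom(1, 100, rep(1 / 3, 3))) / 100
    if (any(w == 0)) w <- (w + 0.01) / sum(w + 0.01)
    sim <- gen_editing_amplicons(ref, cut, indel_rate = 0.2,
                                 spectrum = setNames(w, labels),
                                 snv_rate = 0, n = 1e4, seed = 2000 + seed)
    s <- summarize_editing(call_alleles(sim$reads, ref, cut))
    planted <- table(factor(sim$truth$label[sim$truth$class == "indel"],
                            levels = labels))
    for (lab in labels) {
      est <- s$alleles$count[s$alleles$label == lab]
      if (length(est) == 0) est <- 0
      expect_equal(est, unname(planted[lab]),
                   info = paste("seed", seed, lab))
    }
  }
})
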