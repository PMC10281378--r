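spec_vitro <- eh_library_spec("invitro")

make_table <- function(counts, pattern, label = "x") {
  pam_count_table(counts, pattern, label)
}

test_that("normalized occurrence follows the screen's correction formula", {
  v <- enumerate_pam_variants("TN")  # tiny 4-variant universe
  trt <- make_table(setNames(c(20, 30, 40, 10), v), "TN", "trt")
  ctl <- make_table(setNames(c(10, 20, 30, 40), v), "TN", "ctl")
  norm <- normalize_occurrence(trt, ctl, pseudocount = 0)
  f_t <- trt$counts / trt$total
  f_c <- ctl$counts / ctl$total
  expect_equal(norm$norm, unname(f_t * mean(f_c) / f_c))

  # f_T == f_C for a variant -> norm equals the mean control frequency
  trt2 <- make_table(setNames(c(10, 20, 30, 40), v), "TN", "t2")
  n2 <- normalize_occurrence(trt2, ctl, pseudocount = 0)
  expect_equal(n2$norm, rep(mean(f_c), 4))

  # worked numbers: 0.02 * 0.015 / 0.01 = 0.03
  expect_equal(0.02 * 0.015 / 0.01, 0.03)
})

test_that("uniform control composition reduces normalization to identity", {
  v <- enumerate_pam_variants(spec_vitro$pattern)
  set.seed(1)
  trt_counts <- setNames(stats::rpois(length(v), 10), v)
  ctl_counts <- setNames(rep(5, length(v)), v)
  trt <- make_table(trt_counts, spec_vitro$pattern, "trt")
  ctl <- make_table(ctl_counts, spec_vitro$pattern, "ctl")
  norm <- normalize_occurrence(trt, ctl, pseudocount = 0)
  expect_equal(norm$norm, unname(trt_counts / sum(trt_counts)), tolerance = 1e-12)

  # vectorized result equals a direct per-variant loop
  f_t <- trt_counts / sum(trt_counts)
  f_c <- ctl_counts / sum(ctl_counts)
  loop <- vapply(v, function(x) f_t[[x]] * mean(f_c) / f_c[[x]], numeric(1))
  expect_equal(sum(norm$norm), sum(loop), tolerance = 1e-12)
})

test_that("normalization is invariant to control count scaling", {
  v <- enumerate_pam_variants("NN")
  set.seed(2)
  trt <- make_table(setNames(stats::rpois(16, 50), v), "NN", "t")
  c0 <- stats::rpois(16, 30) + 1
  n1 <- normalize_occurrence(trt, make_table(setNames(c0, v), "NN", "c"), 0)
  n2 <- normalize_occurrence(trt, make_table(setNames(7 * c0, v), "NN", "c"), 0)
  expect_equal(n1$norm, n2$norm, tolerance = 1e-12)
})

test_that("top fraction keeps floor(fraction * V) variants with lexicographic ties", {
  v <- enumerate_pam_variants(spec_vitro$pattern)
  set.seed(3)
  norm <- data.frame(variant = v, norm = stats::runif(length(v)),
                     stringsAsFactors = FALSE)
  top <- top_fraction(norm, 0.10)
  expect_length(top, 1638)  # floor(0.1 * 16384)
  expect_true(min(top) >= max(norm$norm[!norm$variant %in% names(top)]))

  expect_length(top_fraction(norm, 1.0), length(v))

  tie <- data.frame(variant = c("AA", "AC", "AG", "AT"),
                    norm = c(1, 0.5, 0.5, 0.2))
  expect_equal(names(top_fraction(tie, 0.5)), c("AA", "AC"))
  expect_error(top_fraction(tie[0, ], 0.1), "empty")
  expect_error(top_fraction(tie, 0), "fraction")
})

test_that("consensus calling renders required and preferred strings", {
  # uniform PFM -> all N
  unif <- matrix(0.25, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(unname(consensus_from_pfm(unif)),
               c("NNNNNNN", "NNNNNNN"))

  # single variant -> fully determined consensus
  lm <- logo_matrix("TGGATAA")
  expect_equal(unname(consensus_from_pfm(lm)["required"]), "TGGATAA")

  # hand-built PFM mirroring the screen's readout rules
  pfm <- matrix(0.25, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm[, 2] <- c(0, 0, 1, 0)                 # G required
  pfm[, 3] <- c(0, 0, 1, 0)
  pfm[, 4] <- c(0.33, 0.01, 0.33, 0.33)     # C excluded -> D
  pfm[, 5] <- c(0.14, 0.14, 0.15, 0.57)     # T preferred
  cons <- consensus_from_pfm(pfm)
  expect_equal(unname(cons["required"]), "NGGNNNN")
  expect_equal(unname(cons["preferred"]), "NGGDTNN")
})

test_that("a simulated cleavage screen reproduces the published consensus strings", {
  lib <- gen_pam_library(spec_vitro, depth = 2e5, seed = 51)
  act <- eh_activity(names(lib$table$counts), "invitro")
  # treatment reads are drawn from the cleaved pool: weight = cleavage prob
  cleav <- setNames(1 - act, names(act))
  sim <- gen_screen_reads(lib$table, cleav, n_reads = 6e4, error_rate = 0,
                          spec = spec_vitro, seed = 52)
  trt <- count_pams(sim$treatment, spec_vitro, sample_label = "cleaved")
  ctl <- count_pams(sim$control, spec_vitro, sample_label = "library")
  norm <- normalize_occurrence(trt, ctl)
  top <- top_fraction(norm, 0.10)
  expect_length(top, 1638)
  # only cleaved variants can acquire normalized occurrence
  active <- names(cleav)[cleav > 0]
  expect_true(all(names(top)[top > 0] %in% active))
  cons <- consensus_from_pfm(logo_matrix(top))
  expect_equal(unname(cons["required"]), "NGGNNNN")
  expect_equal(unname(cons["preferred"]), "NGGDTNN")
})

test_that("cut-site recovery is exact across random geometries", {
  lib <- gen_pam_library(eh_library_spec("invivo"), depth = 1e4, seed = 61)$table
  surv <- setNames(ifelse(grepl("^TGG", names(lib$counts)), 0.2, 1),
                   names(lib$counts))
  set.seed(62)
  configs <- data.frame(offset = sample(2:8, 20, replace = TRUE),
                        overhang = sample(0:5, 20, replace = TRUE))
  ok <- 0
  for (k in seq_len(nrow(configs))) {
    frag <- gen_cleavage_fragments(lib, surv, configs$offset[k],
                                   configs$overhang[k], n = 10000,
                                   seed = 100 + k)
    prof <- infer_cut_site(frag$reads, frag$context)
    if (identical(unname(prof$modal_offset),
                  c(configs$offset[k], configs$offset[k] + configs$overhang[k])) &&
        prof$overhang == configs$overhang[k]) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("absent junctions raise a no-evidence error", {
  reads <- seq_records("r1", strrep("ACGT", 20))
  ctx <- target_context_from_spec(eh_library_spec("invivo"))
  expect_error(infer_cut_site(reads, ctx), "no cleavage evidence")
  expect_error(infer_cut_site(reads[0, ], ctx), "no cleavage evidence")
})

test_that("fragment size prediction splits the substrate at the cut", {
  sizes <- predict_fragment_sizes(840, pe = 523, offset = 3)
  expect_equal(sum(sizes), 840)
  expect_equal(sizes, c(520, 320))
})
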