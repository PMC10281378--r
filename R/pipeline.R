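# Subcommand schemas: every accepted config key with its default.  Unknown
# keys are rejected by name; flags/overrides replace config-file values.
pipeline_schemas <- function() {
  p <- eh_preset()
  list(
    "simulate/pam-library" = list(screen = "invivo", depth = 1e5, skew = 0),
    "simulate/pam-screen" = list(screen = "invivo", depth = 1e5, n_reads = 1e5,
                                 error_rate = 5e-4, active_survival = 1e-4),
    "simulate/cleavage" = list(screen = "invivo", depth = 1e5, n = 1e4,
                               cut_offset = p$cut$offset, overhang = p$cut$overhang,
                               adapter = p$screen$adapter, read_len = 100),
    "simulate/amplicons" = list(ref = NULL, cut_pos = NULL, indel_rate = 0.1,
                                snv_rate = 0.01, n = 1e4),
    "simulate/locus" = list(repeat_seq = p$`repeat`, spacers = p$spacer,
                            orf_len_aa = p$orf_len_aa, anti_repeat_mismatches = 4),
    "pam-invivo" = list(treatment = NULL, control = NULL, screen = "invivo",
                        pseudocount = 1, threshold = 7, max_anchor_mismatch = 1),
    "pam-invitro" = list(treatment = NULL, control = NULL, pseudocount = 1,
                         fraction = 0.10, require_freq = 0.9,
                         exclude_freq = 0.05, prefer_freq = 0.5),
    "cutsite" = list(reads = NULL, screen = "invivo", adapter = p$screen$adapter,
                     junction_k = 12),
    "mine" = list(contig = NULL, min_repeat = 18, max_repeat = 45,
                  min_spacer = 15, max_spacer = 45, min_units = 2,
                  window = 2000, max_mismatch = 6, min_len_aa = 100),
    "design" = list(repeat_seq = p$`repeat`, tracr = p$tracr, spacer = "",
                    keep_repeat = p$sgrna$keep_repeat, linker = p$sgrna$linker,
                    keep_tracr = p$sgrna$keep_tracr),
    "targets" = list(genome = NULL, pam = p$pam$target_search,
                     guide_len = p$pam$guide_len),
    "indel" = list(reads = NULL, ref = NULL, cut_pos = NULL, window = 5,
                   min_score = 0)
  )
}

#' Run one pipeline stage from a config
#'
#' Single entry point orchestrating all stages: `simulate/{pam-library,
#' pam-screen, cleavage, amplicons, locus}`, `pam-invivo`, `pam-invitro`,
#' `cutsite`, `mine`, `design`, `targets`, `indel`. The effective
#' configuration is `defaults <- config file <- overrides`; unknown keys
#' are rejected by name. Every run writes its outputs plus the resolved
#' config (`config.yaml`), a log (`run.log`) and a manifest
#' (`manifest.json`) listing each output file with an MD5 digest, into
#' `output_dir`. Runs are pure functions of (inputs, config, seed) at the
#' file level: same config and seed, same digests.
#'
#' @param subcommand Stage name (see above).
#' @param config Path to a YAML config file, or a named list, or `NULL`.
#' @param output_dir Output directory (created if needed).
#' @param seed Integer seed for stages that draw random numbers.
#' @param overrides Named list overriding config values (CLI flags).
#' @return Invisibly, a list with `status` (0) and the manifest data frame.
#' @export
run_pipeline <- function(subcommand, config = NULL, output_dir = tempfile("run"),
                         seed = 0, overrides = list()) {
  schemas <- pipeline_schemas()
  if (!subcommand %in% names(schemas))
    usage_error("unknown subcommand: ", subcommand, "\n  available: ",
                paste(names(schemas), collapse = ", "))
  schema <- schemas[[subcommand]]
  user <- list()
  if (is.character(config) && length(config) == 1) user <- yaml::read_yaml(config)
  else if (is.list(config)) user <- config
  user <- modifyList(user, overrides)
  bad <- setdiff(names(user), names(schema))
  if (length(bad))
    usage_error("config validation failed, unknown key(s): ",
                paste(bad, collapse = ", "))
  cfg <- modifyList(schema, user)
  provenance <- ifelse(names(cfg) %in% names(user), "user", "default")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("subcommand: %s", subcommand),
                 sprintf("seed: %d", as.integer(seed)),
                 sprintf("param %s = %s [%s]", names(cfg),
                         vapply(cfg, function(v) paste(format(v), collapse = ","), character(1)),
                         provenance))
  t0 <- proc.time()[["elapsed"]]
  files <- run_stage(subcommand, cfg, output_dir, seed)
  log_lines <- c(log_lines, sprintf("elapsed_s: %.2f", proc.time()[["elapsed"]] - t0))
  yaml::write_yaml(c(list(subcommand = subcommand, seed = as.integer(seed)), cfg),
                   file.path(output_dir, "config.yaml"))
  files <- c(files, file.path(output_dir, "config.yaml"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  writeLines(log_lines, file.path(output_dir, "run.log"))
  message(paste(log_lines, collapse = "\n"))
  invisible(list(status = 0L, manifest = manifest, output_dir = output_dir))
}

# stage dispatch: returns the vector of files written
run_stage <- function(subcommand, cfg, out, seed) {
  path <- function(...) file.path(out, ...)
  need <- function(key) {
    if (is.null(cfg[[key]])) usage_error(subcommand, ": missing required input '", key, "'")
    if (is.character(cfg[[key]]) && !file.exists(cfg[[key]]))
      usage_error(subcommand, ": input file not found: ", cfg[[key]])
    cfg[[key]]
  }
  switch(subcommand,
    "simulate/pam-library" = {
      spec <- eh_library_spec(cfg$screen)
      lib <- gen_pam_library(spec, cfg$depth, cfg$skew, seed)
      write_pam_table(lib$table, path("library.tsv"))
      jsonlite::write_json(lib$truth, path("truth.json"), auto_unbox = TRUE, digits = NA)
      path(c("library.tsv", "truth.json"))
    },
    "simulate/pam-screen" = {
      spec <- eh_library_spec(cfg$screen)
      lib <- gen_pam_library(spec, cfg$depth, seed = seed)
      act <- eh_activity(names(lib$table$counts), cfg$screen,
                         active_survival = cfg$active_survival)
      sim <- gen_screen_reads(lib$table, act, cfg$n_reads, cfg$error_rate,
                              spec, seed + 1)
      write_seq_file(sim$treatment, path("treatment.fastq"), "fastq")
      write_seq_file(sim$control, path("control.fastq"), "fastq")
      truth <- c(sim$truth, list(active_variants =
        names(act)[act < 1]))
      jsonlite::write_json(truth, path("truth.json"), auto_unbox = TRUE, digits = NA)
      path(c("treatment.fastq", "control.fastq", "truth.json"))
    },
    "simulate/cleavage" = {
      spec <- eh_library_spec(cfg$screen)
      lib <- gen_pam_library(spec, cfg$depth, seed = seed)
      act <- eh_activity(names(lib$table$counts), "invivo")
      sim <- gen_cleavage_fragments(lib$table, act, cfg$cut_offset, cfg$overhang,
                                    cfg$adapter, spec, cfg$n, cfg$read_len,
                                    seed + 1)
      write_seq_file(sim$reads, path("fragments.fastq"), "fastq")
      jsonlite::write_json(sim$truth[c("top_offset", "bottom_offset", "overhang")],
                           path("truth.json"), auto_unbox = TRUE, digits = NA)
      path(c("fragments.fastq", "truth.json"))
    },
    "simulate/amplicons" = {
      ref <- read_seq_file(need("ref"))
      sim <- gen_editing_amplicons(ref, need("cut_pos"), cfg$indel_rate,
                                   snv_rate = cfg$snv_rate, n = cfg$n, seed = seed)
      write_seq_file(sim$reads, path("amplicons.fastq"), "fastq")
      utils::write.table(sim$truth, path("truth.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      path(c("amplicons.fastq", "truth.tsv"))
    },
    "simulate/locus" = {
      sim <- gen_locus_contig(cfg$repeat_seq, cfg$spacers, cfg$orf_len_aa,
                              cfg$anti_repeat_mismatches, seed = seed)
      write_seq_file(sim$record, path("contig.fasta"))
      jsonlite::write_json(sim$truth, path("truth.json"), auto_unbox = TRUE, digits = NA)
      path(c("contig.fasta", "truth.json"))
    },
    "pam-invivo" = {
      spec <- eh_library_spec(cfg$screen)
      trt <- count_pams(read_seq_file(need("treatment"), "fastq"), spec,
                        cfg$max_anchor_mismatch, "treatment")
      ctl <- count_pams(read_seq_file(need("control"), "fastq"), spec,
                        cfg$max_anchor_mismatch, "control")
      sc <- depletion_log2fc(trt, ctl, cfg$pseudocount)
      utils::write.table(sc, path("log2fc.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      sel <- select_depleted(sc, cfg$threshold)
      writeLines(sel, path("selected_pams.txt"))
      if (length(sel)) write_logo_tsv(logo_matrix(sel), path("logo.tsv"))
      message("depletion convention: log2(f_control / f_treatment); ",
              "scores above ", cfg$threshold, " select nuclease-permissive PAMs")
      path(c("log2fc.tsv", "selected_pams.txt", if (length(sel)) "logo.tsv"))
    },
    "pam-invitro" = {
      trt <- read_pam_table(need("treatment"))
      ctl <- read_pam_table(need("control"))
      norm <- normalize_occurrence(trt, ctl, cfg$pseudocount)
      utils::write.table(norm, path("normalized.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      top <- top_fraction(norm, cfg$fraction)
      lm <- logo_matrix(top)
      write_logo_tsv(lm, path("logo.tsv"))
      cons <- consensus_from_pfm(lm, cfg$require_freq, cfg$exclude_freq,
                                 cfg$prefer_freq)
      jsonlite::write_json(as.list(cons), path("consensus.json"),
                           auto_unbox = TRUE)
      path(c("normalized.tsv", "logo.tsv", "consensus.json"))
    },
    "cutsite" = {
      reads <- read_seq_file(need("reads"), "fastq")
      ctx <- target_context_from_spec(eh_library_spec(cfg$screen))
      prof <- infer_cut_site(reads, ctx, cfg$adapter, cfg$junction_k)
      jsonlite::write_json(list(
        modal_offset = as.list(prof$modal_offset),
        overhang = prof$overhang, end_type = prof$end_type,
        n_mapped = prof$n_mapped,
        histogram = lapply(prof$histogram, function(h)
          if (is.null(h)) NULL else as.list(setNames(as.integer(h), names(h))))),
        path("cutsite.json"), auto_unbox = TRUE)
      path("cutsite.json")
    },
    "mine" = {
      contig <- read_seq_file(need("contig"))
      arrays <- find_crispr_arrays(contig, cfg$min_repeat, cfg$max_repeat,
                                   cfg$min_spacer, cfg$max_spacer, cfg$min_units)
      arr_tb <- do.call(rbind, lapply(seq_along(arrays), function(i) {
        a <- arrays[[i]]
        data.frame(name = sprintf("array%d", i), start = a$units$start,
                   end = a$units$end, feature = "repeat_unit",
                   repeat_len = a$repeat_len, stringsAsFactors = FALSE)
      })) %||% data.frame()
      utils::write.table(arr_tb, path("arrays.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      orfs <- find_orfs(contig, cfg$min_len_aa)
      utils::write.table(orfs[, c("start", "end", "strand", "len_aa")],
                         path("orfs.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c("arrays.tsv", "orfs.tsv")
      if (length(arrays)) {
        anti <- find_anti_repeat(contig, arrays[[1]], cfg$window, cfg$max_mismatch)
        utils::write.table(anti, path("anti_repeats.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        files <- c(files, "anti_repeats.tsv")
      }
      path(files)
    },
    "design" = {
      d <- design_sgrna(cfg$repeat_seq, cfg$tracr, cfg$spacer, cfg$keep_repeat,
                        cfg$linker, cfg$keep_tracr)
      write_seq_file(seq_records("sgRNA", d$full_sequence), path("sgrna.fasta"))
      jsonlite::write_json(list(components = d$coords,
                                duplex_mismatches = d$duplex_mismatches,
                                length = nchar(d$full_sequence)),
                           path("sgrna.json"), dataframe = "rows", auto_unbox = TRUE)
      path(c("sgrna.fasta", "sgrna.json"))
    },
    "targets" = {
      hits <- find_targets(read_seq_file(need("genome")), cfg$pam, cfg$guide_len)
      utils::write.table(hits, path("targets.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      path("targets.tsv")
    },
    "indel" = {
      reads <- read_seq_file(need("reads"), "fastq")
      ref <- read_seq_file(need("ref"))
      calls <- call_alleles(reads, ref, need("cut_pos"), cfg$window)
      tb <- data.frame(id = vapply(calls, `[[`, character(1), "id"),
                       class = vapply(calls, `[[`, character(1), "class"),
                       label = vapply(calls, `[[`, character(1), "label"),
                       score = vapply(calls, `[[`, numeric(1), "score"),
                       stringsAsFactors = FALSE)
      utils::write.table(tb, path("calls.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      s <- summarize_editing(calls, cfg$min_score)
      jsonlite::write_json(list(n_reads = s$n_reads, n_indel = s$n_indel,
                                percent_indel = s$percent_indel,
                                n_snv_only = s$n_snv_only,
                                n_dropped = s$n_dropped, alleles = s$alleles),
                           path("editing_summary.json"), dataframe = "rows",
                           auto_unbox = TRUE, digits = NA)
      path(c("calls.tsv", "editing_summary.json"))
    },
    usage_error("unhandled subcommand: ", subcommand))
}
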