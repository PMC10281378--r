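#' Per-variant PAM count table
#'
#' Holds read counts over the complete variant universe of a PAM library
#' pattern for one sample (treatment or control arm). The total always
#' equals the sum of counts; reads that could not be anchored or whose PAM
#' window does not match the library pattern are tracked separately in the
#' `unassigned` attribute and are not part of the total.
#'
#' @param counts Named numeric vector of non-negative counts; names are the
#'   PAM variants and must all match `pattern`.
#' @param pattern IUPAC pattern of the library. Variants of the pattern
#'   missing from `counts` are filled in with zero.
#' @param sample_label Free-text sample label.
#' @param unassigned Count of reads not attributable to any variant.
#' @return An object of class `pam_count_table` with fields `counts`
#'   (named, full universe, sorted), `total`, `pattern`, `sample`.
#' @export
pam_count_table <- function(counts, pattern, sample_label = "sample",
                            unassigned = 0L) {
  if (is.null(names(counts))) usage_error("pam_count_table(): counts must be named by variant")
  if (any(counts < 0)) usage_error("pam_count_table(): negative counts")
  universe <- enumerate_pam_variants(pattern)
  if (!all(names(counts) %in% universe))
    usage_error("pam_count_table(): variants outside the library pattern: ",
                paste(head(setdiff(names(counts), universe)), collapse = ", "))
  full <- setNames(numeric(length(universe)), universe)
  full[names(counts)] <- full[names(counts)] + counts
  structure(list(counts = full, total = sum(full), pattern = pattern,
                 sample = sample_label),
            class = "pam_count_table", unassigned = unassigned)
}

#' @export
print.pam_count_table <- function(x, ...) {
  cat(sprintf("PAM count table [%s]: %d variants of %s, %d reads (%s unassigned)\n",
              x$sample, length(x$counts), x$pattern, x$total,
              format(attr(x, "unassigned") %||% 0)))
  top <- sort(x$counts, decreasing = TRUE)
  print(head(top, 5))
  invisible(x)
}

#' Per-variant frequencies with an optional pseudocount
#'
#' `f = (count + pseudocount) / (total + pseudocount * V)` where `V` is the
#' number of variants in the library universe.
#'
#' @param x A `pam_count_table`.
#' @param pseudocount Added to every variant count (default 0).
#' @return Named numeric vector of frequencies summing to 1.
#' @export
pam_freq <- function(x, pseudocount = 0) {
  stopifnot(inherits(x, "pam_count_table"))
  (x$counts + pseudocount) / (x$total + pseudocount * length(x$counts))
}

#' Read / write a PAM count table as TSV
#'
#' Two columns, `variant` and `count`, with the pattern and sample label in
#' `#`-prefixed header lines.
#'
#' @param x A `pam_count_table`.
#' @param path Output path.
#' @return `path` (write) or a `pam_count_table` (read).
#' @export
write_pam_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# pattern=", x$pattern), paste0("# sample=", x$sample)), con)
  utils::write.table(data.frame(variant = names(x$counts), count = x$counts),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pam_table
#' @export
read_pam_table <- function(path) {
  hdr <- readLines(path, n = 2)
  meta <- sub("^# *", "", hdr)
  pattern <- sub("^pattern=", "", meta[grepl("^pattern=", meta)])
  sample <- sub("^sample=", "", meta[grepl("^sample=", meta)])
  tb <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  pam_count_table(setNames(tb$count, tb$variant), pattern,
                  if (length(sample)) sample else "sample")
}
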