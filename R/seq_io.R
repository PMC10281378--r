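#' Sequence records
#'
#' The package's working representation for read sets is a plain data frame
#' with columns `id`, `seq` and `qual` (`qual` is `NA` for FASTA input).
#' Qualities are Phred+33 strings; they are carried through demultiplexing
#' and written back out, but no quality filtering is performed.
#'
#' @param id Character vector of record labels.
#' @param seq Character vector of nucleotide sequences over `{A,C,G,T,N}`.
#' @param qual Optional character vector of Phred+33 quality strings, same
#'   lengths as `seq`.
#' @return A `data.frame` with columns `id`, `seq`, `qual`.
#' @export
#' @examples
#' seq_records("r1", "ACGT", "IIII")
seq_records <- function(id, seq, qual = NULL) {
  seq <- toupper(seq)
  if (!all(grepl("^[ACGTN]*$", seq)))
    usage_error("seq_records(): bases outside {A,C,G,T,N}")
  if (!is.null(qual)) {
    if (any(nchar(qual) != nchar(seq)))
      usage_error("seq_records(): quality string length differs from sequence length")
  } else {
    qual <- rep(NA_character_, length(seq))
  }
  data.frame(id = unname(as.character(id)), seq = unname(seq),
             qual = unname(qual), stringsAsFactors = FALSE)
}

#' Read a FASTA or FASTQ file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]. Bases are uppercased on
#' load; characters outside the IUPAC alphabet are a parse error. Record order
#' is preserved, and a write-then-read round trip through [write_seq_file()]
#' is lossless.
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by file extension).
#' @return A sequence-record data frame (see [seq_records()]); FASTQ
#'   qualities are Phred+33 strings in column `qual`.
#' @export
read_seq_file <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (!file.exists(path)) usage_error("read_seq_file(): no such file: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format, with.qualities = (format == "fastq")),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  qual <- if (format == "fastq") as.character(S4Vectors::mcols(x)$qualities) else NULL
  seq_records(names(x), toupper(as.character(x)), qual)
}

#' Write sequence records to FASTA or FASTQ
#'
#' @param reads Sequence-record data frame.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`; FASTQ requires qualities (reads
#'   without one get a constant maximum-confidence string).
#' @return `path`, invisibly.
#' @export
write_seq_file <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  if (format == "fastq") {
    qual <- reads$qual
    qual[is.na(qual)] <- vapply(nchar(reads$seq[is.na(qual)]),
                                function(n) strrep("I", n), character(1))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual))
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Decode / encode Phred+33 quality strings
#'
#' @param qual A single quality string (Phred+33).
#' @return `phred_to_int()`: integer vector of per-base qualities.
#' @export
#' @examples
#' phred_to_int("IIII")
phred_to_int <- function(qual) utf8ToInt(qual) - 33L

#' @rdname phred_to_int
#' @param q Integer vector of Phred qualities.
#' @export
int_to_phred <- function(q) intToUtf8(q + 33L)

#' Expand an IUPAC nucleotide code
#'
#' @param code Single IUPAC symbol (e.g. `"D"`).
#' @return Character vector of the bases the symbol admits.
#' @export
#' @examples
#' iupac_expand("D")  # A, G, T
iupac_expand <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) usage_error("iupac_expand(): invalid IUPAC code: ", code)
  chars(map[[code]])
}

#' Match a sequence against an IUPAC degenerate pattern
#'
#' True iff every base of `seq` lies in the expansion of the corresponding
#' pattern symbol; e.g. `D` admits A, G or T but not C. `seq` and `pattern`
#' must be the same length (this is a positional motif test, not a search).
#'
#' @param seq Character vector of nucleotide strings over `{A,C,G,T}`.
#' @param pattern A single IUPAC pattern string (e.g. `"NGGDT"`).
#' @return Logical vector, one element per sequence.
#' @export
#' @examples
#' iupac_match(c("TGGAT", "TGGCT"), "NGGDT")
iupac_match <- function(seq, pattern) {
  stopifnot(length(pattern) == 1)
  if (length(seq) == 0) return(logical(0))
  if (any(nchar(seq) != nchar(pattern)))
    usage_error("iupac_match(): sequence and pattern lengths differ")
  psym <- chars(pattern)
  sets <- lapply(psym, iupac_expand)
  m <- matrix(unlist(strsplit(seq, "", fixed = TRUE)), ncol = nchar(pattern), byrow = TRUE)
  ok <- rep(TRUE, length(seq))
  for (j in seq_along(psym)) ok <- ok & (m[, j] %in% sets[[j]])
  ok
}

#' Enumerate all concrete variants of an IUPAC pattern
#'
#' @param pattern IUPAC pattern string.
#' @return Character vector of all matching sequences, lexicographically
#'   sorted (e.g. 64 variants for `"TNNN"`).
#' @export
enumerate_pam_variants <- function(pattern) {
  sets <- lapply(chars(pattern), iupac_expand)
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  v <- do.call(paste0, rev(grid))
  sort(v)
}

#' Demultiplex reads by exact barcode prefix
#'
#' A read is assigned to a sample iff its prefix equals that sample's barcode
#' exactly (no mismatches); reads matching no barcode land in the unassigned
#' bin. Barcodes must be equal length and mutually distinct, so a read can
#' match at most one.
#'
#' @param reads Sequence-record data frame.
#' @param barcodes Named character vector (label -> barcode sequence), or a
#'   path to a two-column TSV (label, sequence).
#' @return List with `bins` (named list of record data frames, one per label,
#'   in barcode order) and `unassigned` (record data frame).
#' @export
demultiplex <- function(reads, barcodes) {
  if (is.character(barcodes) && is.null(names(barcodes)) && length(barcodes) == 1 &&
      file.exists(barcodes)) {
    barcodes <- read_barcode_tsv(barcodes)
  }
  if (is.null(names(barcodes)) || any(names(barcodes) == ""))
    usage_error("demultiplex(): barcodes must be a named vector (label -> sequence)")
  barcodes <- toupper(barcodes)
  if (anyDuplicated(barcodes))
    usage_error("demultiplex(): duplicate barcode sequences")
  if (length(unique(nchar(barcodes))) > 1)
    usage_error("demultiplex(): barcodes must be equal length")
  bl <- nchar(barcodes[1])
  prefix <- substr(reads$seq, 1, bl)
  hit <- match(prefix, barcodes)
  bins <- lapply(seq_along(barcodes), function(i) reads[which(hit == i), , drop = FALSE])
  names(bins) <- names(barcodes)
  list(bins = bins, unassigned = reads[is.na(hit), , drop = FALSE])
}

#' @rdname demultiplex
#' @param path Path to a two-column, tab-separated file (label, sequence),
#'   no header.
#' @export
read_barcode_tsv <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("label", "sequence"))
  setNames(toupper(tb$sequence), tb$label)
}
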